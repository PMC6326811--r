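#' Bundle replicate Ct values for one sample
#'
#' @param sample Sample label.
#' @param target_ct Replicate threshold cycles of the target assay
#'   (e.g. hTR, hexamer- or oligo(dT)-primed), each in (0, 45).
#' @param reference_ct Replicate threshold cycles of the normaliser
#'   (e.g. GAPDH); recycled to the target's length if scalar.
#' @return A tibble of class `ct_measurement`.
#' @export
ct_measurement <- function(sample, target_ct, reference_ct) {
  if (length(target_ct) < 1 || length(reference_ct) < 1) {
    abort("At least one replicate is required.")
  }
  if (any(c(target_ct, reference_ct) <= 0) || any(c(target_ct, reference_ct) >= 45)) {
    abort("Ct values must lie in (0, 45).")
  }
  out <- tibble(sample = sample,
                target_ct = list(as.numeric(target_ct)),
                reference_ct = list(as.numeric(reference_ct)))
  class(out) <- c("ct_measurement", class(out))
  out
}

dct_stats <- function(m) {
  t_ct <- m$target_ct[[1]]
  r_ct <- m$reference_ct[[1]]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(dct = mean(t_ct) - mean(r_ct),
       sd = sqrt(sd0(t_ct)^2 + sd0(r_ct)^2))
}

#' Comparative-CT (delta-delta-CT) fold change
#'
#' Replicates are summarised by their mean Ct; per group
#' `dCt = mean(target) - mean(reference)`, then
#' `ddCt = dCt_sample - dCt_control` and the fold change is `2^(-ddCt)`
#' (amplification efficiency fixed at 2). Replicate standard deviations are
#' propagated in ddCt space: `sd_ddct = sqrt(sd_dct_sample^2 +
#' sd_dct_control^2)` with `sd_dct = sqrt(sd_target^2 + sd_reference^2)`,
#' and reported as a fold-change interval `2^(-ddCt -+ sd)`.
#'
#' @param sample,control `ct_measurement` objects.
#' @return One-row tibble: `sample`, `control`, `ddct`, `fold_change`,
#'   `log2_fold_change`, `sd_ddct`, `fold_lo`, `fold_hi`.
#' @export
#' @examples
#' s <- ct_measurement("KO", target_ct = c(24.1, 24.0), reference_ct = c(18, 18.1))
#' c0 <- ct_measurement("NC", target_ct = c(25.1, 25.0), reference_ct = c(18, 18.1))
#' ddct_fold_change(s, c0)  # ~2-fold up
ddct_fold_change <- function(sample, control) {
  if (!inherits(sample, "ct_measurement") || !inherits(control, "ct_measurement")) {
    abort("Both arguments must be ct_measurement objects.")
  }
  s <- dct_stats(sample)
  c0 <- dct_stats(control)
  ddct <- s$dct - c0$dct
  sd_ddct <- sqrt(s$sd^2 + c0$sd^2)
  tibble(
    sample = sample$sample, control = control$sample,
    ddct = ddct,
    fold_change = 2^(-ddct),
    log2_fold_change = -ddct,
    sd_ddct = sd_ddct,
    fold_lo = 2^(-ddct - sd_ddct),
    fold_hi = 2^(-ddct + sd_ddct)
  )
}

#' Relative activity from paired Ct values
#'
#' PCR-based relative quantification normalised to a control:
#' `2^(control_ct - sample_ct)`, so the control maps to 1 and each extra
#' cycle halves the reported activity. Used for relative telomerase
#' activity readouts from quantitative telomeric repeat amplification.
#'
#' @param sample_ct,control_ct Threshold cycles (vectorised).
#' @return Relative activity value(s); monotone decreasing in `sample_ct`.
#' @export
#' @examples
#' relative_activity(21, 20)  # 0.5
relative_activity <- function(sample_ct, control_ct) {
  if (any(sample_ct <= 0) || any(control_ct <= 0)) abort("Ct values must be positive.")
  2^(control_ct - sample_ct)
}
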