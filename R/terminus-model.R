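#' Terminus mixture models
#'
#' A terminus state is a pair (genomic end `g`, non-templated A count `a`):
#' the transcript retains templated sequence through reference position `g`
#' and carries `a` post-transcriptionally added adenosines. A terminus model
#' is a mixture over such states and serves as the simulator's ground truth
#' for the biological terminus distribution.
#'
#' @param genomic_end Integer vector of last templated positions.
#' @param a_tail Integer vector of non-templated A counts (>= 0).
#' @param weight Non-negative mixture weights; normalised to sum to 1.
#' @return A tibble of class `terminus_model` with columns `genomic_end`,
#'   `a_tail`, `weight`.
#' @export
#' @examples
#' terminus_model(c(451, 451), c(0, 2), c(0.8, 0.2))
terminus_model <- function(genomic_end, a_tail, weight) {
  n <- length(genomic_end)
  if (n == 0) abort("A terminus model needs at least one component.")
  if (length(a_tail) != n || length(weight) != n) {
    abort("genomic_end, a_tail and weight must have equal length.")
  }
  if (any(genomic_end < 1)) abort("genomic_end must be >= 1.")
  if (any(a_tail < 0)) abort("a_tail must be >= 0.")
  if (any(weight < 0) || sum(weight) <= 0) abort("Weights must be non-negative with positive sum.")
  out <- tibble(
    genomic_end = as.integer(genomic_end),
    a_tail = as.integer(a_tail),
    weight = weight / sum(weight)
  )
  class(out) <- c("terminus_model", class(out))
  out
}

validate_terminus_model <- function(model) {
  if (!inherits(model, "terminus_model") || nrow(model) == 0) {
    abort("`model` must be a non-empty terminus_model.")
  }
  if (abs(sum(model$weight) - 1) > 1e-9) abort("Model weights must sum to 1.")
  invisible(model)
}

#' Control-like and knockout-like terminus mixtures
#'
#' Study-condition defaults for a non-polyadenylated RNA whose mature end is
#' `L_m`. The control-like mixture is dominated by the mature terminus with
#' minor single-A, templated-extension and oligo(A) classes; the KO-like
#' mixture (emulating loss of the 3' trimming exonuclease) shifts mass from
#' the mature form to extended and oligoadenylated forms.
#'
#' Control: 0.60 mature (`L_m`, 0); 0.10 single-A (`L_m`, 1); 0.20 spread
#' uniformly over templated extensions `L_m+2 .. L_m+8` (453-459 for hTR);
#' 0.10 spread uniformly over oligo(A) tails a = 2..6 on the mature end.
#' Knockout: 0.30 / 0.15 / 0.35 / 0.20 over the same states.
#'
#' @param L_m Mature end coordinate (default 451).
#' @return A `terminus_model`.
#' @export
control_model <- function(L_m = 451L) {
  mixture_model(L_m, mature = 0.60, single_a = 0.10, extension = 0.20, oligo_a = 0.10)
}

#' @rdname control_model
#' @export
knockout_model <- function(L_m = 451L) {
  mixture_model(L_m, mature = 0.30, single_a = 0.15, extension = 0.35, oligo_a = 0.20)
}

#' @rdname control_model
#' @param mature,single_a,extension,oligo_a Class weights (normalised).
#' @export
mixture_model <- function(L_m = 451L, mature = 0.6, single_a = 0.1,
                          extension = 0.2, oligo_a = 0.1) {
  L_m <- as.integer(L_m)
  ext_ends <- (L_m + 2L):(L_m + 8L)
  oligo_a_len <- 2:6
  terminus_model(
    genomic_end = c(L_m, L_m, ext_ends, rep(L_m, length(oligo_a_len))),
    a_tail = c(0L, 1L, rep(0L, length(ext_ends)), oligo_a_len),
    weight = c(mature, single_a,
               rep(extension / length(ext_ends), length(ext_ends)),
               rep(oligo_a / length(oligo_a_len), length(oligo_a_len)))
  )
}

#' Sample terminus states from a mixture model
#'
#' @param model A `terminus_model`.
#' @param n Number of states to draw.
#' @param seed Optional integer seed (deterministic draw).
#' @return Tibble with columns `genomic_end`, `a_tail`, one row per draw.
#' @export
sample_termini <- function(model, n, seed = NULL) {
  validate_terminus_model(model)
  if (n < 0) abort("n must be >= 0.")
  if (n == 0) return(tibble(genomic_end = integer(), a_tail = integer()))
  idx <- with_seed_if(seed,
    sample.int(nrow(model), n, replace = TRUE, prob = model$weight))
  tibble(genomic_end = model$genomic_end[idx], a_tail = model$a_tail[idx])
}
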