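#' Two-rate 3'->5' trimming model
#'
#' A minimal kinetic model of a processive deadenylase/exonuclease: removal
#' of the current 3'-terminal base is an exponential event with rate `k_A`
#' (per minute) when that base is an adenosine and `k_N` otherwise. Fast
#' deadenylation with slow exonucleolytic processing corresponds to
#' `k_A >> k_N`. Enzyme concentration is absorbed into the rates; there is
#' no sequence-context or length dependence and no saturation.
#'
#' @param k_A Removal rate for a 3'-terminal A (events/min), >= 0.
#' @param k_N Removal rate for a 3'-terminal non-A base, >= 0.
#' @param duration Reaction time in minutes (default 60, the standard
#'   in vitro digestion time).
#' @param floor Minimum retained position (protected core; trimming never
#'   proceeds past it).
#' @return A list of class `trimming_model`.
#' @export
trimming_model <- function(k_A, k_N, duration = 60, floor = 1L) {
  if (k_A < 0 || k_N < 0) abort("Rates must be >= 0.")
  if (duration < 0) abort("duration must be >= 0.")
  if (floor < 1) abort("floor must be >= 1.")
  structure(list(k_A = k_A, k_N = k_N, duration = duration,
                 floor = as.integer(floor)),
            class = "trimming_model")
}

#' Construct a digestion substrate
#'
#' A substrate is an RNA (represented in DNA alphabet) with an explicit 3'
#' end: templated reference sequence through `genomic_end` plus an
#' `a_tail`-adenosine tail. The classic design is the mature sequence plus
#' an 8-nt templated extension plus 7 adenosines
#' (`race_substrate(ref, ref$L_m + 8, 7)`, an hTR-459-7A analogue).
#'
#' @param ref A `reference_locus`.
#' @param genomic_end Last templated position.
#' @param a_tail Number of terminal adenosines.
#' @return A list of class `substrate` with `seq`, `genomic_end`, `a_tail`.
#' @export
race_substrate <- function(ref, genomic_end, a_tail) {
  g <- as.integer(genomic_end)
  a <- as.integer(a_tail)
  if (g < 1 || g > ref$L_m + ref$D) abort("genomic_end outside the reference window.")
  if (a < 0) abort("a_tail must be >= 0.")
  structure(list(seq = paste0(substring(ref_seq(ref), 1L, g), strrep("A", a)),
                 genomic_end = g, a_tail = a),
            class = "substrate")
}

#' Simulate stochastic 3'->5' digestion of a substrate population
#'
#' Exact continuous-time simulation: for each molecule, waiting times for
#' successive single-base removals are drawn as independent exponentials
#' whose rate is `k_A` or `k_N` according to the identity of the current
#' 3'-terminal base; trimming stops when the cumulative time exceeds
#' `duration` or the position reaches `floor`. Because the base removed at
#' each step is determined by the sequence, the per-step rates form a fixed
#' schedule and the simulation vectorises across molecules.
#'
#' @param substrate A `substrate` (or any list with a `seq` string).
#' @param model A `trimming_model`.
#' @param n_molecules Number of molecules, >= 1.
#' @param seed Optional integer seed (deterministic).
#' @return Tibble of class `digestion_distribution` with columns
#'   `end_position`, `n`; attributes `n_molecules`, `boundary` (the
#'   substrate's genomic end, if known), `full_length`.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' sub <- race_substrate(ref, ref$L_m + 8, 7)
#' simulate_digestion(sub, trimming_model(2, 0.02), 1000, seed = 7)
simulate_digestion <- function(substrate, model, n_molecules, seed = NULL) {
  if (n_molecules < 1) abort("n_molecules must be >= 1.")
  len <- nchar(substrate$seq)
  if (len <= model$floor) abort("Substrate must be longer than the floor.")
  bases <- strsplit(substrate$seq, "", fixed = TRUE)[[1]]
  k_max <- len - model$floor
  # rate schedule: step k removes the base at position len - k + 1
  rates <- ifelse(bases[len - seq_len(k_max) + 1L] == "A", model$k_A, model$k_N)
  removed <- with_seed_if(seed, {
    cum <- numeric(n_molecules)
    rem <- integer(n_molecules)
    for (k in seq_len(k_max)) {
      alive <- cum <= model$duration
      if (!any(alive)) break
      if (rates[k] == 0) {
        cum[alive] <- Inf
        next
      }
      cum[alive] <- cum[alive] + stats::rexp(sum(alive), rates[k])
      rem <- rem + (cum <= model$duration)
    }
    rem
  })
  ends <- len - removed
  tab <- dplyr::count(tibble(end_position = as.integer(ends)),
                      .data$end_position, name = "n")
  structure(tab,
            n_molecules = as.integer(n_molecules),
            boundary = substrate$genomic_end %||% NA_integer_,
            full_length = len,
            floor = model$floor,
            class = c("digestion_distribution", class(tab)))
}

#' Probability that an a-base adenosine tail is fully removed by time t
#'
#' With `k_N = 0`, A removals form a Poisson process of rate `k_A`, so the
#' probability that all `a` tail adenosines are gone by time `t` is the
#' upper Poisson tail `P(Poisson(k_A t) >= a)`. This is the closed-form
#' companion to [simulate_digestion()]: in the `k_N = 0` limit it equals the
#' simulated fraction of molecules reaching the A/non-A boundary.
#'
#' @param k_A Deadenylation rate (events/min), >= 0.
#' @param t Time in minutes, >= 0.
#' @param a Tail length in adenosines, >= 0.
#' @return A probability.
#' @export
#' @examples
#' deadenylation_tail_cdf(7 / 60, 60, 7)
deadenylation_tail_cdf <- function(k_A, t, a) {
  if (k_A < 0 || t < 0 || a < 0) abort("Arguments must be non-negative.")
  if (a == 0) return(1)
  stats::ppois(a - 1, lambda = k_A * t, lower.tail = FALSE)
}

#' Turn a digestion distribution into a synthetic 3' RACE library
#'
#' Maps each final end position back to a terminus state using the
#' substrate's template boundary (ends inside the original A tail become
#' non-templated-A states on the substrate's genomic end; ends at or below
#' it are fully templated) and emits one read per molecule, so the library's
#' terminus mixture equals the digestion output exactly. This bridges the
#' kinetic simulator to the sequencing classifier for end-to-end analyses of
#' in vitro digests.
#'
#' @param distribution A `digestion_distribution` whose substrate boundary
#'   is known.
#' @param ref The `reference_locus` the substrate was built from.
#' @param cfg A `library_config` (its `n_reads` is ignored; one read per
#'   molecule is emitted).
#' @param seed Optional integer seed.
#' @return A `race_library` tibble.
#' @export
digest_to_library <- function(distribution, ref, cfg = library_config(),
                              seed = NULL) {
  if (nrow(distribution) == 0) abort("Empty digestion distribution.")
  boundary <- attr(distribution, "boundary")
  if (is.na(boundary)) abort("The distribution's substrate boundary is unknown.")
  ends <- rep(distribution$end_position, distribution$n)
  states <- tibble(
    genomic_end = as.integer(pmin(ends, boundary)),
    a_tail = as.integer(pmax(ends - boundary, 0L))
  )
  out <- with_seed_if(seed, sim_reads_from_states(ref, states, cfg))
  class(out) <- c("race_library", class(out))
  out
}
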