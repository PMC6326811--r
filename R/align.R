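#' Anchored read-retention policy
#'
#' The retention rule for 3' RACE reads: a read must place gaplessly on the
#' reference with its first base matching exactly and at most one mismatch
#' across the 19-nt anchor (the first base plus the following 18), with no
#' insertions or deletions. Gapless placement enforces the no-indel clause
#' by construction.
#'
#' @param anchor_len Anchor length in bases (default 19).
#' @param max_anchor_mismatch Mismatch budget inside the anchor (default 1).
#' @param first_base_exact Require the first insert base to match (default TRUE).
#' @param allow_indels Kept for completeness; must be FALSE (placement is
#'   gapless).
#' @return A list of class `anchor_policy`.
#' @export
anchor_policy <- function(anchor_len = 19L, max_anchor_mismatch = 1L,
                          first_base_exact = TRUE, allow_indels = FALSE) {
  if (anchor_len < 1) abort("anchor_len must be >= 1.")
  if (max_anchor_mismatch >= anchor_len) {
    abort("max_anchor_mismatch must be < anchor_len.")
  }
  if (isTRUE(allow_indels)) abort("Gapless placement cannot allow indels.")
  structure(
    list(anchor_len = as.integer(anchor_len),
         max_anchor_mismatch = as.integer(max_anchor_mismatch),
         first_base_exact = isTRUE(first_base_exact),
         allow_indels = FALSE),
    class = "anchor_policy"
  )
}

# Gapless placement core on integer-coded sequences. Evaluates every
# candidate start, minimising anchor mismatches, ties broken by total
# mismatches over the insert (positions overhanging the reference count as
# mismatches), then by smallest start.
place_gapless_int <- function(ins, ref_int, anchor_len, candidate_starts) {
  L <- length(ref_int)
  li <- length(ins)
  if (li < anchor_len) {
    return(list(start = NA_integer_, anchor_mismatches = NA_integer_,
                total_mismatches = NA_integer_, first_base_match = NA,
                rejected_short = TRUE))
  }
  lo <- max(1L, candidate_starts[1])
  hi <- min(candidate_starts[2], L - anchor_len + 1L)
  if (hi < lo) abort("No candidate start allows full anchor coverage.")
  starts <- lo:hi
  amm <- integer(length(starts))
  for (k in seq_len(anchor_len)) {
    amm <- amm + (ref_int[starts + k - 1L] != ins[k])
  }
  best <- which(amm == min(amm))
  if (length(best) > 1L) {
    tot <- vapply(starts[best], function(s) total_mismatches_int(ins, ref_int, s),
                  integer(1))
    best <- best[tot == min(tot)]
  }
  s <- starts[best[1L]]
  list(start = s,
       anchor_mismatches = amm[match(s, starts)],
       total_mismatches = total_mismatches_int(ins, ref_int, s),
       first_base_match = ins[1L] == ref_int[s],
       rejected_short = FALSE)
}

total_mismatches_int <- function(ins, ref_int, s) {
  idx <- s + seq_along(ins) - 1L
  inside <- idx <= length(ref_int)
  sum(ins[inside] != ref_int[idx[inside]]) + sum(!inside)
}

#' Place an insert gaplessly on the reference
#'
#' @param insert Insert sequence (linker removed).
#' @param ref A `reference_locus`.
#' @param candidate_starts Length-2 interval of allowed reference starts;
#'   `NULL` scans the whole window.
#' @param policy An `anchor_policy` (supplies the anchor length used for
#'   scoring).
#' @return A one-row tibble: `start`, `anchor_mismatches`,
#'   `total_mismatches`, `first_base_match`, `rejected_short`.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' place_gapless(substring(ref_seq(ref), 401, 451), ref)
place_gapless <- function(insert, ref, candidate_starts = NULL,
                          policy = anchor_policy()) {
  cand <- candidate_starts %||% c(1L, ref$L_m + ref$D)
  res <- place_gapless_int(chars_to_int(insert), chars_to_int(ref_seq(ref)),
                           policy$anchor_len, as.integer(cand))
  as_tibble(res)
}

#' Apply the anchored retention filter
#'
#' A placement passes iff the first insert base matches the reference at the
#' start (when `first_base_exact`), the anchor carries at most
#' `max_anchor_mismatch` mismatches, and the placement is gapless (always
#' true here). Short or unplaceable inserts fail.
#'
#' @param aln A placement row from [place_gapless()] (or a tibble of them).
#' @param policy An `anchor_policy`.
#' @return Logical pass flag(s).
#' @export
apply_filter <- function(aln, policy = anchor_policy()) {
  pass <- !aln$rejected_short &
    aln$anchor_mismatches <= policy$max_anchor_mismatch
  if (policy$first_base_exact) pass <- pass & aln$first_base_match
  pass & !is.na(pass)
}

#' Align a table of inserts and apply the retention filter
#'
#' @param inserts Tibble from [preprocess_reads()] (columns `read_id`,
#'   `seq`, `junction_found`).
#' @param ref A `reference_locus`.
#' @param policy An `anchor_policy`.
#' @param candidate_starts Optional length-2 start interval (defaults to the
#'   whole reference window).
#' @return `inserts` with columns `start`, `anchor_mismatches`,
#'   `total_mismatches`, `pass` appended. Reads shorter than the anchor get
#'   `pass = FALSE` with `NA` placement.
#' @export
align_inserts <- function(inserts, ref, policy = anchor_policy(),
                          candidate_starts = NULL) {
  cand <- as.integer(candidate_starts %||% c(1L, ref$L_m + ref$D))
  ref_int <- chars_to_int(ref_seq(ref))
  res <- purrr::map(inserts$seq, function(s) {
    place_gapless_int(chars_to_int(s), ref_int, policy$anchor_len, cand)
  })
  out <- dplyr::bind_cols(
    inserts,
    tibble(
      start = purrr::map_int(res, "start"),
      anchor_mismatches = purrr::map_int(res, "anchor_mismatches"),
      total_mismatches = purrr::map_int(res, "total_mismatches"),
      rejected_short = purrr::map_lgl(res, "rejected_short"),
      first_base_match = purrr::map_lgl(res, "first_base_match")
    )
  )
  out$pass <- apply_filter(out, policy)
  out
}
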