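TERMINUS_CATEGORIES <- c("GENOMIC", "SINGLE_A_452", "OLIGO_A", "MONO_A",
                         "NON_A_TAIL", "UNCLASSIFIED")

#' Decompose an insert's 3' end into templated position and tail
#'
#' Maximal templated matching: the genomic end `g` is the largest reference
#' position such that the insert matches `reference(start..g)` with no
#' mismatches beyond the anchor region (a configurable budget, default 0 —
#' the first post-anchor mismatch terminates the extension). The remaining
#' insert suffix is the non-templated tail. Added adenosines that coincide
#' with genomic A's are absorbed into the templated segment, which is what
#' makes a single A at the mature+1 position ambiguous when that reference
#' base is 'A'.
#'
#' @param insert Insert sequence.
#' @param start Reference start of the placement.
#' @param ref A `reference_locus`.
#' @param anchor_len Anchor length (mismatches inside it were already
#'   budgeted by the filter and do not stop the extension).
#' @param ext_mismatch_budget Post-anchor mismatches tolerated inside the
#'   templated segment (default 0). With a positive budget the extension
#'   must still end on a matching base, so an absorbed mismatch is never
#'   the terminal templated position.
#' @return List with `genomic_end` and `tail`.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)  # base 452 is 'A'
#' ins <- paste0(substring(ref_seq(ref), 401, 451), "AAAA")
#' decompose_terminus(ins, 401, ref)  # g = 452, tail = "AAA"
decompose_terminus <- function(insert, start, ref, anchor_len = 19L,
                               ext_mismatch_budget = 0L) {
  ins <- chars_to_int(insert)
  ref_int <- chars_to_int(ref_seq(ref))
  li <- length(ins)
  if (li < anchor_len) abort("Insert shorter than the anchor cannot be decomposed.")
  if (start < 1 || start > length(ref_int)) abort("Degenerate call: start outside the reference.")
  tlen <- anchor_len
  if (li > anchor_len) {
    idx <- start + anchor_len:(li - 1L)
    inside <- idx <= length(ref_int)
    mism <- rep(TRUE, li - anchor_len)
    mism[inside] <- ins[(anchor_len + 1L):li][inside] != ref_int[idx[inside]]
    # extension may absorb up to the budget of mismatches but must end on a
    # match, so an absorbed error never becomes the terminal templated base
    ok <- which(cumsum(mism) <= ext_mismatch_budget & !mism)
    if (length(ok)) tlen <- anchor_len + max(ok)
  }
  list(genomic_end = start + tlen - 1L,
       tail = substr(insert, tlen + 1L, li))
}

#' Assign the terminus category
#'
#' Categories follow the standard presentation of 3' RACE terminus
#' distributions for a non-polyadenylated RNA with mature end `L_m`:
#' * `GENOMIC` — fully templated terminus (no tail).
#' * `SINGLE_A_452` — terminus at `L_m + 1` ending in a single adenosine,
#'   templated or added; when the reference base at `L_m + 1` is 'A' the two
#'   origins are indistinguishable and are deliberately merged here.
#' * `OLIGO_A` — all-A non-templated tail of length >= 2. With
#'   `a_run_mode = TRUE`, a single non-templated A whose terminal A-run
#'   crosses the template boundary with total run >= 2 also counts.
#' * `MONO_A` — exactly one non-templated A, not at `L_m + 1`.
#' * `NON_A_TAIL` — tail containing a non-A base.
#'
#' @param genomic_end,tail A decomposition from [decompose_terminus()].
#' @param L_m Mature end coordinate.
#' @param ref A `reference_locus` (for terminal-base and A-run lookups).
#' @param a_run_mode Count boundary-straddling A-runs >= 2 as `OLIGO_A`
#'   (default FALSE: only strictly non-templated length counts).
#' @return A category string.
#' @export
categorize <- function(genomic_end, tail, L_m, ref, a_run_mode = FALSE) {
  tl <- nchar(tail)
  end <- genomic_end + tl
  terminal <- if (tl > 0) substr(tail, tl, tl) else ref_base(ref, genomic_end)
  tail_all_a <- tl > 0 && grepl("^A+$", tail)
  if (end == L_m + 1L && terminal == "A" && tl <= 1L) return("SINGLE_A_452")
  if (tail_all_a && tl >= 2L) return("OLIGO_A")
  if (tail_all_a && tl == 1L) {
    if (a_run_mode && genomic_end >= 1 && ref_base(ref, genomic_end) == "A") {
      return("OLIGO_A")
    }
    return("MONO_A")
  }
  if (tl == 0L) return("GENOMIC")
  if (grepl("[^A]", tail)) return("NON_A_TAIL")
  "UNCLASSIFIED"
}

#' Call termini for all passing inserts
#'
#' Decomposes and categorises every aligned insert that passed the retention
#' filter and has an observed linker junction. Other reads are excluded and
#' tallied in the `qc` attribute.
#'
#' With `error_tolerant = TRUE` (the default), a read whose strict
#' (zero-budget) decomposition leaves a tail that is not pure adenosine is
#' re-decomposed with a one-mismatch budget, and the relaxed result is kept
#' only if it yields a clean (empty or all-A) tail. Error-free reads are
#' therefore decomposed exactly as under the strict rule, while an isolated
#' substitution error inside the templated segment is absorbed instead of
#' fabricating a spurious non-A tail.
#'
#' @param aligned Tibble from [align_inserts()] (needs `seq`, `start`,
#'   `pass`, `junction_found`).
#' @param ref A `reference_locus`.
#' @param policy The `anchor_policy` used for alignment.
#' @param ext_mismatch_budget See [decompose_terminus()].
#' @param error_tolerant Absorb an isolated post-anchor mismatch when doing
#'   so cleans the tail (see Details).
#' @param a_run_mode See [categorize()].
#' @return Tibble of class `terminus_calls`: `read_id`, `genomic_end`,
#'   `tail`, `tail_a` (`NA` unless the tail is all-A), `end_position`,
#'   `category`. Attribute `qc` tallies excluded reads.
#' @export
classify_termini <- function(aligned, ref, policy = anchor_policy(),
                             ext_mismatch_budget = 0L, error_tolerant = TRUE,
                             a_run_mode = FALSE) {
  keep <- aligned$pass & aligned$junction_found
  qc <- c(n_reads = nrow(aligned),
          n_no_junction = sum(!aligned$junction_found),
          n_filter_fail = sum(aligned$junction_found & !aligned$pass),
          n_called = sum(keep))
  kept <- aligned[keep, , drop = FALSE]
  dec <- purrr::map2(kept$seq, kept$start, function(s, st) {
    d <- decompose_terminus(s, st, ref, anchor_len = policy$anchor_len,
                            ext_mismatch_budget = ext_mismatch_budget)
    if (error_tolerant && grepl("[^A]", d$tail)) {
      d1 <- decompose_terminus(s, st, ref, anchor_len = policy$anchor_len,
                               ext_mismatch_budget = ext_mismatch_budget + 1L)
      if (!grepl("[^A]", d1$tail)) d <- d1
    }
    d
  })
  g <- purrr::map_int(dec, "genomic_end")
  tail <- purrr::map_chr(dec, "tail")
  cat <- purrr::map2_chr(g, tail, categorize, L_m = ref$L_m, ref = ref,
                         a_run_mode = a_run_mode)
  out <- tibble(
    read_id = kept$read_id,
    genomic_end = g,
    tail = tail,
    tail_a = ifelse(grepl("^A*$", tail), nchar(tail), NA_integer_),
    end_position = g + nchar(tail),
    category = factor(cat, levels = TERMINUS_CATEGORIES)
  )
  attr(out, "qc") <- qc
  attr(out, "L_m") <- ref$L_m
  class(out) <- c("terminus_calls", class(out))
  out
}

#' Tabulate terminus calls into a category table
#'
#' Counts calls by (end position, category) and expresses them as
#' percentages of the denominator: all passing, junction-found inserts (the
#' fragments whose 3' terminus was observed). Prematurely trimmed ends
#' (positions below `L_m`) are included and reported by position.
#'
#' @param calls A `terminus_calls` tibble (one condition).
#' @param L_m Mature end coordinate (defaults to the calls' attribute).
#' @return Tibble of class `category_table` with columns `end_position`,
#'   `category`, `n`, `pct`; attributes `denominator`, `L_m`.
#' @export
summarize_termini <- function(calls, L_m = attr(calls, "L_m")) {
  if (is.null(L_m)) abort("L_m is required.")
  denom <- nrow(calls)
  tab <- tibble(end_position = calls$end_position, category = calls$category) |>
    dplyr::count(.data$end_position, .data$category, name = "n") |>
    dplyr::mutate(pct = if (denom > 0) 100 * .data$n / denom else numeric(nrow(calls))) |>
    dplyr::arrange(.data$end_position, .data$category)
  structure(tab, denominator = denom, L_m = as.integer(L_m),
            class = c("category_table", class(tab)))
}

#' Mature fraction of a category table
#'
#' Share of fragments ending exactly at the mature position with a fully
#' templated (genomic) terminus, in percent.
#'
#' @param table A `category_table`.
#' @return A percentage.
#' @export
mature_pct <- function(table) {
  L_m <- attr(table, "L_m")
  sum(table$pct[table$end_position == L_m & table$category == "GENOMIC"])
}

category_pct <- function(table) {
  table |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = sum(.data$n), pct = sum(.data$pct), .groups = "drop") |>
    tidyr::complete(category = factor(TERMINUS_CATEGORIES,
                                      levels = TERMINUS_CATEGORIES),
                    fill = list(n = 0L, pct = 0))
}

#' Contrast two conditions' terminus distributions
#'
#' Per-category percentage differences (`pct_a - pct_b`) and ratios between
#' two category tables, plus the mature-fraction difference. Calling it as
#' `contrast_conditions(ko, control)` reports the knockout shift: a negative
#' mature delta with a positive oligo(A) delta flags the characteristic
#' loss-of-trimming pattern (mature down, extended/oligoadenylated up).
#'
#' @param table_a,table_b `category_table`s (e.g. knockout and control).
#' @return Tibble of class `terminus_contrast` with columns `category`,
#'   `pct_a`, `pct_b`, `delta_pct`, `ratio`; attributes `mature_delta` and
#'   `shift_mature_down_oligo_up`.
#' @export
contrast_conditions <- function(table_a, table_b) {
  if (attr(table_a, "denominator") == 0 || attr(table_b, "denominator") == 0) {
    abort("Undefined contrast: a table has denominator 0.")
  }
  a <- category_pct(table_a)
  b <- category_pct(table_b)
  out <- dplyr::inner_join(a, b, by = "category", suffix = c("_a", "_b")) |>
    dplyr::transmute(
      .data$category,
      pct_a = .data$pct_a, pct_b = .data$pct_b,
      delta_pct = .data$pct_a - .data$pct_b,
      ratio = ifelse(.data$pct_b > 0, .data$pct_a / .data$pct_b, NA_real_)
    )
  mature_delta <- mature_pct(table_a) - mature_pct(table_b)
  oligo_delta <- out$delta_pct[out$category == "OLIGO_A"]
  structure(out,
            mature_delta = mature_delta,
            oligo_a_delta = oligo_delta,
            shift_mature_down_oligo_up = mature_delta < 0 && oligo_delta > 0,
            class = c("terminus_contrast", class(out)))
}

#' End-to-end terminus profiling of a read table
#'
#' Convenience pipeline: preprocess (linker removal, optional masking),
#' anchored alignment + retention filter, terminus calling. Returns the
#' calls; pipe into [summarize_termini()] for the category table.
#'
#' @param reads Tibble with `read_id`, `seq` (and `qual` if masking).
#' @param ref A `reference_locus`.
#' @param linker Linker sequence.
#' @param policy An `anchor_policy`.
#' @param mask Apply quality/complexity masking (default FALSE for
#'   plain-sequence inputs).
#' @param candidate_starts Optional alignment start interval.
#' @param ... Passed to [classify_termini()].
#' @return A `terminus_calls` tibble.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' lib <- simulate_library(ref, control_model(),
#'                         library_config(n_reads = 50, err_rate = 0), seed = 2)
#' calls <- call_termini(lib, ref)
#' summarize_termini(calls)
call_termini <- function(reads, ref, linker = default_linker(),
                         policy = anchor_policy(), mask = FALSE,
                         candidate_starts = NULL, ...) {
  reads |>
    preprocess_reads(linker = linker, mask = mask) |>
    align_inserts(ref = ref, policy = policy,
                  candidate_starts = candidate_starts) |>
    classify_termini(ref = ref, policy = policy, ...)
}
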