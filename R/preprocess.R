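#' Locate the ligated linker in a read
#'
#' Scans every offset of the read for a gapless match to a *prefix* of the
#' linker (the linker may run off the read's 3' end). Returns the smallest
#' 1-based index of the first linker base such that the overlap is at least
#' `min_overlap` and the mismatch fraction over the overlap is at most
#' `max_mismatch_frac`; `NA` if no offset qualifies. The insert is
#' `read[1..j-1]`, whose last base is the observed RNA 3' terminus.
#'
#' @param read A single read sequence.
#' @param linker Linker sequence (>= 15 nt).
#' @param max_mismatch_frac Maximum mismatch fraction over the overlap.
#' @param min_overlap Minimum read/linker overlap in bases.
#' @return Integer junction index, or `NA_integer_`.
#' @export
#' @examples
#' locate_linker(paste0("ACGTACGTAC", default_linker()), default_linker())
locate_linker <- function(read, linker, max_mismatch_frac = 0.1,
                          min_overlap = 10L) {
  if (nchar(linker) < 15) abort("linker must be >= 15 nt.")
  locate_linker_int(chars_to_int(read), chars_to_int(linker),
                    max_mismatch_frac, min_overlap)
}

# integer-coded core; loops over linker positions (short) vectorised over
# read offsets (long)
locate_linker_int <- function(rd, lk, max_mismatch_frac, min_overlap) {
  n <- length(rd)
  k <- length(lk)
  last_j <- n - min_overlap + 1L
  if (last_j < 1L) return(NA_integer_)
  js <- seq_len(last_j)
  mm <- integer(last_j)
  for (i in seq_len(min(k, n))) {
    idx <- js + i - 1L
    ok <- idx <= n
    mm[ok] <- mm[ok] + (rd[idx[ok]] != lk[i])
  }
  overlap <- pmin(k, n - js + 1L)
  hit <- overlap >= min_overlap & mm / overlap <= max_mismatch_frac
  if (!any(hit)) return(NA_integer_)
  js[which(hit)[1L]]
}

#' Trim a read to its insert at a linker junction
#'
#' @param read A read sequence.
#' @param junction Index of the first linker base (from [locate_linker()]),
#'   or `NA` if none was found.
#' @return A list with `seq` (the insert; the full read when no junction)
#'   and `junction_found`.
#' @export
trim_to_insert <- function(read, junction) {
  if (is.na(junction)) {
    return(list(seq = read, junction_found = FALSE))
  }
  if (junction <= 1) abort("Empty insert: linker at the very start of the read.")
  if (junction > nchar(read) + 1) abort("Junction outside the read.")
  list(seq = substr(read, 1L, junction - 1L), junction_found = TRUE)
}

#' Mask low-quality and low-complexity bases
#'
#' Replaces with 'N' every base whose phred quality is below `min_phred`,
#' and every base inside a sliding window of `entropy_window` nt whose
#' Shannon entropy (bits, over base frequencies) falls below `entropy_min`.
#' Sequence length never changes; downstream stages count 'N' as a mismatch.
#'
#' @param seq A single sequence.
#' @param qual Its phred+33 quality string (same length).
#' @param min_phred Minimum phred score kept unmasked (default 20).
#' @param entropy_window Sliding window width in nt (default 16).
#' @param entropy_min Minimum window entropy in bits (default 1.0).
#' @return List with `seq` (masked) and `masked_frac`.
#' @export
#' @examples
#' mask_low_quality(strrep("A", 30), strrep("I", 30))$masked_frac  # homopolymer -> 1
mask_low_quality <- function(seq, qual, min_phred = 20L, entropy_window = 16L,
                             entropy_min = 1.0) {
  n <- nchar(seq)
  if (nchar(qual) != n) abort("Quality string length must match the sequence.")
  if (n == 0) return(list(seq = seq, masked_frac = 0))
  mask <- (utf8ToInt(qual) - 33L) < min_phred
  if (n >= entropy_window) {
    ch <- chars_to_int(seq)
    ent <- window_entropy(ch, entropy_window)
    low <- which(ent < entropy_min)
    for (s in low) mask[s:(s + entropy_window - 1L)] <- TRUE
  }
  if (any(mask)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ch[mask] <- "N"
    seq <- paste(ch, collapse = "")
  }
  list(seq = seq, masked_frac = mean(mask))
}

# Shannon entropy (bits) of every length-w window, via per-symbol cumulative
# counts; returns a vector indexed by window start.
window_entropy <- function(ch, w) {
  n <- length(ch)
  syms <- unique(ch)
  starts <- seq_len(n - w + 1L)
  h <- numeric(length(starts))
  for (s in syms) {
    cs <- c(0L, cumsum(ch == s))
    cnt <- cs[starts + w] - cs[starts]
    p <- cnt / w
    nz <- p > 0
    h[nz] <- h[nz] - p[nz] * log2(p[nz])
  }
  h
}

#' Preprocess a read table into inserts
#'
#' For each read: locate the linker, trim to the insert, and optionally mask
#' low-quality/low-complexity bases of the insert. Reads without a detected
#' junction are retained with `junction_found = FALSE`; their 3' boundary is
#' unobserved, so downstream terminus calling excludes them (they appear in
#' the QC tally, not in the percentage denominator).
#'
#' @param reads Tibble with columns `read_id`, `seq` and (if masking)
#'   `qual` — e.g. a `race_library` or the result of [read_race_fastq()].
#' @param linker Linker sequence.
#' @param max_mismatch_frac,min_overlap Linker-matching tolerances.
#' @param mask Apply [mask_low_quality()] to each insert.
#' @param min_phred,entropy_window,entropy_min Masking parameters.
#' @return Tibble with columns `read_id`, `seq` (insert), `junction_found`,
#'   `masked_frac`.
#' @export
preprocess_reads <- function(reads, linker = default_linker(),
                             max_mismatch_frac = 0.1, min_overlap = 10L,
                             mask = TRUE, min_phred = 20L,
                             entropy_window = 16L, entropy_min = 1.0) {
  if (nchar(linker) < 15) abort("linker must be >= 15 nt.")
  lk <- chars_to_int(linker)
  juncs <- vapply(reads$seq, function(s) {
    locate_linker_int(chars_to_int(s), lk, max_mismatch_frac, min_overlap)
  }, integer(1), USE.NAMES = FALSE)
  found <- !is.na(juncs)
  ins <- ifelse(found, substr(reads$seq, 1L, ifelse(found, juncs, 2L) - 1L),
                reads$seq)
  masked_frac <- rep(0, nrow(reads))
  if (mask) {
    if (is.null(reads$qual)) abort("Masking requires a `qual` column.")
    qual_ins <- ifelse(found, substr(reads$qual, 1L, ifelse(found, juncs, 2L) - 1L),
                       reads$qual)
    for (i in seq_along(ins)) {
      m <- mask_low_quality(ins[i], qual_ins[i], min_phred, entropy_window,
                            entropy_min)
      ins[i] <- m$seq
      masked_frac[i] <- m$masked_frac
    }
  }
  tibble(read_id = reads$read_id, seq = ins, junction_found = found,
         masked_frac = masked_frac)
}
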