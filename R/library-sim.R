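#' The universal RT primer and default linker
#'
#' In ligation-mediated 3' RACE a linker is ligated to the RNA 3' end and
#' reverse-transcribed from a linker-complementary primer, so each read's
#' insert/linker junction marks the RNA's exact 3' terminus. The ligated
#' linker appears in the read as the reverse complement of the universal RT
#' primer (5'-CTACGTAACGATTGATGGTGCCTACAG).
#'
#' @return A single DNA string.
#' @export
rt_primer_r1 <- function() "CTACGTAACGATTGATGGTGCCTACAG"

#' @rdname rt_primer_r1
#' @export
default_linker <- function() revcomp(rt_primer_r1())

#' Library simulation configuration
#'
#' @param read_len Read length in bases (default 250, MiSeq 2x250 style).
#' @param paired Also emit a reverse-complement mate read (default FALSE:
#'   single already-merged fragments, which isolate the classification
#'   logic; mate merging of the real data is not modelled).
#' @param err_rate Per-base substitution probability, in `[0, 0.1)`.
#' @param linker_seq Ligated linker as it appears in the read (>= 15 nt).
#' @param fragment_start_window Length-2 integer vector: inserts begin
#'   uniformly in this reference interval. `NULL` means `[L_m-70, L_m-30]`,
#'   resolved at simulation time.
#' @param n_reads Number of reads.
#' @param phred Constant base quality (phred scale) written to FASTQ.
#' @return A list of class `library_config`.
#' @export
library_config <- function(read_len = 250L, paired = FALSE, err_rate = 0.003,
                           linker_seq = default_linker(),
                           fragment_start_window = NULL,
                           n_reads = 1000L, phred = 37L) {
  if (err_rate < 0 || err_rate >= 0.1) abort("err_rate must be in [0, 0.1).")
  if (read_len < 50) abort("read_len must be >= 50.")
  if (nchar(linker_seq) < 15) abort("linker_seq must be >= 15 nt.")
  if (!is.null(fragment_start_window) &&
      (length(fragment_start_window) != 2 ||
       fragment_start_window[1] > fragment_start_window[2])) {
    abort("fragment_start_window must be an increasing length-2 interval.")
  }
  structure(
    list(read_len = as.integer(read_len), paired = isTRUE(paired),
         err_rate = err_rate, linker_seq = toupper(linker_seq),
         fragment_start_window = fragment_start_window,
         n_reads = as.integer(n_reads), phred = as.integer(phred)),
    class = "library_config"
  )
}

#' Construct one amplicon fragment
#'
#' The fragment is `reference(start..g) + A^a + linker`: the templated RNA
#' segment ending at the genomic end `g`, the non-templated adenosine tail,
#' then the ligated linker. The linker junction (index of the first linker
#' base) is `g - start + 1 + a + 1`; the insert length is `g - start + 1 + a`.
#'
#' @param ref A `reference_locus`.
#' @param genomic_end Last templated reference position `g`.
#' @param a_tail Non-templated A count.
#' @param start Reference position of the fragment's first base.
#' @param linker_seq Ligated linker sequence.
#' @return A single DNA string.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' frag <- make_fragment(ref, 451, 0, start = 401)
#' nchar(frag) == 51 + nchar(default_linker())
make_fragment <- function(ref, genomic_end, a_tail, start,
                          linker_seq = default_linker()) {
  g <- as.integer(genomic_end)
  a <- as.integer(a_tail)
  if (g < start) abort("genomic_end must be >= fragment start.")
  if (g > ref$L_m + ref$D) abort("genomic_end beyond the reference window.")
  if (a < 0) abort("a_tail must be >= 0.")
  paste0(substring(ref_seq(ref), start, g), strrep("A", a), linker_seq)
}

# Core: turn a table of (genomic_end, a_tail) states into reads. All
# randomness (starts, pad bases, errors) happens inside the caller's seed
# scope so fixed seeds give byte-identical libraries.
sim_reads_from_states <- function(ref, states, cfg) {
  n <- nrow(states)
  win <- cfg$fragment_start_window %||% c(ref$L_m - 70L, ref$L_m - 30L)
  starts <- if (win[1] == win[2]) rep(win[1], n) else
    sample(win[1]:win[2], n, replace = TRUE)
  if (any(states$genomic_end < starts)) {
    abort("fragment_start_window extends beyond a sampled genomic end.")
  }
  full <- ref_seq(ref)
  frags <- paste0(substring(full, starts, states$genomic_end),
                  strrep("A", states$a_tail), cfg$linker_seq)
  rl <- cfg$read_len
  # pad short fragments with random bases (downstream sequencing adapter
  # stand-in), truncate long ones
  need <- pmax(0L, rl - nchar(frags))
  pad <- vapply(need, function(k) {
    if (k == 0) "" else paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
  }, character(1))
  reads <- substr(paste0(frags, pad), 1L, rl)
  if (cfg$err_rate > 0) reads <- add_substitution_errors(reads, cfg$err_rate)
  out <- tibble(
    read_id = sprintf("read_%06d", seq_len(n)),
    seq = reads,
    qual = strrep(intToUtf8(33L + cfg$phred), rl),
    start = as.integer(starts),
    genomic_end = states$genomic_end,
    a_tail = states$a_tail
  )
  if (cfg$paired) out$seq2 <- revcomp(out$seq)
  out
}

# i.i.d. substitutions at rate p; each error replaces the base with one of
# the three other bases uniformly. Equal-length reads -> one char matrix.
add_substitution_errors <- function(reads, p) {
  rl <- unique(nchar(reads))
  stopifnot(length(rl) == 1)
  ch <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
               nrow = rl)
  hit <- which(stats::runif(length(ch)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    code <- match(ch[hit], DNA_BASES)
    ch[hit] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
  }
  apply(ch, 2, paste, collapse = "")
}

#' Simulate a 3' RACE sequencing library with known ground truth
#'
#' Draws terminus states from `model`, builds the amplicon fragments
#' (templated segment + A tail + linker), pads/truncates to the read length,
#' applies i.i.d. substitution errors, and returns reads together with their
#' true terminus states. Deterministic for a fixed seed.
#'
#' @param ref A `reference_locus`.
#' @param model A `terminus_model`.
#' @param cfg A `library_config`.
#' @param seed Optional integer seed.
#' @return A tibble of class `race_library` with columns `read_id`, `seq`,
#'   `qual`, `start`, `genomic_end`, `a_tail` (the last three are ground
#'   truth), and `seq2` if `cfg$paired`.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' lib <- simulate_library(ref, control_model(), library_config(n_reads = 10), seed = 7)
simulate_library <- function(ref, model, cfg = library_config(), seed = NULL) {
  validate_terminus_model(model)
  out <- with_seed_if(seed, {
    states <- sample_termini(model, cfg$n_reads)
    sim_reads_from_states(ref, states, cfg)
  })
  class(out) <- c("race_library", class(out))
  out
}

#' Write a simulated library to FASTQ and its ground truth to TSV
#'
#' @param lib A `race_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  x <- Biostrings::DNAStringSet(lib$seq)
  names(x) <- lib$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(lib$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth_tsv <- function(lib, path) {
  readr::write_tsv(lib[, c("read_id", "genomic_end", "a_tail")], path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file path.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_race_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
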