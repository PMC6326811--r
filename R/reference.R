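#' Build a reference locus for 3' RACE simulation
#'
#' A reference locus is the mature RNA sequence (length `L_m`; for hTR,
#' 451 nt) followed by downstream genomic sequence (length `D`), mirroring
#' the mapping window used for 3' RACE reads: the gene plus its surrounding
#' downstream region. Positions are 1-based; position `L_m` is the last
#' mature base.
#'
#' The true hTR sequence is not bundled; the generator fabricates a random
#' locus so that every downstream stage can be tested against known ground
#' truth. The `first_downstream_A` flag controls the single-A ambiguity at
#' position `L_m + 1` (452 for hTR) in both directions: `TRUE` forces that
#' base to be an adenosine, so a terminus ending in a single A there cannot
#' be assigned as templated versus post-transcriptionally added; `FALSE`
#' forces a non-A base there, which makes every terminus state (including
#' oligo(A) tails, which would otherwise have their first A absorbed into
#' the template) unambiguously recoverable from error-free reads.
#'
#' @param seed Integer seed; the locus is deterministic given the seed.
#' @param L_m Mature RNA length (default 451, the mature hTR length).
#' @param D Downstream genomic window length (default 1000, a 1 kb window).
#' @param gc_frac GC fraction of the random sequence.
#' @param first_downstream_A `TRUE` forces position `L_m + 1` to be 'A'
#'   (ambiguity on); `FALSE` forces it to a non-A base (ambiguity off).
#' @param name Locus name.
#' @return An object of class `reference_locus` with fields `name`,
#'   `mature_seq`, `downstream_seq`, `L_m`, `D`.
#' @export
#' @examples
#' ref <- build_reference(seed = 1)
#' ref_base(ref, 452)  # "A" because first_downstream_A defaults to TRUE
build_reference <- function(seed, L_m = 451L, D = 1000L, gc_frac = 0.5,
                            first_downstream_A = TRUE, name = "synthetic_locus") {
  if (L_m < 19) abort("L_m must be >= 19 (the anchor length).")
  if (D < 1) abort("D must be >= 1.")
  with_seed_if(seed, {
    mature <- random_dna(L_m, gc_frac)
    down <- random_dna(D, gc_frac)
  })
  if (first_downstream_A) {
    substr(down, 1, 1) <- "A"
  } else if (substr(down, 1, 1) == "A") {
    # keep the ambiguity genuinely off; 'T' preserves a gc_frac = 1 downstream
    # only when no A was drawn there in the first place
    substr(down, 1, 1) <- "T"
  }
  structure(
    list(name = name, mature_seq = mature, downstream_seq = down,
         L_m = as.integer(L_m), D = as.integer(D)),
    class = "reference_locus"
  )
}

#' Construct a reference locus from explicit sequences
#'
#' @param mature_seq Mature RNA sequence (DNA alphabet).
#' @param downstream_seq Downstream genomic sequence.
#' @param name Locus name.
#' @return A `reference_locus`.
#' @export
reference_locus <- function(mature_seq, downstream_seq, name = "locus") {
  mature_seq <- toupper(mature_seq)
  downstream_seq <- toupper(downstream_seq)
  if (!is_dna(c(mature_seq, downstream_seq))) {
    abort("Reference sequences must be over {A,C,G,T}.")
  }
  if (nchar(mature_seq) < 19) abort("Mature sequence must be >= 19 nt.")
  if (nchar(downstream_seq) < 1) abort("Downstream sequence must be >= 1 nt.")
  structure(
    list(name = name, mature_seq = mature_seq, downstream_seq = downstream_seq,
         L_m = nchar(mature_seq), D = nchar(downstream_seq)),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s: mature %d nt + downstream %d nt (base %d = %s)\n",
              x$name, x$L_m, x$D, x$L_m + 1L, ref_base(x, x$L_m + 1L)))
  invisible(x)
}

#' Full reference sequence (mature + downstream)
#' @param ref A `reference_locus`.
#' @return A single string of length `L_m + D`.
#' @export
ref_seq <- function(ref) paste0(ref$mature_seq, ref$downstream_seq)

#' Reference base(s) at 1-based position(s)
#' @param ref A `reference_locus`.
#' @param i Positions in `1..(L_m + D)`.
#' @return Character vector of single bases.
#' @export
ref_base <- function(ref, i) {
  if (any(i < 1 | i > ref$L_m + ref$D)) abort("Position outside the reference window.")
  s <- ref_seq(ref)
  substring(s, i, i)
}

#' Write / read a reference locus as FASTA
#'
#' Two records are written (`<name>|mature`, `<name>|downstream`) so the
#' mature-end coordinate survives the round trip.
#'
#' @param ref A `reference_locus`.
#' @param path FASTA file path.
#' @return `path`, invisibly (writer); a `reference_locus` (reader).
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(c(ref$mature_seq, ref$downstream_seq))
  names(x) <- paste0(ref$name, c("|mature", "|downstream"))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  nm <- names(x)
  im <- grep("\\|mature$", nm)
  id <- grep("\\|downstream$", nm)
  if (length(im) != 1 || length(id) != 1) {
    abort("FASTA must contain exactly one '|mature' and one '|downstream' record.")
  }
  reference_locus(as.character(x[[im]]), as.character(x[[id]]),
                  name = sub("\\|mature$", "", nm[im]))
}
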