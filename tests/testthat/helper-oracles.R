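# Independent brute-force oracles. These deliberately use plain character
# vectors and explicit loops, sharing no code with the package's vectorised
# implementations.

chr <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Exhaustive gapless placement: every start, anchor mismatches first, then
# total mismatches over the insert (overhang = mismatch), then smallest start.
oracle_place <- function(insert, ref_string, anchor_len = 19L) {
  ins <- chr(insert)
  ref <- chr(ref_string)
  L <- length(ref)
  li <- length(ins)
  if (li < anchor_len) return(list(rejected_short = TRUE))
  best <- NULL
  for (s in seq_len(L - anchor_len + 1L)) {
    amm <- sum(ins[1:anchor_len] != ref[s:(s + anchor_len - 1L)])
    if (is.null(best) || amm < best$amm) {
      tot <- oracle_total_mm(ins, ref, s)
      best <- list(start = s, amm = amm, tot = tot)
    } else if (amm == best$amm) {
      tot <- oracle_total_mm(ins, ref, s)
      if (tot < best$tot) best <- list(start = s, amm = amm, tot = tot)
    }
  }
  list(start = best$start, anchor_mismatches = best$amm,
       total_mismatches = best$tot,
       first_base_match = ins[1] == ref[best$start],
       rejected_short = FALSE)
}

oracle_total_mm <- function(ins, ref, s) {
  mm <- 0L
  for (i in seq_along(ins)) {
    p <- s + i - 1L
    if (p > length(ref) || ins[i] != ref[p]) mm <- mm + 1L
  }
  mm
}

oracle_pass <- function(o, max_anchor_mismatch = 1L) {
  !isTRUE(o$rejected_short) && o$first_base_match &&
    o$anchor_mismatches <= max_anchor_mismatch
}

# All-offsets linker scan with explicit per-offset loops.
oracle_locate_linker <- function(read, linker, max_mismatch_frac = 0.1,
                                 min_overlap = 10L) {
  rd <- chr(read); lk <- chr(linker)
  for (j in seq_len(length(rd) - min_overlap + 1L)) {
    ov <- min(length(lk), length(rd) - j + 1L)
    mm <- sum(rd[j:(j + ov - 1L)] != lk[1:ov])
    if (ov >= min_overlap && mm / ov <= max_mismatch_frac) return(j)
  }
  NA_integer_
}

# Brute force over all split points: the largest templated length whose
# post-anchor part matches the reference exactly.
oracle_decompose <- function(insert, start, ref_string, anchor_len = 19L) {
  ins <- chr(insert); ref <- chr(ref_string)
  li <- length(ins)
  best <- anchor_len
  for (m in (anchor_len + 1L):li) {
    if (li <= anchor_len) break
    seg <- (anchor_len + 1L):m
    pos <- start + seg - 1L
    if (all(pos <= length(ref)) && all(ins[seg] == ref[pos])) best <- m
  }
  list(genomic_end = start + best - 1L,
       tail = paste(ins[seq_len(li) > best], collapse = ""))
}

# Ground-truth category from a simulated library's true terminus states
# (valid only for ambiguity-free references, i.e. base L_m+1 != 'A').
truth_categories <- function(lib, L_m) {
  ifelse(lib$genomic_end + lib$a_tail == L_m + 1L & lib$a_tail == 1L,
         "SINGLE_A_452",
         ifelse(lib$a_tail >= 2L, "OLIGO_A",
                ifelse(lib$a_tail == 1L, "MONO_A", "GENOMIC")))
}

truth_pct <- function(lib, L_m) {
  tc <- factor(truth_categories(lib, L_m),
               levels = c("GENOMIC", "SINGLE_A_452", "OLIGO_A", "MONO_A",
                          "NON_A_TAIL", "UNCLASSIFIED"))
  100 * table(tc) / nrow(lib)
}

called_pct <- function(tab) {
  p <- tidy(tab)
  stats::setNames(p$pct, as.character(p$category))
}
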