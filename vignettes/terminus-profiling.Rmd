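---
title: "Profiling RNA 3' termini from 3' RACE sequencing, and simulating their trimming kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling RNA 3' termini from 3' RACE sequencing, and simulating their trimming kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raceterm)
library(ggplot2)
```

## The problem

The human telomerase RNA (hTR/TERC) matures into a 451-nt species with no
poly(A) tail. Its nascent transcripts carry genomically encoded 3'
extensions and short non-templated oligo(A) tails, which are removed by
3'→5' deadenylases/exonucleases (PARN, TOE1). Where exactly each transcript
ends — mature 451, a templated extension to 452–459, a single terminal A,
or an oligo(A) tail — is the readout that distinguishes a working
maturation pathway from a broken one.

Ligation-mediated 3' RACE answers this at single-nucleotide resolution: a
linker is ligated to the RNA 3' end, cDNA is primed from the linker, and
the amplicon is sequenced, so the insert/linker junction in each read marks
the transcript's exact 3' terminus. This package implements the complete
downstream analysis of such libraries, a ground-truth simulator for them,
a stochastic model of the trimming kinetics, and the comparative-CT
arithmetic used for the accompanying expression readouts.

## The read model and its processing stages

A read is modelled as

```
[templated segment: reference(start..g)] [A × a] [linker] [filler]
```

where `g` is the last templated reference position and `a` the number of
non-templated adenosines. Processing proceeds in four stages, each an
exported function operating on a tibble:

1. **Linker removal** (`preprocess_reads()`): the linker is located as the
   smallest read offset where a gapless match to a linker *prefix* has at
   least 10 nt of overlap and at most 10% mismatches. These two tolerances
   are not biologically derived; they follow common adaptor-trimming
   practice and are configurable. Reads without a junction keep their full
   sequence but are flagged: their terminus is unobserved, so they are
   excluded from terminus calling and from every percentage denominator
   (they appear in the QC tally instead).
2. **Masking** (`mask_low_quality()`): bases under phred 20, and every
   16-nt window with Shannon entropy below 1 bit, become 'N'. Masking never
   changes sequence length, and 'N' counts as a mismatch everywhere
   downstream — a masked base can only make calls more conservative, never
   fabricate a match.
3. **Anchored placement and retention** (`align_inserts()`): each insert is
   placed gaplessly at every candidate start in the reference window
   (mature sequence + 1 kb downstream by default); the start minimising
   anchor mismatches wins, ties broken by total mismatches, then by
   smallest start. A read is retained iff its first base matches exactly
   and the 19-nt anchor (first base + following 18) carries at most one
   mismatch. Gapless placement enforces "no indels" by construction rather
   than post-filtering a gapped aligner — for the retained class the two
   are equivalent, and the gapless scan is exhaustively testable against a
   brute-force scorer.
4. **Terminus decomposition and categories** (`classify_termini()`,
   `summarize_termini()`): described next.

## Terminus decomposition: templated-first, maximal matching

The decomposition rule is *maximal templated extension*: `g` is the largest
reference position such that the insert matches `reference(start..g)` with
zero post-anchor mismatches; everything after `g` is the non-templated
tail. Templated-first matching means an added A that coincides with a
genomic A is credited to the genome. This is deliberate: when the
reference base at 452 (the mature end + 1) is 'A', a transcript ending in
a single A there is *genuinely* ambiguous — it may be the templated 452
terminus or mature-451 + one added A — and the category scheme absorbs
exactly this ambiguity into its single-A class rather than pretending to
resolve it.

Categories (for mature end `L_m`):

* `GENOMIC` — empty tail;
* `SINGLE_A_452` — total end `L_m + 1`, terminal base A, at most one
  non-templated base (templated or added — the merged ambiguous class);
* `OLIGO_A` — all-A tail, `a >= 2`;
* `MONO_A` — one non-templated A elsewhere; reported separately and never
  merged into `OLIGO_A`, so the oligo(A) class is not silently inflated;
* `NON_A_TAIL` — tail containing a non-A base.

An oligo(A) read is recorded in the position histogram at its *total* end
(`g + |tail|`); the templated/non-templated split is retained in the table.
A terminal A-run that straddles the template boundary (e.g. one added A
after a templated A) is counted `OLIGO_A` only in the optional
`a_run_mode`; the default counts strictly non-templated length, the more
conservative convention.

**Error tolerance.** With strict zero-mismatch extension, a single
sequencing error in the templated segment truncates the extension and
turns the entire downstream remainder into a spurious "tail". At a 0.003
per-base error rate and ~50-nt inserts this would misclassify ~9% of
reads — an order of magnitude above the noise floor of the class
percentages themselves. `classify_termini()` therefore retries a read with
a one-mismatch budget (the extension must still end on a matching base)
*only when* the strict decomposition leaves a tail that is not pure A, and
keeps the relaxed result only if its tail is clean. Error-free reads are
never affected — their decomposition is identical to the strict rule — and
the residual misclassification (errors at the terminal base or inside the
A tail itself) stays below ~0.5 percentage points. Setting
`error_tolerant = FALSE` restores the strict rule everywhere.

The percentage denominator is the number of retained, junction-found
inserts — the fragments whose 3' end was actually observed. Prematurely
trimmed ends (positions below `L_m`) are included and reported by
position.

## The synthetic library generator

The generator exists so that every stage above is testable against known
truth without any external data. Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `L_m`, `D` | 451, 1000 | mature length; downstream mapping window |
| `read_len` | 250 | single merged fragments (see below) |
| `err_rate` | 0.003 | i.i.d. substitutions; no indels |
| `linker_seq` | `CTGTAGGCACCATCAATCGTTACGTAG` | reverse complement of the universal RT primer |
| start window | `[L_m-70, L_m-30]` | where inserts begin (nested-primer region) |
| control mixture | 0.60 / 0.10 / 0.20 / 0.10 | mature / single-A / extensions 453–459 / oligo(A) a = 2–6 |
| knockout mixture | 0.30 / 0.15 / 0.35 / 0.20 | mature down, extended & oligo(A) up |

Design choices worth stating:

* **The reference is fabricated.** The generator draws a random locus per
  seed rather than bundling the real gene sequence; all downstream logic
  is sequence-agnostic. The `first_downstream_A` flag controls the
  single-A ambiguity in *both* directions: `TRUE` forces base `L_m+1` to
  'A' (the documented ambiguity), `FALSE` forces it non-A, which provably
  makes every terminus state recoverable from error-free reads. Exactness
  claims in the tests use the ambiguity-free variant; the merge behaviour
  is tested separately with the ambiguity on.
* **Single merged fragments by default.** How the real 2×250 bp pairs were
  merged is not modelled; merged fragments isolate the classification
  logic. A `paired` mode emitting reverse-complement mates exists.
* **Substitutions only.** The retention filter discards indel-bearing
  placements anyway, so indel simulation is left out of the default error
  model.
* Reads shorter than `read_len` are padded with random bases after the
  linker (a stand-in for reading into the sequencing adaptor); the linker
  locator makes the padding invisible to the analysis.

What the generator does *not* emulate: PCR amplification bias, ligation
sequence preferences, position-dependent quality decay, chimeric reads.
Passing round-trip tests therefore demonstrate correctness of the
*analysis*, not robustness to every artefact of real libraries.

## A worked example

```{r example}
ref <- build_reference(seed = 1)          # base 452 = 'A'
lib <- simulate_library(ref, control_model(),
                        library_config(n_reads = 4000, err_rate = 0.003),
                        seed = 42)
tab <- lib |>
  call_termini(ref) |>
  summarize_termini()
glance(tab)
tidy(tab)
```

```{r fig5d-style, fig.width = 6, fig.height = 3.5}
autoplot(tab)
```

Contrasting a knockout-like condition:

```{r contrast}
ko <- simulate_library(ref, knockout_model(),
                       library_config(n_reads = 4000, err_rate = 0.003),
                       seed = 43)
ct <- contrast_conditions(ko |> call_termini(ref) |> summarize_termini(), tab)
glance(ct)
```

## Trimming kinetics

The in vitro digestion of a precursor substrate (mature + 8-nt extension +
7 adenosines) by a deadenylase/exonuclease is modelled as a continuous-time
Markov chain with exactly two rates: the current 3'-terminal base is
removed at rate `k_A` (A) or `k_N` (non-A) per minute, until the reaction
time (default 60 min) elapses or a protected floor is reached. This is the
minimal model consistent with "rapid deadenylation, slow exonucleolysis";
no kinetic constants are fitted — none are available — so the rates are
user parameters, with enzyme concentration absorbed into them.

The simulation is exact (per-molecule sequential exponentials, not
tau-leaping): substrates are short, and exactness buys two analytic
cross-checks. With `k_N = 0`, removals form a Poisson process, so the
fraction of molecules reaching the A/non-A boundary is the Poisson upper
tail `P(Pois(k_A t) >= a)` (`deadenylation_tail_cdf()`); with
`k_A = k_N = k`, the number of removals is Poisson(`kt`) truncated at the
floor. The test suite holds the simulator to both closed forms.

```{r kinetics, fig.width = 6, fig.height = 3}
sub <- race_substrate(ref, ref$L_m + 8, 7)
d <- simulate_digestion(sub, trimming_model(k_A = 2, k_N = 0.02), 20000, seed = 7)
autoplot(d)
```

With fast deadenylation and slow exonucleolysis the product distribution
piles up at and a few bases below the extension boundary (459) — the
qualitative signature of a deadenylation-to-exonucleolysis switch.
`digest_to_library()` converts a digestion outcome into a synthetic RACE
library (one read per molecule, so the mixture is preserved exactly),
closing the loop with the sequencing classifier.

## Comparative CT

`ddct_fold_change()` implements the standard comparative-CT method:
replicates are summarised by mean Ct *before* differencing (not
per-replicate fold changes averaged), ΔCt = target − reference per group,
ΔΔCt across groups, fold change `2^(−ΔΔCt)` with amplification efficiency
fixed at 2 (no standard-curve efficiencies are available for correction).
Replicate standard deviations propagate in ΔΔCt space:
`sd = sqrt(sd_dct_sample² + sd_dct_control²)`. `relative_activity()` is
the same arithmetic for single-channel relative readouts
(`2^(control − sample)`, control ≡ 1).

## Numerical and testing notes

* All randomness flows through a single seed argument per entry point;
  fixed seeds give byte-identical FASTQ/TSV/JSON outputs.
* Alignment tie-breaks (total mismatches, then smallest start) are
  declared conventions for determinism, not biological claims.
* Positions where an insert overhangs the reference window count as
  mismatches — conservative, like 'N' handling.
* Problem sizes in the shipped tests: 20,000-read libraries for recovery
  and contrast checks, 50,000 molecules for kinetic law checks, 1,000
  randomised pairs for the brute-force alignment equivalence. These give
  binomial standard errors a few times smaller than every tolerance
  asserted.
* Known limitations: no gapped alignment (indel-bearing true termini are
  rejected, as intended by the retention rule, but also invisible); no
  mate-pair merging; category percentages inherit any bias of the
  junction-detection step under extreme error rates; the kinetic model
  has no sequence context beyond A/non-A.
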