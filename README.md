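# raceterm

Single-nucleotide profiling of RNA 3′ termini from ligation-mediated
3′ RACE deep sequencing, built around the human telomerase RNA (hTR/TERC,
mature length 451 nt, non-polyadenylated), plus a stochastic simulator of
3′→5′ trimming kinetics and comparative-CT quantification.

It is written for people studying 3′-end maturation of non-polyadenylated
RNAs — where each transcript ends (mature end, templated genomic
extension, single terminal adenosine, oligo(A) tail) and how that
distribution shifts when a 3′ trimming enzyme is removed.

## What it computes

Each 3′ RACE read has the structure
`[templated segment ending at reference position g] [A × a] [linker]`,
where the insert/linker junction marks the transcript's exact 3′ end.
The pipeline:

1. locates and removes the ligated **linker** (gapless prefix match,
   ≥ 10 nt overlap, ≤ 10% mismatches) and masks low-quality /
   low-complexity bases;
2. applies the **anchored retention filter**: gapless placement on the
   reference window (mature sequence + 1 kb downstream) with a perfect
   first base, ≤ 1 mismatch over the 19-nt anchor, and no indels (enforced
   by gapless placement itself);
3. **decomposes** each terminus by maximal templated matching into
   (last templated position *g*, non-templated tail) and assigns a
   category — `GENOMIC`, `SINGLE_A_452` (a single terminal A at the
   mature+1 position, which may be genomically encoded and is therefore a
   deliberately merged ambiguous class), `OLIGO_A` (all-A tail, n ≥ 2),
   `MONO_A`, `NON_A_TAIL`;
4. tabulates counts and **percentages of fragments enclosing the 3′ end**
   per position and category, and contrasts conditions.

A synthetic library generator (`simulate_library()`) with per-read ground
truth makes the whole chain testable end to end, and a two-rate
continuous-time trimming simulator (`simulate_digestion()`) models
deadenylation (rate *k*<sub>A</sub> for a 3′-terminal A) versus slower
exonucleolysis (rate *k*<sub>N</sub> otherwise); with *k*<sub>N</sub> = 0
the fraction of molecules reaching the A/non-A boundary is the Poisson
tail *P*(Pois(*k*<sub>A</sub>·*t*) ≥ *a*), which the simulator is tested
against. `ddct_fold_change()` implements 2^(−ΔΔCt) relative
quantification with replicate-SD propagation.

## Worked example

```r
library(raceterm)

ref <- build_reference(seed = 1)                       # fabricated 451+1000 nt locus, base 452 = 'A'
lib <- simulate_library(ref, control_model(),
                        library_config(n_reads = 4000, err_rate = 0.003),
                        seed = 42)
tab <- lib |> call_termini(ref) |> summarize_termini()
glance(tab)
#>   denominator mature_pct single_a_pct oligo_a_pct genomic_pct
#> 1        3979       59.2         9.07        9.15        79.1
```

3,979 of 4,000 reads survived linker detection and the anchor filter
(the denominator); 59.2% end at the mature 451 with a fully templated
terminus, 9.1% carry the ambiguous single A at 452, and 9.2% an oligo(A)
tail — recovering the simulated 60/10/10 mixture to within sampling and
sequencing-error noise. (`tidy(tab)` gives all categories; the small
`MONO_A` class here is oligo(A) reads whose first A was absorbed by the
templated 'A' at 452 — see the vignette on the single-A ambiguity.)
`autoplot(tab)` draws the stacked position-by-category bar chart.

Contrast with a trimming-deficient condition:

```r
ko <- simulate_library(ref, knockout_model(),
                       library_config(n_reads = 4000, err_rate = 0.003),
                       seed = 43)
ct <- contrast_conditions(ko |> call_termini(ref) |> summarize_termini(), tab)
glance(ct)
#>   mature_delta oligo_a_delta shift_mature_down_oligo_up
#> 1        -28.4          6.26 TRUE
```

The mature fraction drops by 28 percentage points while oligo(A) forms
rise — the signature of losing the 3′ trimming exonuclease.

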