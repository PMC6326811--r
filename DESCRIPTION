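Package: raceterm
Title: 3' RACE Terminus Profiling and Stochastic 3' Trimming Kinetics for
    Telomerase RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the 3' termini of non-polyadenylated RNAs (the human
    telomerase RNA hTR in particular) from ligation-mediated 3' RACE
    deep-sequencing libraries. Provides a synthetic library generator with
    known ground truth, linker location and removal, low-quality and
    low-complexity masking, an anchored gapless read-retention filter
    (perfect first base, at most one mismatch over a 19-nt anchor, no
    indels), decomposition of each read's 3' end into its last templated
    reference position and non-templated adenosine tail, category
    tabulation (genomic, single-A at the mature+1 position, oligo(A) n>=2),
    condition contrasts, a two-rate continuous-time simulator of
    deadenylation followed by slower 3'-to-5' exonucleolytic trimming, and
    comparative-CT (delta-delta-CT) relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
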