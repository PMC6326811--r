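ref_amb <- build_reference(seed = 51, first_downstream_A = TRUE)   # base 452 = A
ref_clean <- build_reference(seed = 51, first_downstream_A = FALSE)

test_that("decomposition splits templated segment from non-templated tail", {
  full <- ref_seq(ref_amb)
  # fully templated mature end
  d <- decompose_terminus(substring(full, 401, 451), 401, ref_amb)
  expect_equal(d$genomic_end, 451)
  expect_identical(d$tail, "")
  # added A's over an 'A' at 452: maximal matching absorbs one
  d2 <- decompose_terminus(paste0(substring(full, 401, 451), "AAAA"), 401, ref_amb)
  expect_equal(d2$genomic_end, 452)
  expect_identical(d2$tail, "AAA")
  # templated through 452 is indistinguishable from a single added A
  d3 <- decompose_terminus(substring(full, 401, 452), 401, ref_amb)
  expect_equal(d3$genomic_end, 452)
  expect_identical(d3$tail, "")
  # without the ambiguity nothing is absorbed
  d4 <- decompose_terminus(paste0(substring(ref_seq(ref_clean), 401, 451), "AAAA"),
                           401, ref_clean)
  expect_equal(d4$genomic_end, 451)
  expect_identical(d4$tail, "AAAA")
})

test_that("decomposition agrees with the brute-force split-point oracle", {
  withr::local_seed(52)
  full <- ref_clean
  fs <- ref_seq(full)
  for (i in 1:1000) {
    start <- sample(350:430, 1)
    tlen <- sample(19:45, 1)
    tail <- paste(sample(c("A", "A", "A", "C", "G", "T"),
                         sample(0:8, 1), replace = TRUE), collapse = "")
    insert <- paste0(substring(fs, start, start + tlen - 1), tail)
    got <- decompose_terminus(insert, start, full)
    want <- oracle_decompose(insert, start, fs)
    expect_equal(got$genomic_end, want$genomic_end, info = paste("case", i))
    expect_identical(got$tail, want$tail, info = paste("case", i))
  }
})

test_that("categories follow the genomic / single-A / oligo(A) scheme", {
  L_m <- 451
  expect_identical(categorize(451, "", L_m, ref_amb), "GENOMIC")
  expect_identical(categorize(452, "", L_m, ref_amb), "SINGLE_A_452")  # templated A
  expect_identical(categorize(451, "A", L_m, ref_clean), "SINGLE_A_452")  # added A
  expect_identical(categorize(452, "", L_m, ref_clean), "GENOMIC")  # 452 not A
  expect_identical(categorize(455, "AAAAA", L_m, ref_amb), "OLIGO_A")
  expect_identical(categorize(451, "AA", L_m, ref_clean), "OLIGO_A")
  expect_identical(categorize(453, "A", L_m, ref_clean), "MONO_A")
  expect_identical(categorize(451, "AG", L_m, ref_clean), "NON_A_TAIL")
  # a 2-A tail ending at 452 is an oligo(A) addition, not the single-A class
  expect_identical(categorize(450, "AA", L_m, ref_clean), "OLIGO_A")
})

test_that("run mode counts boundary-straddling A-runs as oligo(A)", {
  # find a templated position ending in 'A' downstream of the mature end
  fs <- ref_seq(ref_clean)
  g <- 452 + regexpr("A", substring(fs, 453, 520), fixed = TRUE)
  expect_identical(substr(fs, g, g), "A")
  expect_identical(categorize(g, "A", 451, ref_clean, a_run_mode = FALSE), "MONO_A")
  expect_identical(categorize(g, "A", 451, ref_clean, a_run_mode = TRUE), "OLIGO_A")
})

test_that("every passing junction-found insert yields exactly one call", {
  lib <- simulate_library(ref_clean, control_model(),
                          library_config(n_reads = 400, err_rate = 0.003),
                          seed = 53)
  pre <- preprocess_reads(lib, mask = FALSE)
  aln <- align_inserts(pre, ref_clean)
  calls <- classify_termini(aln, ref_clean)
  qc <- attr(calls, "qc")
  expect_equal(nrow(calls), sum(aln$pass & aln$junction_found))
  expect_equal(unname(qc["n_called"] + qc["n_no_junction"] + qc["n_filter_fail"]),
               unname(qc["n_reads"]))
  tab <- summarize_termini(calls)
  expect_equal(sum(tab$n), attr(tab, "denominator"))
  expect_equal(sum(tab$pct), 100, tolerance = 1e-6)
})

test_that("summaries recover an error-free mixture exactly", {
  lib <- simulate_library(ref_clean, control_model(),
                          library_config(n_reads = 3000, err_rate = 0),
                          seed = 54)
  tab <- lib |> call_termini(ref_clean) |> summarize_termini()
  got <- called_pct(tab)
  want <- truth_pct(lib, 451)
  expect_equal(unname(got[names(want)]), unname(as.numeric(want)),
               tolerance = 1e-12)
  # position histogram records oligo(A) reads at their total end position
  oligo <- lib[lib$a_tail >= 2, ]
  want_pos <- table(oligo$genomic_end + oligo$a_tail)
  got_pos <- tab[tab$category == "OLIGO_A", ]
  expect_equal(got_pos$n[match(names(want_pos), got_pos$end_position)],
               as.integer(want_pos))
})

test_that("summarize of no calls returns an empty table with denominator 0", {
  empty <- tibble::tibble(read_id = character(), genomic_end = integer(),
                          tail = character(), tail_a = integer(),
                          end_position = integer(),
                          category = factor(character()))
  tab <- summarize_termini(empty, L_m = 451)
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "denominator"), 0)
})

test_that("condition contrasts report directions and are antisymmetric", {
  cfg <- library_config(n_reads = 4000, err_rate = 0)
  tab_nc <- simulate_library(ref_clean, control_model(), cfg, seed = 55) |>
    call_termini(ref_clean) |> summarize_termini()
  tab_ko <- simulate_library(ref_clean, knockout_model(), cfg, seed = 56) |>
    call_termini(ref_clean) |> summarize_termini()

  ct <- contrast_conditions(tab_ko, tab_nc)
  expect_lt(attr(ct, "mature_delta"), 0)
  expect_gt(attr(ct, "oligo_a_delta"), 0)
  expect_true(attr(ct, "shift_mature_down_oligo_up"))

  # identical tables -> all differences zero
  ct0 <- contrast_conditions(tab_nc, tab_nc)
  expect_true(all(ct0$delta_pct == 0))
  # swapping arguments negates the differences
  ct_rev <- contrast_conditions(tab_nc, tab_ko)
  expect_equal(ct_rev$delta_pct, -ct$delta_pct)

  expect_error(contrast_conditions(summarize_termini(
    tibble::tibble(read_id = character(), genomic_end = integer(),
                   tail = character(), tail_a = integer(),
                   end_position = integer(), category = factor(character())),
    L_m = 451), tab_nc), "denominator")
})

test_that("tidy, glance and autoplot work on the result objects", {
  lib <- simulate_library(ref_clean, control_model(),
                          library_config(n_reads = 500, err_rate = 0), seed = 57)
  tab <- lib |> call_termini(ref_clean) |> summarize_termini()
  td <- tidy(tab)
  expect_s3_class(td, "tbl_df")
  expect_setequal(as.character(td$category),
                  c("GENOMIC", "SINGLE_A_452", "OLIGO_A", "MONO_A",
                    "NON_A_TAIL", "UNCLASSIFIED"))
  gl <- glance(tab)
  expect_equal(gl$denominator, nrow(lib))
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
  ct <- contrast_conditions(tab, tab)
  expect_s3_class(ggplot2::autoplot(ct), "ggplot")
  expect_true(is.logical(glance(ct)$shift_mature_down_oligo_up))
})
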