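lk <- default_linker()

test_that("locate_linker finds exact and mismatched junctions", {
  withr::local_seed(21)
  ins <- rand_seq(50)
  expect_identical(locate_linker(paste0(ins, lk), lk), 51L)
  # no linker anywhere
  expect_identical(locate_linker(rand_seq(80), lk), NA_integer_)
  # one mismatch in the linker copy is tolerated at 10%
  lk_mut <- lk
  substr(lk_mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(lk, 5, 5))[1]
  expect_identical(locate_linker(paste0(ins, lk_mut), lk), 51L)
  # linker truncated at the read end still found given min_overlap
  expect_identical(locate_linker(paste0(ins, substr(lk, 1, 12)), lk), 51L)
  expect_identical(locate_linker(paste0(ins, substr(lk, 1, 8)), lk), NA_integer_)
})

test_that("locate_linker agrees with the all-offsets oracle on random reads", {
  withr::local_seed(22)
  for (i in 1:1000) {
    n <- sample(30:300, 1)
    read <- rand_seq(n)
    if (i %% 2 == 0) {
      # plant a (possibly mutated, possibly truncated) linker copy
      j <- sample(seq_len(max(1, n - 15)), 1)
      piece <- substr(lk, 1, min(nchar(lk), n - j + 1))
      if (i %% 4 == 0 && nchar(piece) > 12) {
        p <- sample(nchar(piece), 1)
        substr(piece, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      substr(read, j, j + nchar(piece) - 1) <- piece
    }
    expect_identical(locate_linker(read, lk), oracle_locate_linker(read, lk),
                     info = paste("case", i))
  }
})

test_that("trim_to_insert is the inverse of appending the linker", {
  read <- paste0("ACGTACGTAA", lk, "GGGG")
  tr <- trim_to_insert(read, 11L)
  expect_identical(tr$seq, "ACGTACGTAA")
  expect_true(tr$junction_found)
  expect_identical(substr(paste0(tr$seq, lk), 1, 20), substr(read, 1, 20))
  # absent junction keeps the full read, flagged
  tr2 <- trim_to_insert(read, NA_integer_)
  expect_identical(tr2$seq, read)
  expect_false(tr2$junction_found)
  expect_error(trim_to_insert(read, 1L), "Empty insert")
})

test_that("masking flags low quality and low complexity without changing length", {
  withr::local_seed(23)
  s <- rand_seq(60)
  q_hi <- strrep("I", 60)  # phred 40
  m <- mask_low_quality(s, q_hi)
  expect_identical(m$seq, s)
  expect_equal(m$masked_frac, 0)

  # homopolymer window: entropy 0 < 1 bit
  hp <- strrep("A", 30)
  m2 <- mask_low_quality(hp, strrep("I", 30))
  expect_identical(m2$seq, strrep("N", 30))
  expect_equal(m2$masked_frac, 1)

  # half the bases at phred 2
  q_half <- paste0(strrep("#", 30), strrep("I", 30))
  m3 <- mask_low_quality(s, q_half)
  expect_equal(m3$masked_frac, 0.5)
  expect_equal(nchar(m3$seq), 60)
  expect_error(mask_low_quality(s, "II"), "length")
})

test_that("preprocess_reads separates inserts from linker-less reads", {
  withr::local_seed(24)
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    seq = c(paste0(rand_seq(40), lk, rand_seq(10)), rand_seq(80)),
    qual = c(strrep("I", 77), strrep("I", 80))
  )
  out <- preprocess_reads(reads)
  expect_equal(out$junction_found, c(TRUE, FALSE))
  expect_equal(nchar(out$seq[1]), 40)
  expect_equal(nchar(out$seq[2]), 80)
})

test_that("masking outside the terminal region leaves terminus calls unchanged", {
  ref <- build_reference(seed = 31, first_downstream_A = FALSE)
  cfg <- library_config(n_reads = 150, err_rate = 0)
  lib <- simulate_library(ref, control_model(), cfg, seed = 32)
  calls_plain <- call_termini(lib, ref)
  # degrade qualities of insert bases 2-11 only (far from the 3' end; base 1
  # stays intact so the first-base-exact rule still applies)
  lib_low <- lib
  lib_low$qual <- paste0(substr(lib$qual, 1, 1), strrep("#", 10),
                         substr(lib$qual, 12, nchar(lib$qual)))
  calls_masked <- call_termini(lib_low, ref, mask = TRUE,
                               policy = anchor_policy(max_anchor_mismatch = 12))
  common <- intersect(calls_plain$read_id, calls_masked$read_id)
  expect_gt(length(common), 0)
  a <- calls_plain[match(common, calls_plain$read_id), c("genomic_end", "tail", "category")]
  b <- calls_masked[match(common, calls_masked$read_id), c("genomic_end", "tail", "category")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})
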