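test_that("AB1 round-trip recovers trace, basecalls and sequence", {
  chrom <- make_test_chromatogram()
  path <- withr::local_tempfile(fileext = ".ab1")
  write_synthetic_ab1(path,
                      channels = as.data.frame(chrom$trace),
                      ploc0 = chrom$basecall_positions - 1L,
                      sequence = chrom$called_sequence)
  got <- read_ab1(path, direction = "F", sample_id = "t1")
  expect_equal(got$called_sequence, chrom$called_sequence)
  expect_equal(got$basecall_positions, chrom$basecall_positions)
  expect_equal(unname(got$trace), unname(round(chrom$trace)), tolerance = 1e-9)
})

test_that("AB1 channel mapping follows the dye-order record", {
  chrom <- make_test_chromatogram()
  p1 <- withr::local_tempfile(fileext = ".ab1")
  p2 <- withr::local_tempfile(fileext = ".ab1")
  ch <- as.data.frame(chrom$trace)
  write_synthetic_ab1(p1, ch, chrom$basecall_positions - 1L,
                      chrom$called_sequence, dye_order = "GATC")
  write_synthetic_ab1(p2, ch, chrom$basecall_positions - 1L,
                      chrom$called_sequence, dye_order = "ACGT")
  a <- read_ab1(p1)
  b <- read_ab1(p2)
  expect_equal(a$trace, b$trace)
})

test_that("truncated or alien files produce format errors naming the problem", {
  p <- withr::local_tempfile(fileext = ".ab1")
  writeLines("not a chromatogram", p)
  expect_error(read_ab1(p), "ABIF")
  chrom <- make_test_chromatogram()
  p2 <- withr::local_tempfile(fileext = ".ab1")
  write_synthetic_ab1(p2, as.data.frame(chrom$trace),
                      chrom$basecall_positions - 1L, chrom$called_sequence)
  raw_all <- readBin(p2, "raw", file.size(p2))
  writeBin(raw_all[1:200], p2)
  expect_error(read_ab1(p2), "truncated|missing")
})

test_that("tabular trace dialect round-trips a simulated chromatogram", {
  chrom <- simulate_trace("ACGTTGCA", 5L, c(T = 180, G = 120),
                          noise_floor = 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trace_table(chrom, path)
  got <- read_trace_table(path)
  expect_equal(got$called_sequence, chrom$called_sequence)
  expect_equal(got$basecall_positions, chrom$basecall_positions)
  expect_equal(got$trace, chrom$trace, tolerance = 1e-12)
  expect_equal(got$sample_id, chrom$sample_id)
  expect_equal(got$direction, chrom$direction)
})

test_that("trace table reader rejects empty and malformed files", {
  p <- withr::local_tempfile()
  file.create(p)
  expect_error(read_trace_table(p), "empty")
  writeLines(c("#sample=s", "#direction=F", "#basecalls=1",
               "#sequence=A", "1\t2\t3"), p)
  expect_error(read_trace_table(p), "four")
})

test_that("single-basecall trace is read back intact", {
  chrom <- simulate_trace("A", 1L, c(A = 100, G = 50))
  path <- withr::local_tempfile()
  write_trace_table(chrom, path)
  got <- read_trace_table(path)
  expect_length(got$basecall_positions, 1L)
  expect_equal(nchar(got$called_sequence), 1L)
})

test_that("variant location by flanks is exact, unique, and strand-consistent", {
  chrom <- make_test_chromatogram()   # "ACGTYGCA", variant at 5
  expect_equal(locate_variant_index(chrom, "ACGT", "GCA"), 5L)
  expect_error(locate_variant_index(chrom, "ZZZZ", "GCA"), "not found")

  dup <- chromatogram(matrix(1, nrow = 90, ncol = 4),
                      seq(10, 90, by = 10), "ACGTACGTA")
  expect_error(locate_variant_index(dup, "A", "G"), "extend")

  # reverse-strand read of the same molecule: simulate the complement trace
  fwd_seq <- "ACGTYGCA"
  rev_seq <- reverse_complement(fwd_seq)
  rev <- simulate_trace(rev_seq, nchar(rev_seq) - 5L + 1L,
                        c(G = 200, A = 100), direction = "R")
  i_f <- locate_variant_index(chrom, "ACGT", "GCA")
  i_r <- locate_variant_index(rev, reverse_complement("GCA"),
                              reverse_complement("ACGT"))
  expect_equal(i_r, nchar(fwd_seq) - i_f + 1L)
})

test_that("peak extraction recovers configured amplitudes and is linear", {
  chrom <- make_test_chromatogram(allele_heights = c(C = 200, T = 100))
  pair <- extract_peak_pair(chrom, 5L, "C", "T")
  expect_equal(pair$height1, 200, tolerance = 0.02)
  expect_equal(pair$height2, 100, tolerance = 0.02)

  doubled <- chrom
  doubled$trace <- chrom$trace * 2
  pair2 <- extract_peak_pair(doubled, 5L, "C", "T")
  expect_equal(pair2$height1, 2 * pair$height1, tolerance = 1e-12)
  expect_equal(pair2$height2, 2 * pair$height2, tolerance = 1e-12)
  expect_equal(log(pair2$height1 / pair2$height2),
               log(pair$height1 / pair$height2), tolerance = 1e-12)

  # flat allele2 channel (no T anywhere else in the simulated read)
  hom <- make_test_chromatogram(sequence = "ACGGYGCA",
                                allele_heights = c(C = 200, T = 0))
  pair3 <- extract_peak_pair(hom, 5L, "C", "T")
  expect_equal(pair3$height2, 0)
})

test_that("QC flags clean, low-signal and off-target cases as designed", {
  clean <- make_test_chromatogram()
  pair <- extract_peak_pair(clean, 5L, "C", "T")
  expect_length(qc_assess(pair, clean, 5L)$qc_flags, 0L)

  # allele2 buried in baseline noise
  noisy <- simulate_trace("ACGTYGCA", 5L, c(C = 500, T = 10),
                          base_amplitude = 600, noise_floor = 20, seed = 3)
  pair_lo <- extract_peak_pair(noisy, 5L, "C", "T")
  flags_lo <- qc_assess(pair_lo, noisy, 5L,
                        config = list(min_signal = 10))$qc_flags
  expect_true("low_signal" %in% flags_lo)
  # the strong allele is never the one flagged
  expect_gt(pair_lo$height1, 10 * 20)

  # contaminating third peak at 0.9 x the minor allele height
  cont <- make_test_chromatogram(allele_heights = c(C = 200, T = 100))
  center <- cont$basecall_positions[5]
  x <- seq_len(nrow(cont$trace))
  cont$trace[, "G"] <- cont$trace[, "G"] +
    90 * exp(-((x - center)^2) / (2 * 2^2))
  pair_ot <- extract_peak_pair(cont, 5L, "C", "T")
  flags <- qc_assess(pair_ot, cont, 5L,
                     config = list(max_offtarget = 0.5))$qc_flags
  expect_true("offtarget_peak" %in% flags)
})

test_that("peak table writer/reader round-trips simulation output", {
  sim <- simulate_peak_table(simulation_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(sim$peaks, path)
  got <- read_peak_table(path)
  expect_equal(as.data.frame(got), as.data.frame(sim$peaks),
               tolerance = 1e-12)
})
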