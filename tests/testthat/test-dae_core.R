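make_measurements <- function(df) {
  defaults <- tibble::tibble(
    sample_id = "s1", snp_id = "rs1", group = "control",
    template = "cDNA", direction = "F", allele1 = "C", allele2 = "T",
    r = 0, oriented = FALSE, rho = NA_real_
  )
  out <- dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) defaults))
  for (col in names(df)) out[[col]] <- df[[col]]
  out
}

test_that("log allelic ratio is ln(h1/h2), antisymmetric, undefined at zero", {
  expect_equal(log_allelic_ratio(150, 150), 0)
  expect_equal(log_allelic_ratio(200, 100), log(2))
  expect_equal(log_allelic_ratio(100, 200), -log_allelic_ratio(200, 100))
  pair <- peak_pair("rs1", "C", "T", 200, 100)
  expect_equal(log_allelic_ratio(pair), log(2))
  expect_error(log_allelic_ratio(0, 100), "> 0")
})

test_that("orientation maps reverse reads to forward-strand reference-first", {
  # reverse read with numerator G; complement(G) = C = reference: unchanged
  m <- list(direction = "R", allele1 = "G", allele2 = "A", r = 0.3,
            oriented = FALSE)
  o <- orient_measurement(m, "C", "T")
  expect_equal(o$r, 0.3)
  expect_equal(o$allele1, "C")
  expect_true(o$oriented)

  # forward read already reference-first: identity
  f <- list(direction = "F", allele1 = "C", allele2 = "T", r = 0.2,
            oriented = FALSE)
  expect_equal(orient_measurement(f, "C", "T")$r, 0.2)

  # reverse read observed (A, G): complement (T, C), reorder negates r
  s <- list(direction = "R", allele1 = "A", allele2 = "G", r = 0.7,
            oriented = FALSE)
  o2 <- orient_measurement(s, "C", "T")
  expect_equal(o2$r, -0.7)
  expect_equal(o2$allele1, "C")

  # orienting twice is the identity
  expect_equal(orient_measurement(o2, "C", "T"), o2)

  # alleles inconsistent with the SNP
  bad <- list(direction = "F", allele1 = "A", allele2 = "C", r = 0,
              oriented = FALSE)
  expect_error(orient_measurement(bad, "C", "T"), "do not match")
})

test_that("gDNA centering zeroes each direction's gDNA mean and shifts cDNA", {
  m <- make_measurements(tibble::tibble(
    sample_id = c("g1", "g2", "g3", "c1"),
    template = c("gDNA", "gDNA", "gDNA", "cDNA"),
    r = c(0.2, -0.2, 0.0, 0.5)
  ))
  study <- center_by_gdna(dae_study("rs1", "C", "T", m))
  expect_equal(unname(study$gdna_means["F"]), 0)
  expect_equal(study$measurements$rho[4], 0.5)

  m2 <- make_measurements(tibble::tibble(
    sample_id = c("g1", "g2", "g3", "c1"),
    template = c("gDNA", "gDNA", "gDNA", "cDNA"),
    r = c(0.1, 0.1, 0.1, 0.5)
  ))
  study2 <- center_by_gdna(dae_study("rs1", "C", "T", m2))
  expect_equal(study2$measurements$rho[1:3], rep(0, 3))
  expect_equal(study2$measurements$rho[4], 0.4)

  # a direction without any gDNA measurement cannot be centred
  m3 <- make_measurements(tibble::tibble(
    sample_id = c("g1", "c1"), template = c("gDNA", "cDNA"),
    direction = c("F", "R"), allele1 = c("C", "G"), allele2 = c("T", "A"),
    r = c(0.1, 0.5)
  ))
  expect_error(center_by_gdna(dae_study("rs1", "C", "T", m3)),
               "direction R")
})

test_that("direction-specific shift invariance: centering removes dye bias exactly", {
  sim <- simulate_peak_table(simulation_config(seed = 21))
  base <- center_by_gdna(dae_study("rs600753", "C", "T",
                                   peaks_to_measurements(sim$peaks)))
  shifted_peaks <- sim$peaks
  is_f <- shifted_peaks$direction == "F"
  shifted_peaks$height1[is_f] <- shifted_peaks$height1[is_f] * exp(0.8)
  shifted <- center_by_gdna(dae_study("rs600753", "C", "T",
                                      peaks_to_measurements(shifted_peaks)))
  expect_equal(shifted$measurements$rho, base$measurements$rho,
               tolerance = 1e-12)
})

test_that("swapping reference and alternate negates every corrected value", {
  sim <- simulate_peak_table(simulation_config(seed = 22))
  m <- peaks_to_measurements(sim$peaks)
  a <- center_by_gdna(dae_study("rs600753", "C", "T", m))
  b <- center_by_gdna(dae_study("rs600753", "T", "C", m))
  expect_equal(b$measurements$rho, -a$measurements$rho, tolerance = 1e-12)
  expect_equal(summarize_snp(b)$mean, -summarize_snp(a)$mean,
               tolerance = 1e-12)
})

test_that("noise-free measurements reproduce the configured effects exactly", {
  cfg <- simulation_config(noise_sd = 0, b_F = 0.3, b_R = -0.4,
                           theta_family = 0.4, theta_control = -0.2,
                           seed = 1)
  sim <- simulate_peak_table(cfg)
  study <- center_by_gdna(dae_study("rs600753", "C", "T",
                                    peaks_to_measurements(sim$peaks)))
  comb <- combine_directions(study)
  fam <- comb$rho[comb$group == "affected_family" & comb$template == "cDNA"]
  ctl <- comb$rho[comb$group == "control" & comb$template == "cDNA"]
  expect_equal(fam, rep(0.4, length(fam)), tolerance = 1e-12)
  expect_equal(ctl, rep(-0.2, length(ctl)), tolerance = 1e-12)
})

test_that("direction combination averages, falls back, and is idempotent", {
  m <- make_measurements(tibble::tibble(
    sample_id = c("g1", "g1", "c1", "c1", "c2"),
    template = c("gDNA", "gDNA", "cDNA", "cDNA", "cDNA"),
    direction = c("F", "R", "F", "R", "F"),
    allele1 = c("C", "G", "C", "G", "C"),
    allele2 = c("T", "A", "T", "A", "T"),
    r = c(0, 0, 0.4, 0.6, 0.25)
  ))
  study <- center_by_gdna(dae_study("rs1", "C", "T", m))
  comb <- combine_directions(study)
  expect_equal(comb$rho[comb$sample_id == "c1"], 0.5)
  expect_equal(comb$n_directions[comb$sample_id == "c1"], 2L)
  expect_equal(comb$rho[comb$sample_id == "c2"], 0.25)
  expect_equal(comb$n_directions[comb$sample_id == "c2"], 1L)
  expect_true(all(comb$analysis_set == "F&R"))

  m$r[3:4] <- c(0.7, 0.7)
  study2 <- center_by_gdna(dae_study("rs1", "C", "T", m))
  comb2 <- combine_directions(study2)
  expect_equal(comb2$rho[comb2$sample_id == "c1"], 0.7)
})

test_that("summaries report per-group n, mean, SD, with NA for empty groups", {
  m <- make_measurements(tibble::tibble(
    sample_id = c("g1", "g2", "c1", "c2"),
    group = c("control", "control", "control", "control"),
    template = c("gDNA", "gDNA", "cDNA", "cDNA"),
    r = c(0.1, -0.1, 0.3, 0.3)
  ))
  s <- summarize_snp(center_by_gdna(dae_study("rs1", "C", "T", m)), "F")
  expect_equal(s$mean[s$comparison_group == "gDNA"], 0)
  expect_equal(s$mean[s$comparison_group == "control"], 0.3)
  expect_equal(s$sd[s$comparison_group == "control"], 0)
  expect_equal(s$n[s$comparison_group == "affected_family"], 0L)
  expect_true(is.na(s$mean[s$comparison_group == "affected_family"]))
})

test_that("simulated group means converge on the configured effects", {
  cfg <- simulation_config(n_family = 40, n_control = 40, noise_sd = 0.2,
                           seed = 31)
  sim <- simulate_peak_table(cfg)
  study <- center_by_gdna(dae_study("rs600753", "C", "T",
                                    peaks_to_measurements(sim$peaks)))
  s <- summarize_snp(study, "F&R")
  # Monte-Carlo tolerance: ~4 SE of a mean of 40 samples x 2 directions
  tol <- 4 * 0.2 / sqrt(40)
  expect_lt(abs(s$mean[s$comparison_group == "affected_family"] - 0.42), tol)
  expect_lt(abs(s$mean[s$comparison_group == "control"] - (-0.34)), tol)
})
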