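test_that("peak table generator is deterministic and honours its truth record", {
  cfg <- simulation_config(seed = 41)
  a <- simulate_peak_table(cfg)
  b <- simulate_peak_table(cfg)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)

  # different seed, different data
  c <- simulate_peak_table(simulation_config(seed = 42))
  expect_false(identical(a$peaks$height1, c$peaks$height1))

  # noise-free: every observed ln ratio equals the recorded truth exactly
  cfg0 <- simulation_config(noise_sd = 0, b_F = 0.2, b_R = -0.3, seed = 1)
  sim0 <- simulate_peak_table(cfg0)
  obs <- log(sim0$peaks$height1 / sim0$peaks$height2)
  key <- paste(sim0$peaks$sample_id, sim0$peaks$template,
               sim0$peaks$direction)
  tkey <- paste(sim0$truth$measurements$sample_id,
                sim0$truth$measurements$template,
                sim0$truth$measurements$direction)
  expect_equal(obs, sim0$truth$measurements$true_log_ratio[match(key, tkey)],
               tolerance = 1e-12)
})

test_that("all-zero configuration yields exactly balanced peaks", {
  cfg <- simulation_config(noise_sd = 0, b_F = 0, b_R = 0,
                           theta_family = 0, theta_control = 0, seed = 1)
  sim <- simulate_peak_table(cfg)
  expect_equal(log(sim$peaks$height1 / sim$peaks$height2),
               rep(0, nrow(sim$peaks)), tolerance = 1e-12)
})

test_that("direction dropout and artifact flags appear at the configured rates", {
  cfg <- simulation_config(n_family = 60, n_control = 60,
                           missing_direction_rate = 0.3,
                           qc_artifact_rate = 0.2, seed = 43)
  sim <- simulate_peak_table(cfg)
  n_full <- 120 * 2 * 2
  drop_rate <- 1 - nrow(sim$peaks) / n_full
  expect_lt(abs(drop_rate - 0.3), 0.06)
  flag_rate <- mean(sim$peaks$qc_flags == "simulated_artifact")
  expect_lt(abs(flag_rate - 0.2), 0.06)
})

test_that("direction bias of any magnitude cancels exactly at zero noise", {
  for (b in c(0, 0.5, -2, 7)) {
    cfg <- simulation_config(noise_sd = 0, b_F = b, b_R = -b / 3, seed = 1)
    sim <- simulate_peak_table(cfg)
    study <- center_by_gdna(dae_study("rs600753", "C", "T",
                                      peaks_to_measurements(sim$peaks)))
    s <- summarize_snp(study, "F&R")
    expect_equal(s$mean[s$comparison_group == "affected_family"], 0.42,
                 tolerance = 1e-12)
    expect_equal(s$mean[s$comparison_group == "control"], -0.34,
                 tolerance = 1e-12)
  }
})

test_that("simulated traces are reproducible and carry the configured peaks", {
  t1 <- simulate_trace("ACGTYGCA", 5, c(C = 200, T = 100), noise_floor = 5,
                       seed = 3)
  t2 <- simulate_trace("ACGTYGCA", 5, c(C = 200, T = 100), noise_floor = 5,
                       seed = 3)
  expect_identical(t1, t2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_trace_table(t1, p1); write_trace_table(t2, p2)
  expect_identical(readLines(p1), readLines(p2))

  single <- simulate_trace("G", 1, c(G = 150, T = 0))
  expect_equal(max(single$trace[, "G"]), 150, tolerance = 1e-6)
  expect_equal(max(single$trace[, c("A", "C")]), 0)
  expect_warning(simulate_trace("ACGT", 2, c(C = 10, G = 10),
                                peak_spacing = 4, peak_sd = 8), "overlap")
})

test_that("genotype generator: monomorphic, missingness, determinism", {
  mono <- simulate_genotype_table(3, n_family = 5, n_control = 10,
                                  maf_range = c(0, 0), seed = 2)
  el <- eligibility_filter(mono$genotypes)
  expect_equal(el$het_family + el$het_control, rep(0L, 3))
  expect_false(any(el$eligible))

  m <- simulate_genotype_table(50, n_family = 10, n_control = 18,
                               missing_rate = 0.05, seed = 3)
  rate <- mean(is.na(m$genotypes$calls))
  expect_lt(abs(rate - 0.05), 0.02)
  qc <- genotype_qc(m$genotypes)
  expect_gt(mean(qc$call_rate < 0.97), 0.4)  # 0.95 expected call rate

  again <- simulate_genotype_table(50, n_family = 10, n_control = 18,
                                   missing_rate = 0.05, seed = 3)
  expect_identical(m$genotypes$calls, again$genotypes$calls)
})

test_that("family genotypes obey Mendelian transmission", {
  sim <- simulate_genotype_table(100, n_family = 10, n_control = 0,
                                 maf_range = c(0.3, 0.5), seed = 13)
  calls <- sim$genotypes$calls
  ped <- list(c(3, 1, 2), c(4, 1, 2), c(6, 3, 5), c(7, 3, 5),
              c(9, 4, 8), c(10, 4, 8))
  minor_count <- function(g) c(AA = 0, AB = 1, BB = 2)[g]
  for (trio in ped) {
    child <- minor_count(calls[, trio[1]])
    pa <- minor_count(calls[, trio[2]])
    ma <- minor_count(calls[, trio[3]])
    # a parent passes at least (count - 1) and at most min(count, 1) ... i.e.
    # child count within [max contribution bounds] of the parents
    lo <- pmax(pa - 1, 0) + pmax(ma - 1, 0)
    hi <- pmin(pa, 1) + pmin(ma, 1)
    expect_true(all(child >= lo & child <= hi))
  }
})

test_that("null-study collections are independent but reproducible", {
  cfg <- simulation_config(seed = 99)
  sims <- simulate_null_study(cfg, n_studies = 3)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]]$peaks$height1, sims[[2]]$peaks$height1))
  again <- simulate_null_study(cfg, n_studies = 3)
  expect_identical(sims[[1]]$peaks, again[[1]]$peaks)
  # all thetas forced equal
  expect_true(all(vapply(sims, function(s) {
    all(s$truth$group_means$true_mean == 0)
  }, TRUE)))
})

test_that("parameter recovery at n = 50 per group stays within 3 sd / sqrt(n)", {
  hits <- vapply(1:60, function(k) {
    cfg <- simulation_config(n_family = 50, n_control = 50, noise_sd = 0.3,
                             seed = 1000 + k)
    sim <- simulate_peak_table(cfg)
    study <- center_by_gdna(dae_study("rs600753", "C", "T",
                                      peaks_to_measurements(sim$peaks)))
    s <- summarize_snp(study, "F&R")
    tol <- 3 * 0.3 / sqrt(50)
    abs(s$mean[s$comparison_group == "affected_family"] - 0.42) < tol &&
      abs(s$mean[s$comparison_group == "control"] + 0.34) < tol
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
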