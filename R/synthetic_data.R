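#' Simulation configuration for synthetic DAE studies
#'
#' Defines the study conditions the generator emulates: heterozygous
#' cell-line counts per group, true group allelic log fold changes on the
#' natural-log scale, direction-specific assay biases, multiplicative
#' (log-normal) peak-height noise, and the SNP panel.
#'
#' Defaults mirror a small family-vs-control DAE design: 6 affected-family
#' and 7 control heterozygous lines, group effects +0.42 (family) and -0.34
#' (controls), balanced gDNA (0), modest dye biases, and height noise
#' `noise_sd = 0.2` (each height is multiplied by `exp(e)`, e ~ N(0, sd^2),
#' so the induced log-ratio noise has variance `2 * noise_sd^2`).
#'
#' @param n_family,n_control Heterozygous cell-line counts per group.
#' @param theta_family,theta_control True cDNA allelic log fold change per
#'   group (ln scale; positive = reference allele higher).
#' @param theta_gdna True gDNA imbalance (0 for a clean heterozygote).
#' @param b_F,b_R Additive ln-scale assay bias per sequencing direction.
#' @param noise_sd SD of the per-height ln-scale noise.
#' @param base_intensity Mean total peak signal (fluorescence units).
#' @param missing_direction_rate Probability that a sample/template/direction
#'   measurement is missing.
#' @param qc_artifact_rate Probability that a measurement carries a simulated
#'   QC artifact (flagged `simulated_artifact`; excluded downstream).
#' @param snp_panel Tibble with `snp_id`, `reference_allele`,
#'   `alternate_allele` (defaults to the first panel row of
#'   [dyslexia_snp_panel()]).
#' @param seed Integer root seed; every stochastic draw flows from a named
#'   substream of it, so regenerating with the same config is reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_family = 6L, n_control = 7L,
                              theta_family = 0.42, theta_control = -0.34,
                              theta_gdna = 0,
                              b_F = 0.1, b_R = -0.15,
                              noise_sd = 0.2, base_intensity = 1000,
                              missing_direction_rate = 0,
                              qc_artifact_rate = 0,
                              snp_panel = dyslexia_snp_panel()[2, ],
                              seed = 1L) {
  stopifnot(n_family >= 0, n_control >= 0, noise_sd >= 0,
            base_intensity > 0,
            missing_direction_rate >= 0, missing_direction_rate <= 1,
            qc_artifact_rate >= 0, qc_artifact_rate <= 1)
  structure(
    list(n_family = as.integer(n_family), n_control = as.integer(n_control),
         theta_family = theta_family, theta_control = theta_control,
         theta_gdna = theta_gdna, b_F = b_F, b_R = b_R,
         noise_sd = noise_sd, base_intensity = base_intensity,
         missing_direction_rate = missing_direction_rate,
         qc_artifact_rate = qc_artifact_rate,
         snp_panel = tibble::as_tibble(snp_panel),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic substream seed: root seed combined with a stream name, so
# adding a new draw stream never perturbs existing ones
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

iupac_ambiguity <- function(a, b) {
  pair <- paste(sort(c(toupper(a), toupper(b))), collapse = "")
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  code <- codes[pair]
  if (is.na(code)) stop("not a valid allele pair: ", pair, call. = FALSE)
  unname(code)
}

#' Simulate a peak-height table with recorded ground truth
#'
#' For every SNP in the panel, heterozygous sample, template (cDNA, gDNA) and
#' direction (F, R), the true log allelic ratio is
#' `t = theta_group(template) + b_direction`; the reference-allele fraction is
#' `p = exp(t) / (1 + exp(t))` and the two heights are
#' `h1 = L * p * exp(e1)`, `h2 = L * (1 - p) * exp(e2)` with independent
#' `e ~ N(0, noise_sd^2)` and `L = base_intensity`. Reverse-direction rows
#' report complemented alleles (as a reverse Sanger read would). Directions
#' are dropped at `missing_direction_rate`, and `qc_artifact_rate` of the
#' remaining rows are flagged `simulated_artifact`.
#'
#' @param config A [simulation_config()].
#' @return List: `peaks` (tibble in the peak-table dialect), `truth` (list
#'   with per-measurement `measurements` and per-SNP `group_means`), and
#'   `config`.
#' @export
simulate_peak_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$snp_panel
  samples <- tibble::tibble(
    sample_id = c(sprintf("FAM%02d", seq_len(config$n_family)),
                  sprintf("CTRL%02d", seq_len(config$n_control))),
    group = rep(c("affected_family", "control"),
                c(config$n_family, config$n_control))
  )
  grid <- tidyr::expand_grid(
    snp_id = panel$snp_id,
    sample_id = samples$sample_id,
    template = c("cDNA", "gDNA"),
    direction = c("F", "R")
  ) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(panel[, c("snp_id", "reference_allele",
                               "alternate_allele")], by = "snp_id")
  theta <- ifelse(grid$template == "gDNA", config$theta_gdna,
                  ifelse(grid$group == "affected_family",
                         config$theta_family, config$theta_control))
  bias <- ifelse(grid$direction == "F", config$b_F, config$b_R)
  grid$true_log_ratio <- theta + bias
  n <- nrow(grid)
  eps <- with_substream(config$seed, "peak_noise",
                        matrix(stats::rnorm(2 * n, sd = config$noise_sd), ncol = 2))
  keep <- with_substream(config$seed, "direction_dropout",
                         stats::runif(n) >= config$missing_direction_rate)
  artifact <- with_substream(config$seed, "qc_artifacts",
                             stats::runif(n) < config$qc_artifact_rate)
  p <- stats::plogis(grid$true_log_ratio)
  h_ref <- config$base_intensity * p * exp(eps[, 1])
  h_alt <- config$base_intensity * (1 - p) * exp(eps[, 2])
  rev <- grid$direction == "R"
  a1 <- ifelse(rev, iupac_complement(grid$reference_allele),
               grid$reference_allele)
  a2 <- ifelse(rev, iupac_complement(grid$alternate_allele),
               grid$alternate_allele)
  peaks <- tibble::tibble(
    sample_id = grid$sample_id, group = grid$group,
    template = grid$template, direction = grid$direction,
    snp_id = grid$snp_id, allele1 = a1, allele2 = a2,
    height1 = h_ref, height2 = h_alt,
    qc_flags = ifelse(artifact, "simulated_artifact", "")
  )[keep, ]
  truth_meas <- tibble::tibble(
    sample_id = grid$sample_id, snp_id = grid$snp_id,
    group = grid$group, template = grid$template,
    direction = grid$direction, true_log_ratio = grid$true_log_ratio
  )
  group_means <- tidyr::expand_grid(snp_id = panel$snp_id,
                                    comparison_group = c("gDNA", "control",
                                                         "affected_family"))
  group_means$true_mean <- ifelse(
    group_means$comparison_group == "gDNA", config$theta_gdna,
    ifelse(group_means$comparison_group == "affected_family",
           config$theta_family, config$theta_control)
  )
  list(peaks = peaks,
       truth = list(measurements = truth_meas, group_means = group_means),
       config = config)
}

#' Simulate a four-channel Sanger chromatogram
#'
#' Builds a plain-text-dialect chromatogram: one Gaussian peak per base at a
#' regular spacing (amplitude `base_amplitude`), with the two allele channels
#' superposed at the variant position at the configured `allele_heights`.
#' Basecall positions sit at the peak centres; the variant is called as the
#' IUPAC ambiguity code of the two alleles (or the single allele when one
#' height is zero). Optional additive non-negative baseline noise.
#'
#' @param sequence Base string to simulate (the variant position may hold any
#'   placeholder; it is overwritten by the allele call).
#' @param variant_index 1-based position of the variant within `sequence`.
#' @param allele_heights Named numeric vector of length 2: allele base ->
#'   peak amplitude.
#' @param peak_spacing Trace points between adjacent basecalls (default 12).
#' @param peak_sd Gaussian peak SD in trace points (default `spacing / 5`).
#' @param base_amplitude Amplitude of non-variant peaks (default 400).
#' @param noise_floor Scale of additive baseline noise (default 0; noise is
#'   `abs(N(0, noise_floor^2))`, keeping intensities non-negative).
#' @param sample_id,direction Chromatogram identity fields.
#' @param seed Seed for the baseline noise.
#' @return A [chromatogram()].
#' @export
simulate_trace <- function(sequence, variant_index, allele_heights,
                           peak_spacing = 12, peak_sd = peak_spacing / 5,
                           base_amplitude = 400, noise_floor = 0,
                           sample_id = "sim", direction = "F", seed = 1L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty", call. = FALSE)
  variant_index <- as.integer(variant_index)
  if (variant_index < 1L || variant_index > n) {
    stop("variant_index outside sequence", call. = FALSE)
  }
  alleles <- toupper(names(allele_heights))
  if (length(allele_heights) != 2L || is.null(alleles) ||
      !all(alleles %in% c("A", "C", "G", "T")) || alleles[1] == alleles[2]) {
    stop("allele_heights must be a named vector over two distinct bases",
         call. = FALSE)
  }
  if (peak_sd > peak_spacing) {
    warning("peak_sd exceeds peak_spacing: peaks overlap heavily",
            call. = FALSE)
  }
  bases <- strsplit(sequence, "")[[1]]
  centers <- as.integer(round(peak_spacing * seq_len(n)))
  len <- as.integer(round(peak_spacing * (n + 1)))
  x <- seq_len(len)
  trace <- matrix(0, nrow = len, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  add_peak <- function(channel, center, amplitude) {
    if (amplitude <= 0) return()
    trace[, channel] <<- trace[, channel] +
      amplitude * exp(-((x - center)^2) / (2 * peak_sd^2))
  }
  for (i in seq_len(n)) {
    if (i == variant_index) {
      add_peak(alleles[1], centers[i], allele_heights[[1]])
      add_peak(alleles[2], centers[i], allele_heights[[2]])
    } else if (bases[i] %in% c("A", "C", "G", "T")) {
      add_peak(bases[i], centers[i], base_amplitude)
    }
  }
  if (noise_floor > 0) {
    noise <- with_substream(seed, "trace_baseline",
                            abs(stats::rnorm(length(trace),
                                             sd = noise_floor)))
    trace <- trace + matrix(noise, nrow = len)
  }
  call_at_variant <- if (all(allele_heights > 0)) {
    iupac_ambiguity(alleles[1], alleles[2])
  } else {
    alleles[which.max(unlist(allele_heights))]
  }
  bases[variant_index] <- call_at_variant
  chromatogram(trace, centers, paste(bases, collapse = ""),
               sample_id = sample_id, direction = direction)
}

#' Simulate a genotype table with known truth
#'
#' Control genotypes are multinomial draws under Hardy-Weinberg equilibrium
#' at a MAF drawn per SNP from `maf_range`, optionally perturbed by a
#' fixation-index-style disequilibrium `hwe_disequilibrium` (f): genotype
#' probabilities `(p^2 + f*p*q, 2*p*q*(1-f), q^2 + f*p*q)`. Family genotypes
#' are generated by gene-dropping through a fixed three-generation,
#' ten-member pedigree template (founders drawn from the population allele
#' frequency, offspring by Mendelian transmission). Missingness is applied
#' uniformly at `missing_rate`.
#'
#' @param n_snps Number of SNPs.
#' @param n_family Family samples (at most 10, drawn from the pedigree
#'   template).
#' @param n_control Control samples.
#' @param maf_range Length-2 range the per-SNP MAF is drawn from.
#' @param hwe_disequilibrium Fixation-index-style departure from HWE in the
#'   controls (0 = HWE).
#' @param missing_rate Per-call missingness probability.
#' @param seed Root seed.
#' @return List: `genotypes` (a [genotype_table()]) and `truth` (tibble with
#'   per-SNP `maf` and `f`).
#' @export
simulate_genotype_table <- function(n_snps, n_family = 10L, n_control = 18L,
                                    maf_range = c(0.1, 0.5),
                                    hwe_disequilibrium = 0,
                                    missing_rate = 0, seed = 1L) {
  stopifnot(n_snps >= 1, n_family >= 0, n_family <= 10, n_control >= 0,
            missing_rate >= 0, missing_rate <= 1,
            hwe_disequilibrium >= -1, hwe_disequilibrium <= 1)
  # pedigree template: founders 1,2; their children 3,4; married-in founders
  # 5 and 8; grandchildren 6,7 (parents 3+5) and 9,10 (parents 4+8)
  ped <- data.frame(
    id = 1:10,
    father = c(NA, NA, 1, 1, NA, 3, 3, NA, 4, 4),
    mother = c(NA, NA, 2, 2, NA, 5, 5, NA, 8, 8)
  )
  mafs <- with_substream(seed, "maf",
                         stats::runif(n_snps, maf_range[1], maf_range[2]))
  f <- hwe_disequilibrium
  snp_ids <- sprintf("snp%03d", seq_len(n_snps))
  sample_ids <- c(sprintf("FAM%02d", seq_len(n_family)),
                  sprintf("CTRL%02d", seq_len(n_control)))
  calls <- matrix(NA_character_, nrow = n_snps,
                  ncol = n_family + n_control,
                  dimnames = list(snp_ids, sample_ids))
  geno_label <- function(n_minor) c("AA", "AB", "BB")[n_minor + 1L]
  for (i in seq_len(n_snps)) {
    q <- mafs[i]; p <- 1 - q
    if (n_family > 0) {
      fam <- with_substream(seed, paste0("family_", i), {
        alleles <- matrix(NA_integer_, nrow = 10, ncol = 2)
        for (id in ped$id) {
          if (is.na(ped$father[id])) {
            alleles[id, ] <- stats::rbinom(2, 1, q)
          } else {
            alleles[id, 1] <- alleles[ped$father[id], sample(2, 1)]
            alleles[id, 2] <- alleles[ped$mother[id], sample(2, 1)]
          }
        }
        rowSums(alleles)
      })
      calls[i, seq_len(n_family)] <- geno_label(fam[seq_len(n_family)])
    }
    if (n_control > 0) {
      probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      probs <- pmax(probs, 0); probs <- probs / sum(probs)
      ctrl <- with_substream(seed, paste0("control_", i),
                             sample(0:2, n_control, replace = TRUE,
                                    prob = probs))
      calls[i, n_family + seq_len(n_control)] <- geno_label(ctrl)
    }
  }
  if (missing_rate > 0) {
    miss <- with_substream(seed, "missingness",
                           stats::runif(length(calls)) < missing_rate)
    calls[matrix(miss, nrow = n_snps)] <- NA_character_
  }
  groups <- stats::setNames(
    rep(c("affected_family", "control"), c(n_family, n_control)), sample_ids
  )
  list(genotypes = genotype_table(calls, groups),
       truth = tibble::tibble(snp_id = snp_ids, maf = mafs, f = f))
}

#' Simulate a collection of null studies
#'
#' Generates `n_studies` independent peak tables under the global null (all
#' group effects equal), for empirical error-rate estimation of the closed
#' testing procedure. The base configuration's `theta_family`,
#' `theta_control` and `theta_gdna` are all set to `theta`.
#'
#' @param config A [simulation_config()]; its seed is the root seed, study k
#'   uses substream `"null_study_k"`.
#' @param n_studies Number of independent studies.
#' @param theta Common true log fold change (default 0).
#' @return List of `n_studies` simulation results (as from
#'   [simulate_peak_table()]).
#' @export
simulate_null_study <- function(config, n_studies = 1L, theta = 0) {
  stopifnot(inherits(config, "simulation_config"), n_studies >= 1)
  lapply(seq_len(n_studies), function(k) {
    cfg <- config
    cfg$theta_family <- theta
    cfg$theta_control <- theta
    cfg$theta_gdna <- theta
    cfg$seed <- substream_seed(config$seed, paste0("null_study_", k))
    simulate_peak_table(cfg)
  })
}
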