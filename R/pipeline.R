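#' Quantify DAE studies from a peak-height table
#'
#' Splits the peak table by SNP, computes log allelic ratios, orients to the
#' forward-strand reference allele, and centres by the direction-specific
#' gDNA mean — returning one ready-to-test [dae_study()] per SNP in the
#' panel.
#'
#' @param peaks Peak table (tibble or TSV path).
#' @param snp_panel Tibble with `snp_id`, `reference_allele`,
#'   `alternate_allele`.
#' @return Named list of centred [dae_study()] objects.
#' @export
quantify_studies <- function(peaks, snp_panel) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  measurements <- peaks_to_measurements(peaks)
  snp_panel <- tibble::as_tibble(snp_panel)
  studies <- lapply(seq_len(nrow(snp_panel)), function(i) {
    snp <- snp_panel$snp_id[i]
    m <- measurements[measurements$snp_id == snp, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    study <- dae_study(snp, snp_panel$reference_allele[i],
                       snp_panel$alternate_allele[i], m)
    center_by_gdna(study)
  })
  names(studies) <- snp_panel$snp_id
  Filter(Negate(is.null), studies)
}

#' Run the full DAE pipeline
#'
#' Orchestrates screen (optional) -> quantify -> centre -> combine -> test ->
#' report. Inputs are either a simulation configuration (the study is
#' generated) or a peak table plus SNP panel; a genotype table adds the
#' upstream screening stage, whose analyzable set then restricts the SNPs
#' tested.
#'
#' @param peaks Peak table (tibble or TSV path); ignored when `sim_config`
#'   is given.
#' @param snp_panel SNP panel tibble (default [dyslexia_snp_panel()]; when
#'   simulating, the simulation's own panel).
#' @param sim_config Optional [simulation_config()]; when given, peaks are
#'   simulated from it.
#' @param genotypes Optional [genotype_table()] for the screening stage.
#' @param expressed_flags Optional named logical vector for the expression
#'   gate.
#' @param screen_cfg A [screen_config()].
#' @param alpha Significance level.
#' @param analysis_sets Analysis sets to test.
#' @param method Test method (see [closed_test_posthoc()]).
#' @return List: `screen_report` (or NULL), `studies`, `measurements`,
#'   `association`, `manifest`.
#' @export
run_pipeline <- function(peaks = NULL, snp_panel = dyslexia_snp_panel(),
                         sim_config = NULL, genotypes = NULL,
                         expressed_flags = NULL,
                         screen_cfg = screen_config(), alpha = 0.05,
                         analysis_sets = c("F", "R", "F&R"),
                         method = "auto") {
  stages <- list()
  truth <- NULL
  if (!is.null(sim_config)) {
    sim <- simulate_peak_table(sim_config)
    peaks <- sim$peaks
    truth <- sim$truth
    snp_panel <- sim_config$snp_panel
    stages$simulate <- list(n_rows = nrow(peaks),
                            seed = sim_config$seed)
  }
  if (is.null(peaks)) {
    stop("pipeline needs either a peak table or a simulation config",
         call. = FALSE)
  }
  if (is.character(peaks)) peaks <- read_peak_table(peaks)

  screen_report <- NULL
  if (!is.null(genotypes)) {
    screen_report <- screen_snps(genotypes, screen_cfg, expressed_flags)
    analyzable <- if (!is.null(expressed_flags)) {
      screen_report$snp_id[screen_report$analyzable %in% TRUE]
    } else {
      screen_report$snp_id[screen_report$eligible %in% TRUE]
    }
    stages$screen <- list(
      n_candidates = nrow(screen_report),
      n_qc_pass = sum(screen_report$qc_pass),
      n_eligible = sum(screen_report$eligible %in% TRUE),
      n_analyzable = length(analyzable)
    )
    snp_panel <- snp_panel[snp_panel$snp_id %in% analyzable, , drop = FALSE]
    if (nrow(snp_panel) == 0L) {
      stop("screening stage left no analyzable SNPs in the panel",
           call. = FALSE)
    }
  }

  studies <- quantify_studies(peaks, snp_panel)
  if (length(studies) == 0L) {
    stop("quantification stage produced no studies (no usable peak rows)",
         call. = FALSE)
  }
  stages$quantify <- list(
    n_snps = length(studies),
    n_measurements = sum(vapply(studies,
                                function(s) nrow(s$measurements), 1L))
  )
  association <- dae_association_table(studies, alpha = alpha,
                                       analysis_sets = analysis_sets,
                                       method = method)
  stages$test <- list(n_rows = nrow(association), alpha = alpha)

  measurements <- dplyr::bind_rows(lapply(studies,
                                          function(s) s$measurements))
  manifest <- list(
    tool = "daequant",
    version = as.character(utils::packageVersion("daequant")),
    seed = if (!is.null(sim_config)) sim_config$seed else NA_integer_,
    alpha = alpha,
    analysis_sets = analysis_sets,
    stages = stages
  )
  list(screen_report = screen_report, studies = studies,
       measurements = measurements, association = association,
       truth = truth, manifest = manifest)
}

#' Render an association table
#'
#' Writes the association table as TSV, JSON, or a human-readable text
#' report. The text layout mirrors the standard DAE report: mean (SD) per
#' comparison group, the global p-value with a significance asterisk, and
#' the three post-hoc p-values — left blank when the global test does not
#' reject, as the closed procedure then makes no pairwise claims.
#'
#' @param association Tibble from [dae_association_table()].
#' @param format `"tsv"`, `"text"` or `"json"`.
#' @param path Output file; when `NULL`, the rendered lines (text) or string
#'   (json) are returned invisibly without writing.
#' @return The path (or rendered content when `path` is NULL), invisibly.
#' @export
render_report <- function(association, format = c("tsv", "text", "json"),
                          path = NULL) {
  format <- match.arg(format)
  if (nrow(association) == 0L) stop("association table is empty",
                                    call. = FALSE)
  if (format == "tsv") {
    if (is.null(path)) stop("tsv rendering needs a path", call. = FALSE)
    utils::write.table(association, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (format == "json") {
    out <- jsonlite::toJSON(association, digits = NA, na = "null",
                            pretty = TRUE)
    if (!is.null(path)) {
      writeLines(out, path)
      return(invisible(path))
    }
    return(invisible(out))
  }
  msd <- function(m, s) {
    ifelse(is.na(m), "-",
           sprintf("%.2f (%.2f)", m, ifelse(is.na(s), 0, s)))
  }
  star <- function(p, gate = TRUE) {
    gate <- rep_len(gate, length(p))
    ifelse(!gate, "",
           sprintf("%.4g%s", p, ifelse(p < association$alpha, "*", "")))
  }
  gate <- association$global_p < association$alpha
  lines <- c(
    paste("SNP", "set", "gDNA", "cDNA controls", "cDNA family", "n (g/c/f)",
          "global p", "ctrl vs fam", "fam vs gDNA", "ctrl vs gDNA",
          sep = "\t"),
    paste(association$snp_id, association$analysis_set,
          msd(association$mean_gdna, association$sd_gdna),
          msd(association$mean_control, association$sd_control),
          msd(association$mean_family, association$sd_family),
          sprintf("%d/%d/%d", association$n_gdna, association$n_control,
                  association$n_family),
          star(association$global_p),
          star(association$p_control_vs_family, gate),
          star(association$p_family_vs_gdna, gate),
          star(association$p_control_vs_gdna, gate),
          sep = "\t")
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  invisible(lines)
}

#' Re-run the association analysis under a different stratification
#'
#' Relabels the cDNA comparison groups by an arbitrary per-sample stratum
#' (e.g. sex, or affection status within the family) and re-runs the closed
#' testing analysis — no bespoke statistics, just group relabelling.
#' The gDNA reference group is unaffected.
#'
#' @param study A centred [dae_study()].
#' @param strata Named character vector: sample_id -> stratum label (exactly
#'   two distinct labels among the study's cDNA samples).
#' @param alpha,analysis_sets,method As in [dae_association_table()].
#' @return Association tibble with the strata as the two cDNA groups.
#' @export
stratified_association <- function(study, strata, alpha = 0.05,
                                   analysis_sets = c("F", "R", "F&R"),
                                   method = "auto") {
  stopifnot(inherits(study, "dae_study"))
  m <- study$measurements
  lab <- strata[m$sample_id]
  if (anyNA(lab[m$template == "cDNA"])) {
    stop("every cDNA sample needs a stratum label", call. = FALSE)
  }
  lev <- unique(lab[m$template == "cDNA"])
  if (length(lev) != 2L) {
    stop("stratified analysis needs exactly two strata; got ",
         length(lev), call. = FALSE)
  }
  # map strata onto the two cDNA group slots of the three-group design
  m$group <- ifelse(lab == lev[1], "affected_family", "control")
  relabelled <- study
  relabelled$measurements <- m
  out <- dae_association_table(list(relabelled), alpha = alpha,
                               analysis_sets = analysis_sets,
                               method = method)
  attr(out, "strata_levels") <- c(family_slot = lev[1], control_slot = lev[2])
  out
}

#' Empirical family-wise error rate of the closed procedure
#'
#' Runs the full quantify-centre-combine-test pipeline on each simulated null
#' study and reports the proportion of studies in which the closed testing
#' procedure declares any pairwise comparison significant.
#'
#' @param config A [simulation_config()] (its thetas are forced equal).
#' @param n_studies Number of null studies.
#' @param alpha Significance level.
#' @param analysis_set Analysis set the error rate is computed on.
#' @param theta Common null effect.
#' @return List: `fwer`, `n_studies`, `rejections` (logical vector).
#' @export
estimate_fwer <- function(config, n_studies = 2000L, alpha = 0.05,
                          analysis_set = "F&R", theta = 0) {
  sims <- simulate_null_study(config, n_studies, theta = theta)
  rejections <- vapply(sims, function(sim) {
    studies <- suppressMessages(
      quantify_studies(sim$peaks, config$snp_panel)
    )
    assoc <- dae_association_table(studies, alpha = alpha,
                                   analysis_sets = analysis_set)
    any(assoc$sig_control_vs_family | assoc$sig_family_vs_gdna |
          assoc$sig_control_vs_gdna)
  }, TRUE)
  list(fwer = mean(rejections), n_studies = n_studies,
       rejections = rejections)
}
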