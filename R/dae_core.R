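#' Natural-log allelic ratio of a peak pair
#'
#' The raw per-measurement statistic: `r = ln(height1 / height2)`, the natural
#' log of the ratio of the two allele peak heights. Both heights must be
#' strictly positive; a zero height means the site is uninformative (or
#' homozygous) and the measurement is excluded upstream.
#'
#' @param pair A [peak_pair()], or a numeric `height1` when `height2` is given.
#' @param height2 Second allele height when `pair` is numeric.
#' @return The log allelic ratio (dimensionless).
#' @export
log_allelic_ratio <- function(pair, height2 = NULL) {
  if (inherits(pair, "peak_pair")) {
    h1 <- pair$height1; h2 <- pair$height2
  } else {
    h1 <- pair; h2 <- height2
  }
  if (any(h1 <= 0) || any(h2 <= 0)) {
    stop("log allelic ratio undefined: both peak heights must be > 0",
         call. = FALSE)
  }
  log(h1 / h2)
}

measurement_columns <- c("sample_id", "snp_id", "group", "template",
                         "direction", "allele1", "allele2", "r", "oriented",
                         "rho")

#' Convert a peak-height table to allelic measurements
#'
#' Computes the raw log allelic ratio for every QC-passing row with two
#' positive heights. Rows that fail QC or have a non-positive height are
#' dropped (with a message naming how many).
#'
#' @param peaks Peak table as from [read_peak_table()] or
#'   [simulate_peak_table()].
#' @return Tibble of measurements: `sample_id`, `snp_id`, `group`,
#'   `template`, `direction`, `allele1`, `allele2`, `r` (raw ln ratio),
#'   `oriented` (FALSE), `rho` (NA until centred).
#' @export
peaks_to_measurements <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (is.null(peaks$qc_flags)) peaks$qc_flags <- ""
  flagged <- nzchar(peaks$qc_flags) & !is.na(peaks$qc_flags)
  nonpos <- peaks$height1 <= 0 | peaks$height2 <= 0
  drop <- flagged | nonpos
  if (any(drop)) {
    message(sprintf("dropping %d of %d peak rows (%d QC-flagged, %d with a non-positive height)",
                    sum(drop), nrow(peaks), sum(flagged), sum(nonpos & !flagged)))
  }
  kept <- peaks[!drop, , drop = FALSE]
  tibble::tibble(
    sample_id = kept$sample_id,
    snp_id = kept$snp_id,
    group = kept$group,
    template = kept$template,
    direction = kept$direction,
    allele1 = toupper(kept$allele1),
    allele2 = toupper(kept$allele2),
    r = log(kept$height1 / kept$height2),
    oriented = FALSE,
    rho = NA_real_
  )
}

#' Construct a DAE study for one SNP
#'
#' Bundles the measurements of a single SNP with its forward-strand allele
#' pair. The reference allele is the numerator of every oriented ratio, so a
#' positive corrected ratio means the reference allele is the more expressed
#' one.
#'
#' @param snp_id SNP identifier; measurements for other SNPs are rejected.
#' @param reference_allele,alternate_allele Distinct forward-strand bases.
#' @param measurements Measurement tibble (see [peaks_to_measurements()]).
#' @return A `dae_study` object.
#' @export
dae_study <- function(snp_id, reference_allele, alternate_allele,
                      measurements) {
  reference_allele <- toupper(reference_allele)
  alternate_allele <- toupper(alternate_allele)
  if (reference_allele == alternate_allele) {
    stop("reference and alternate allele must differ", call. = FALSE)
  }
  measurements <- tibble::as_tibble(measurements)
  missing <- setdiff(measurement_columns, names(measurements))
  if (length(missing) > 0L) {
    stop("measurements missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(measurements$snp_id == snp_id)) {
    stop("measurements contain rows for other SNPs", call. = FALSE)
  }
  if (any(!is.finite(measurements$r))) {
    stop("all raw log ratios must be finite", call. = FALSE)
  }
  structure(
    list(snp_id = snp_id,
         reference_allele = reference_allele,
         alternate_allele = alternate_allele,
         measurements = measurements,
         gdna_means = NULL),
    class = "dae_study"
  )
}

#' @export
print.dae_study <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("<dae_study> %s (%s/%s): %d measurements (%d cDNA, %d gDNA)%s\n",
              x$snp_id, x$reference_allele, x$alternate_allele, nrow(m),
              sum(m$template == "cDNA"), sum(m$template == "gDNA"),
              if (is.null(x$gdna_means)) "" else ", centred"))
  invisible(x)
}

#' Orient one measurement to the forward-strand reference allele
#'
#' Reverse-strand reads report complementary bases: their alleles are
#' complemented back to forward-strand bases. If the resulting numerator
#' allele is the alternate rather than the reference, the ratio is negated
#' and the alleles swapped. Orienting an already-oriented measurement is the
#' identity.
#'
#' @param m One measurement (one-row tibble or named list) with fields
#'   `direction`, `allele1`, `allele2`, `r`, `oriented`.
#' @param reference_allele,alternate_allele Forward-strand allele pair.
#' @return The measurement with forward-strand alleles, reference-first, and
#'   `oriented = TRUE`.
#' @export
orient_measurement <- function(m, reference_allele, alternate_allele) {
  if (isTRUE(m$oriented)) return(m)
  a1 <- toupper(m$allele1); a2 <- toupper(m$allele2)
  if (identical(m$direction, "R")) {
    a1 <- iupac_complement(a1)
    a2 <- iupac_complement(a2)
  }
  ref <- toupper(reference_allele); alt <- toupper(alternate_allele)
  if (a1 == ref && a2 == alt) {
    # reference already in the numerator
  } else if (a1 == alt && a2 == ref) {
    tmp <- a1; a1 <- a2; a2 <- tmp
    m$r <- -m$r
  } else {
    stop(sprintf("observed alleles %s/%s (forward-strand %s/%s) do not match SNP alleles %s/%s",
                 m$allele1, m$allele2, a1, a2, ref, alt), call. = FALSE)
  }
  m$allele1 <- a1
  m$allele2 <- a2
  m$oriented <- TRUE
  m
}

#' Orient every measurement of a study
#'
#' Vectorised application of [orient_measurement()] over the study's
#' measurement table.
#'
#' @param study A [dae_study()].
#' @return The study with all measurements oriented.
#' @export
orient_study <- function(study) {
  stopifnot(inherits(study, "dae_study"))
  m <- study$measurements
  if (nrow(m) == 0L) return(study)
  ref <- study$reference_allele; alt <- study$alternate_allele
  todo <- !m$oriented
  a1 <- m$allele1; a2 <- m$allele2
  rev <- todo & m$direction == "R"
  a1[rev] <- iupac_complement(a1[rev])
  a2[rev] <- iupac_complement(a2[rev])
  ok_fwd <- a1 == ref & a2 == alt
  ok_swap <- a1 == alt & a2 == ref
  bad <- todo & !(ok_fwd | ok_swap)
  if (any(bad)) {
    stop(sprintf("%d measurements have alleles inconsistent with %s/%s (first: %s/%s %s)",
                 sum(bad), ref, alt, m$allele1[which(bad)[1]],
                 m$allele2[which(bad)[1]], m$direction[which(bad)[1]]),
         call. = FALSE)
  }
  flip <- todo & ok_swap
  m$r[flip] <- -m$r[flip]
  m$allele1[todo] <- ref
  m$allele2[todo] <- alt
  m$oriented <- TRUE
  study$measurements <- m
  study
}

#' Centre measurements by the assay-specific gDNA mean
#'
#' Genomic DNA from heterozygous individuals carries a true 1:1 allele ratio,
#' so the mean oriented gDNA log ratio per sequencing direction estimates the
#' direction-specific assay (dye) bias. That mean is subtracted from every
#' measurement of the same direction, cDNA and gDNA alike:
#' `rho = r_oriented - gdna_mean[direction]`. After centring, the corrected
#' gDNA ratios of each direction average exactly zero.
#'
#' Centring pools the gDNA measurements of all samples (family and controls)
#' into one reference group per direction.
#'
#' @param study An oriented [dae_study()] (un-oriented studies are oriented
#'   first).
#' @return The study with `rho` filled in and `gdna_means` recorded
#'   (named vector, one entry per direction present).
#' @export
center_by_gdna <- function(study) {
  stopifnot(inherits(study, "dae_study"))
  study <- orient_study(study)
  m <- study$measurements
  dirs <- unique(m$direction)
  gmeans <- vapply(dirs, function(d) {
    g <- m$r[m$template == "gDNA" & m$direction == d]
    if (length(g) == 0L) {
      stop("no gDNA measurement for direction ", d,
           ": cannot centre that direction", call. = FALSE)
    }
    mean(g)
  }, 1)
  names(gmeans) <- dirs
  m$rho <- m$r - unname(gmeans[m$direction])
  study$measurements <- m
  study$gdna_means <- gmeans
  study
}

#' Combine sequencing directions per sample
#'
#' For each sample and template, the combined corrected ratio is the mean of
#' the available per-direction corrected ratios. A sample with only one
#' passing direction contributes that single value, so the per-direction and
#' combined analyses can have different sample compositions.
#'
#' @param study A centred [dae_study()].
#' @return Tibble with one row per sample and template: `sample_id`, `group`,
#'   `template`, `rho`, `n_directions`, `analysis_set = "F&R"`.
#' @export
combine_directions <- function(study) {
  stopifnot(inherits(study, "dae_study"))
  if (is.null(study$gdna_means)) {
    stop("centre the study first (center_by_gdna)", call. = FALSE)
  }
  study$measurements |>
    dplyr::group_by(.data$sample_id, .data$group, .data$template) |>
    dplyr::summarise(rho = mean(.data$rho),
                     n_directions = dplyr::n_distinct(.data$direction),
                     .groups = "drop") |>
    dplyr::mutate(analysis_set = "F&R")
}

#' Corrected ratios for one analysis set
#'
#' `"F"` and `"R"` select the single-direction measurements; `"F&R"` returns
#' the per-sample direction averages from [combine_directions()].
#'
#' @param study A centred [dae_study()].
#' @param analysis_set One of `"F"`, `"R"`, `"F&R"`.
#' @return Tibble with columns `sample_id`, `group`, `template`, `rho`,
#'   `analysis_set`.
#' @export
analysis_set_values <- function(study, analysis_set = c("F&R", "F", "R")) {
  analysis_set <- match.arg(analysis_set)
  if (is.null(study$gdna_means)) {
    stop("centre the study first (center_by_gdna)", call. = FALSE)
  }
  if (analysis_set == "F&R") {
    return(combine_directions(study)[, c("sample_id", "group", "template",
                                         "rho", "analysis_set")])
  }
  m <- study$measurements
  m <- m[m$direction == analysis_set, , drop = FALSE]
  tibble::tibble(sample_id = m$sample_id, group = m$group,
                 template = m$template, rho = m$rho,
                 analysis_set = analysis_set)
}

#' Analysis group of a measurement
#'
#' gDNA measurements form their own comparison group regardless of the donor's
#' cohort; cDNA measurements keep the donor group.
#'
#' @param template,group Vectors of template and sample group labels.
#' @return Character vector of analysis group labels.
#' @export
analysis_group <- function(template, group) {
  ifelse(template == "gDNA", "gDNA", group)
}

#' Group means and SDs of corrected allelic ratios for one SNP
#'
#' Summarises one analysis set into the three comparison groups: pooled gDNA,
#' cDNA controls, cDNA affected family. Groups with no data are reported with
#' `NA`, never silent zeros.
#'
#' @param study A centred [dae_study()].
#' @param analysis_set One of `"F"`, `"R"`, `"F&R"`.
#' @return Tibble: `snp_id`, `analysis_set`, `comparison_group`, `n`, `mean`,
#'   `sd` (sample SD; `NA` when `n < 2`).
#' @export
summarize_snp <- function(study, analysis_set = c("F&R", "F", "R")) {
  analysis_set <- match.arg(analysis_set)
  vals <- analysis_set_values(study, analysis_set)
  vals$comparison_group <- analysis_group(vals$template, vals$group)
  groups <- c("gDNA", "control", "affected_family")
  out <- lapply(groups, function(g) {
    x <- vals$rho[vals$comparison_group == g]
    tibble::tibble(
      snp_id = study$snp_id, analysis_set = analysis_set,
      comparison_group = g, n = length(x),
      mean = if (length(x) > 0) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_
    )
  })
  dplyr::bind_rows(out)
}

#' Strip chart of corrected allelic ratios by group
#'
#' Simple per-SNP dot plot of the corrected log allelic ratios in the three
#' comparison groups, one panel per analysis set. Requires ggplot2.
#'
#' @param study A centred [dae_study()].
#' @param analysis_sets Analysis sets to show.
#' @return A ggplot object.
#' @export
dae_strip_chart <- function(study, analysis_sets = c("F", "R", "F&R")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  vals <- dplyr::bind_rows(lapply(analysis_sets, analysis_set_values,
                                  study = study))
  vals$comparison_group <- analysis_group(vals$template, vals$group)
  vals$analysis_set <- factor(vals$analysis_set, levels = analysis_sets)
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$comparison_group,
                                     y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.8) +
    ggplot2::facet_wrap(~analysis_set) +
    ggplot2::labs(x = NULL, y = "corrected log allelic ratio",
                  title = study$snp_id) +
    ggplot2::theme_minimal()
}
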