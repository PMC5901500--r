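#' Hardy-Weinberg equilibrium exact test (Levene-Haldane)
#'
#' Conditional on the observed allele counts, the probability of each possible
#' heterozygote count under Hardy-Weinberg equilibrium is
#' `P(nAB) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!`,
#' computed in log space. The p-value sums the probabilities of all outcomes
#' no more probable than the observed one (the standard two-sided exact
#' convention for this test).
#'
#' @param nAA,nAB,nBB Non-negative genotype counts; at least one positive.
#' @return The exact p-value.
#' @export
hwe_exact_p <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("counts must be non-negative",
                                      call. = FALSE)
  n <- nAA + nAB + nBB
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_a <- 2 * nAA + nAB           # count of allele A
  n_b <- 2 * nBB + nAB
  # feasible heterozygote counts share the parity of the minor allele count
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  log_prob <- lgamma(n + 1) -
    lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) - lgamma((n_b - h) / 2 + 1) +
    h * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  obs <- log_prob[h == nAB]
  sum(exp(log_prob[log_prob <= obs + 1e-12]))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test against the genotype
#' frequencies expected from the observed allele frequencies. Offered as the
#' large-sample alternative to [hwe_exact_p()]; unreliable for cohorts of a
#' few dozen samples.
#'
#' @inheritParams hwe_exact_p
#' @return The asymptotic p-value.
#' @export
hwe_chisq_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  p <- (2 * nAA + nAB) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expected == 0)) return(1)  # monomorphic
  x2 <- sum((c(nAA, nAB, nBB) - expected)^2 / expected)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Construct a genotype table
#'
#' @param calls Character matrix, SNPs in rows and samples in columns, entries
#'   `"AA"`, `"AB"`, `"BB"` or `NA` (missing). Row names are SNP ids, column
#'   names sample ids.
#' @param groups Named character vector mapping sample id to group
#'   (`"affected_family"` or `"control"`).
#' @param alleles Optional tibble with `snp_id`, `allele_a`, `allele_b`
#'   (forward-strand bases).
#' @return A `genotype_table` object.
#' @export
genotype_table <- function(calls, groups, alleles = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have SNP row names and sample column names",
         call. = FALSE)
  }
  ok <- is.na(calls) | calls %in% c("AA", "AB", "BB")
  if (!all(ok)) {
    stop("genotype calls must be AA/AB/BB or NA; offending value: ",
         calls[which(!ok)[1]], call. = FALSE)
  }
  groups <- groups[colnames(calls)]
  if (anyNA(groups)) {
    stop("every sample needs a group label", call. = FALSE)
  }
  bad <- setdiff(unique(groups), c("affected_family", "control"))
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(calls = calls, groups = groups, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d SNPs x %d samples (%d family, %d control)\n",
              nrow(x$calls), ncol(x$calls),
              sum(x$groups == "affected_family"), sum(x$groups == "control")))
  invisible(x)
}

#' Default screening thresholds
#'
#' HWE exact p (Bonferroni-adjusted across the SNPs tested) must exceed
#' `hwe_alpha`; call rate must exceed `min_call_rate`; MAF must exceed
#' `min_maf`; and at least `min_het_per_group` heterozygous samples are
#' required in each of the two groups for DAE eligibility.
#'
#' @param hwe_alpha HWE significance level (default 0.05).
#' @param hwe_bonferroni Apply Bonferroni correction across SNPs (default
#'   TRUE).
#' @param min_call_rate Minimum SNP-wise call rate, exclusive (default 0.97).
#' @param min_maf Minimum minor allele frequency, exclusive (default 0.05).
#' @param min_het_per_group Minimum heterozygotes per group, inclusive
#'   (default 3).
#' @param hwe_test `"exact"` (Levene-Haldane) or `"chisq"`.
#' @return A list of thresholds (class `screen_config`).
#' @export
screen_config <- function(hwe_alpha = 0.05, hwe_bonferroni = TRUE,
                          min_call_rate = 0.97, min_maf = 0.05,
                          min_het_per_group = 3L,
                          hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  stopifnot(hwe_alpha > 0, hwe_alpha < 1,
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf < 0.5,
            min_het_per_group >= 0)
  structure(list(hwe_alpha = hwe_alpha, hwe_bonferroni = hwe_bonferroni,
                 min_call_rate = min_call_rate, min_maf = min_maf,
                 min_het_per_group = as.integer(min_het_per_group),
                 hwe_test = hwe_test),
            class = "screen_config")
}

#' Per-SNP genotype quality control
#'
#' Computes per SNP: call rate, minor allele frequency among called
#' genotypes, HWE p-value (Bonferroni-adjusted across all SNPs entering QC:
#' adjusted p = min(1, m * p)), and the overall pass flag
#' `(adjusted HWE p > hwe_alpha) & (call_rate > min_call_rate) &
#' (maf > min_maf)`. A report, never an error.
#'
#' @param table A [genotype_table()].
#' @param config A [screen_config()].
#' @return Tibble: `snp_id`, `n_called`, `call_rate`, `maf`, `hwe_p`,
#'   `hwe_p_adj`, `qc_pass`.
#' @export
genotype_qc <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "genotype_table"))
  calls <- table$calls
  m <- nrow(calls)
  hwe_fun <- if (config$hwe_test == "exact") hwe_exact_p else hwe_chisq_p
  rows <- lapply(seq_len(m), function(i) {
    x <- calls[i, ]
    called <- x[!is.na(x)]
    nAA <- sum(called == "AA"); nAB <- sum(called == "AB")
    nBB <- sum(called == "BB")
    n_called <- length(called)
    maf <- if (n_called == 0) NA_real_ else {
      fa <- (2 * nAA + nAB) / (2 * n_called)
      min(fa, 1 - fa)
    }
    hwe_p <- if (n_called == 0) NA_real_ else hwe_fun(nAA, nAB, nBB)
    tibble::tibble(snp_id = rownames(calls)[i], n_called = n_called,
                   call_rate = n_called / ncol(calls), maf = maf,
                   hwe_p = hwe_p)
  })
  rep <- dplyr::bind_rows(rows)
  mult <- if (config$hwe_bonferroni) m else 1L
  rep$hwe_p_adj <- pmin(1, mult * rep$hwe_p)
  rep$qc_pass <- !is.na(rep$hwe_p_adj) &
    rep$hwe_p_adj > config$hwe_alpha &
    rep$call_rate > config$min_call_rate &
    !is.na(rep$maf) & rep$maf > config$min_maf
  rep
}

#' Heterozygote-count eligibility filter
#'
#' A SNP is eligible for DAE analysis iff it has at least
#' `min_het_per_group` heterozygous samples in each of the two groups —
#' heterozygotes are the only samples informative for within-sample allelic
#' comparison.
#'
#' @param table A [genotype_table()].
#' @param config A [screen_config()].
#' @return Tibble: `snp_id`, `het_family`, `het_control`, `eligible`.
#' @export
eligibility_filter <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "genotype_table"))
  het <- !is.na(table$calls) & table$calls == "AB"
  fam <- table$groups == "affected_family"
  tibble::tibble(
    snp_id = rownames(table$calls),
    het_family = as.integer(rowSums(het[, fam, drop = FALSE])),
    het_control = as.integer(rowSums(het[, !fam, drop = FALSE])),
    eligible = rowSums(het[, fam, drop = FALSE]) >= config$min_het_per_group &
      rowSums(het[, !fam, drop = FALSE]) >= config$min_het_per_group
  )
}

#' Expression gate
#'
#' Intersects the eligible SNPs with externally supplied expression flags
#' (whether the SNP-bearing transcript is detectably expressed in the assayed
#' cells — a wet-lab determination this package cannot make). Flags for
#' unknown SNPs are ignored with a warning; a missing flag for an eligible
#' SNP is an error.
#'
#' @param snp_ids Character vector of eligible SNP ids.
#' @param expressed_flags Named logical vector, names are SNP ids.
#' @return Character vector of analyzable SNP ids.
#' @export
expression_gate <- function(snp_ids, expressed_flags) {
  unknown <- setdiff(names(expressed_flags), snp_ids)
  if (length(unknown) > 0L) {
    warning("ignoring expression flags for unknown SNP(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(snp_ids, names(expressed_flags))
  if (length(missing) > 0L) {
    stop("no expression flag for eligible SNP(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  snp_ids[expressed_flags[snp_ids]]
}

#' Full SNP screening report
#'
#' Runs genotype QC, the heterozygote eligibility filter and (optionally) the
#' expression gate, and returns one combined row per SNP — the screening
#' cascade from candidate SNPs down to the analyzable set.
#'
#' @param table A [genotype_table()].
#' @param config A [screen_config()].
#' @param expressed_flags Optional named logical vector of expression flags;
#'   when absent, `expressed` and `analyzable` are `NA`.
#' @return Tibble: QC columns plus `het_family`, `het_control`, `qc_pass`,
#'   `eligible`, `expressed`, `analyzable`.
#' @export
screen_snps <- function(table, config = screen_config(),
                        expressed_flags = NULL) {
  qc <- genotype_qc(table, config)
  el <- eligibility_filter(table, config)
  rep <- dplyr::left_join(qc, el, by = "snp_id")
  rep$eligible <- rep$eligible & rep$qc_pass
  if (is.null(expressed_flags)) {
    rep$expressed <- NA
    rep$analyzable <- NA
  } else {
    analyzable <- expression_gate(rep$snp_id[rep$eligible], expressed_flags)
    rep$expressed <- unname(expressed_flags[rep$snp_id])
    rep$analyzable <- rep$eligible & rep$snp_id %in% analyzable
  }
  rep
}

#' Read and write genotype tables as TSV matrices
#'
#' The TSV dialect: first column `snp_id`, remaining columns one per sample
#' with calls `AA`/`AB`/`BB` or empty for missing; sample-to-group mapping in
#' a two-column TSV (`sample_id`, `group`).
#'
#' @param path Genotype matrix TSV path.
#' @param groups_path Sample-group TSV path.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, groups_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "snp_id") {
    stop("genotype TSV must start with an snp_id column", call. = FALSE)
  }
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$snp_id
  calls[calls == ""] <- NA_character_
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  genotype_table(calls, stats::setNames(g$group, g$sample_id))
}

#' @rdname read_genotype_table
#' @param table A [genotype_table()] to write.
#' @export
write_genotype_table <- function(table, path, groups_path) {
  stopifnot(inherits(table, "genotype_table"))
  df <- data.frame(snp_id = rownames(table$calls), table$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(
    data.frame(sample_id = names(table$groups), group = unname(table$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
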