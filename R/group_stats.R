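# cache of combination index matrices, keyed by "n,k" — the exact Wilcoxon
# enumerates C(n, k) subsets and the same shapes recur across simulations
.enum_cache <- new.env(parent = emptyenv())

cached_combn <- function(n, k) {
  key <- paste(n, k, sep = ",")
  if (is.null(.enum_cache[[key]])) {
    .enum_cache[[key]] <- utils::combn(n, k)
  }
  .enum_cache[[key]]
}

#' Kruskal-Wallis statistic on midranks with tie correction
#'
#' @param values Numeric vector of observations.
#' @param labels Group label per observation.
#' @return The tie-corrected H statistic (0 when all values are tied).
#' @export
kw_statistic <- function(values, labels) {
  n <- length(values)
  ranks <- rank(values)
  rank_sums <- tapply(ranks, labels, sum)
  sizes <- tapply(ranks, labels, length)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) return(0)  # every observation tied
  h / correction
}

# all ways to partition indices `idx` into ordered groups of the given sizes;
# returns a list of integer label vectors aligned with idx order
enumerate_partitions <- function(idx, sizes) {
  if (length(sizes) == 1L) {
    lab <- integer(max(idx))
    return(list(idx))
  }
  out <- list()
  first <- utils::combn(idx, sizes[1], simplify = FALSE)
  for (s in first) {
    rest <- enumerate_partitions(setdiff(idx, s), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(s, r)))
  }
  out
}

#' Kruskal-Wallis test p-value (exact or asymptotic)
#'
#' The global test for a location difference among k groups of corrected
#' allelic ratios. `method = "exact"` enumerates every assignment of the
#' pooled observations to the observed group sizes and reports the proportion
#' of assignments with H at least as large as observed; when the number of
#' assignments exceeds `max_enumeration` a complete-randomisation Monte Carlo
#' with `n_mc` permutations is used instead. `method = "asymptotic"` uses the
#' chi-square reference with k-1 degrees of freedom. `"auto"` picks exact for
#' total n at most 12.
#'
#' @param groups Named list of numeric vectors, one per group (at least 2,
#'   each non-empty).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @param max_enumeration Assignment-count cap above which exact switches to
#'   Monte Carlo.
#' @param n_mc Number of Monte Carlo permutations.
#' @return The two-sided p-value.
#' @export
kruskal_wallis_p <- function(groups, method = c("auto", "exact", "asymptotic"),
                             max_enumeration = 2e5, n_mc = 10000) {
  method <- match.arg(method)
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  if (method == "auto") method <- if (n <= 12L) "exact" else "asymptotic"
  h_obs <- kw_statistic(values, labels)
  if (method == "asymptotic") {
    return(stats::pchisq(h_obs, df = length(groups) - 1L, lower.tail = FALSE))
  }
  sizes <- lengths(groups)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  eps <- 1e-9
  if (n_assign <= max_enumeration) {
    parts <- enumerate_partitions(seq_len(n), sizes)
    lab_template <- rep(seq_along(sizes), sizes)
    h_all <- vapply(parts, function(ord) {
      lab <- integer(n)
      lab[ord] <- lab_template
      kw_statistic(values, lab)
    }, 1)
    mean(h_all >= h_obs - eps)
  } else {
    h_mc <- vapply(seq_len(n_mc), function(i) {
      kw_statistic(values, sample(labels))
    }, 1)
    (1 + sum(h_mc >= h_obs - eps)) / (1 + n_mc)
  }
}

wilcoxon_tie_corrected_sd <- function(pooled, n_a, n_b) {
  n <- n_a + n_b
  ties <- table(pooled)
  v <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  sqrt(max(v, 0))
}

#' Two-sided Wilcoxon rank-sum p-value (exact or asymptotic)
#'
#' Rank-sum statistic on midranks. `method = "exact"` enumerates all
#' `C(n_a + n_b, n_a)` assignments of the pooled midranks to the first group;
#' the two-sided p-value doubles the smaller tail probability (capped at 1).
#' `method = "asymptotic"` uses the normal approximation with tie-corrected
#' variance and no continuity correction. `"auto"` picks exact for
#' `n_a + n_b` at most 20.
#'
#' An alternative exact two-sided convention sums the probability of outcomes
#' at least as extreme in both tails; tail-doubling is used here because it is
#' well defined for asymmetric enumeration distributions under ties.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return The two-sided p-value.
#' @export
wilcoxon_ranksum_p <- function(a, b, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (method == "auto") method <- if (n <= 20L) "exact" else "asymptotic"
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_a)])
  if (method == "asymptotic") {
    sd_w <- wilcoxon_tie_corrected_sd(pooled, n_a, n_b)
    if (sd_w == 0) return(1)
    z <- (w_obs - n_a * (n + 1) / 2) / sd_w
    return(2 * stats::pnorm(-abs(z)))
  }
  idx <- cached_combn(n, n_a)
  w_all <- colSums(matrix(ranks[idx], nrow = n_a))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Closed-testing decisions for the three-group design
#'
#' The decision rule of the closed testing procedure for exactly three
#' groups: a pairwise comparison is declared significant iff its own p-value
#' and the global p-value are both below `alpha`. (With three groups every
#' intersection hypothesis containing two pairwise nulls equals the global
#' null, so the closure collapses to gating each pairwise test on the global
#' test.) Pairwise p-values are reported raw; the multiplicity control lives
#' in the decisions.
#'
#' @param global_p Global (Kruskal-Wallis) p-value.
#' @param pairwise_p Named numeric vector of the three pairwise p-values.
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector of decisions, aligned with `pairwise_p`.
#' @export
closed_test_decisions <- function(global_p, pairwise_p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stats::setNames(global_p < alpha & pairwise_p < alpha, names(pairwise_p))
}

#' Closed-testing post-hoc analysis of three groups
#'
#' Global Kruskal-Wallis test plus pairwise Wilcoxon rank-sum post-hoc tests
#' under the closed testing procedure. Designs with other than three groups
#' are refused: the closure shortcut implemented here is specific to k = 3.
#'
#' @param groups Named list of exactly three non-empty numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @param method Test method passed to [kruskal_wallis_p()] and
#'   [wilcoxon_ranksum_p()].
#' @return List with `global_p`, `pairwise_p` (named vector, names
#'   `"g1_vs_g2"`), `significant` (named logical vector), `alpha`.
#' @export
closed_test_posthoc <- function(groups, alpha = 0.05,
                                method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(groups) != 3L) {
    stop("closed testing implemented for exactly three groups; got ",
         length(groups), call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("all three groups must be non-empty", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  global_p <- kruskal_wallis_p(groups, method = method)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pairwise_p <- vapply(pairs, function(pr) {
    wilcoxon_ranksum_p(groups[[pr[1]]], groups[[pr[2]]], method = method)
  }, 1)
  names(pairwise_p) <- vapply(pairs, paste, "", collapse = "_vs_")
  list(global_p = global_p,
       pairwise_p = pairwise_p,
       significant = closed_test_decisions(global_p, pairwise_p, alpha),
       alpha = alpha)
}

#' Association table across SNPs and analysis sets
#'
#' One row per SNP and analysis set, mirroring the usual DAE report layout:
#' per-group mean (SD) of the corrected allelic ratios (pooled gDNA, cDNA
#' controls, cDNA affected family), the global Kruskal-Wallis p-value, the
#' three pairwise Wilcoxon p-values, and the closed-test decisions.
#'
#' @param studies List of centred [dae_study()] objects.
#' @param alpha Significance level for the closure decisions.
#' @param analysis_sets Which analysis sets to report.
#' @param method Test method (see [closed_test_posthoc()]).
#' @return Tibble with columns `snp_id`, `analysis_set`, `n_*`, `mean_*`,
#'   `sd_*` for the three groups, `global_p`, `p_control_vs_family`,
#'   `p_family_vs_gdna`, `p_control_vs_gdna`, and matching `sig_*` logicals.
#' @export
dae_association_table <- function(studies, alpha = 0.05,
                                  analysis_sets = c("F", "R", "F&R"),
                                  method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (inherits(studies, "dae_study")) studies <- list(studies)
  rows <- list()
  for (study in studies) {
    for (set in analysis_sets) {
      vals <- analysis_set_values(study, set)
      if (nrow(vals) == 0L) next
      vals$comparison_group <- analysis_group(vals$template, vals$group)
      grp <- function(g) vals$rho[vals$comparison_group == g]
      groups <- list(gDNA = grp("gDNA"), control = grp("control"),
                     family = grp("affected_family"))
      ct <- closed_test_posthoc(groups, alpha = alpha, method = method)
      msd <- function(x) {
        c(n = length(x),
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x) > 1) stats::sd(x) else NA_real_)
      }
      sg <- msd(groups$gDNA); sc <- msd(groups$control); sf <- msd(groups$family)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        snp_id = study$snp_id, analysis_set = set,
        n_gdna = sg["n"], mean_gdna = sg["mean"], sd_gdna = sg["sd"],
        n_control = sc["n"], mean_control = sc["mean"], sd_control = sc["sd"],
        n_family = sf["n"], mean_family = sf["mean"], sd_family = sf["sd"],
        global_p = ct$global_p,
        p_control_vs_family = ct$pairwise_p[["control_vs_family"]],
        p_family_vs_gdna = ct$pairwise_p[["gDNA_vs_family"]],
        p_control_vs_gdna = ct$pairwise_p[["gDNA_vs_control"]],
        sig_control_vs_family = ct$significant[["control_vs_family"]],
        sig_family_vs_gdna = ct$significant[["gDNA_vs_family"]],
        sig_control_vs_gdna = ct$significant[["gDNA_vs_control"]],
        alpha = alpha
      )
    }
  }
  if (length(rows) == 0L) {
    stop("no analysis-set values available for any study", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
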