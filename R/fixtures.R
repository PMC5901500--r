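#' Candidate SNP panel of the dyslexia DAE study
#'
#' The four dyslexia-candidate SNPs that survive the full screening cascade,
#' with their gene, forward-strand allele pair (reference allele = numerator
#' of every oriented allelic ratio) and short flanking sequences used by the
#' trace simulator. Flanking sequences are synthetic stand-ins, not genomic
#' context.
#'
#' @return Tibble: `snp_id`, `gene`, `reference_allele`, `alternate_allele`,
#'   `flank5`, `flank3`.
#' @export
dyslexia_snp_panel <- function() {
  tibble::tibble(
    snp_id = c("rs10046", "rs600753", "rs934634", "rs9467075"),
    gene = c("CYP19A1", "DYX1C1", "CYP19A1", "DCDC2"),
    reference_allele = c("C", "C", "G", "A"),
    alternate_allele = c("T", "T", "A", "G"),
    flank5 = c("ACGGTA", "TTGACC", "CCATGA", "GATTCG"),
    flank3 = c("TGCCAT", "AGGTTC", "TTCAGG", "CCAGTA")
  )
}

# printed per-group heterozygote counts of the 12 candidate SNPs; the six
# ineligible SNPs get sub-threshold counts (their exact genotype
# configurations were never published — synthetic fill)
dyslexia_het_counts <- function() {
  tibble::tibble(
    snp_id = c("rs10046", "rs934634", "rs9467075", "rs600753", "rs555879",
               "rs2143340", "rs3743205", "rs2038137", "rs3178", "rs17819126",
               "rs3734972", "rs4504469"),
    gene = c("CYP19A1", "CYP19A1", "DCDC2", "DYX1C1", "MYO5B", "TDP2",
             "DYX1C1", "KIAA0319", "NRSN1", "DYX1C1", "FLNC", "KIAA0319"),
    het_family = c(6L, 4L, 5L, 7L, 7L, 4L, 2L, 1L, 0L, 2L, 1L, 2L),
    het_control = c(11L, 9L, 8L, 10L, 14L, 7L, 5L, 8L, 4L, 2L, 6L, 9L),
    expressed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  NA, NA, NA, NA, NA, NA)
  )
}

#' Synthetic genotype fixture for the 12-SNP screening cascade
#'
#' A 12-SNP by 28-sample genotype table (10 affected-family, 18 control cell
#' lines) whose per-group heterozygote counts equal the counts reported for
#' the study's candidate SNPs: six SNPs reach three or more heterozygotes in
#' both groups, and four of those are flagged as expressed in the assayed
#' B-cell lines. Homozygous genotypes are synthetic fill — for each SNP the
#' AA/BB split of the non-heterozygous samples is the one most probable under
#' Hardy-Weinberg equilibrium given the heterozygote count — so the table is
#' a deterministic stand-in, not the (unpublished) study genotypes.
#'
#' @return List with `genotypes` (a [genotype_table()]) and `expressed`
#'   (named logical vector over the six eligible SNPs).
#' @export
dyslexia_snp_fixture <- function() {
  counts <- dyslexia_het_counts()
  n_family <- 10L; n_control <- 18L
  sample_ids <- c(sprintf("FAM%02d", seq_len(n_family)),
                  sprintf("CTRL%02d", seq_len(n_control)))
  groups <- stats::setNames(
    rep(c("affected_family", "control"), c(n_family, n_control)), sample_ids
  )
  n <- n_family + n_control
  calls <- matrix(NA_character_, nrow = nrow(counts), ncol = n,
                  dimnames = list(counts$snp_id, sample_ids))
  for (i in seq_len(nrow(counts))) {
    hf <- counts$het_family[i]; hc <- counts$het_control[i]
    row <- rep(NA_character_, n)
    row[seq_len(hf)] <- "AB"
    row[n_family + seq_len(hc)] <- "AB"
    hom_idx <- which(is.na(row))
    n_hom <- length(hom_idx)
    h <- hf + hc
    # most probable AA/BB split under HWE given h heterozygotes
    ll <- vapply(0:n_hom, function(nbb) {
      p <- hwe_genotype_log_prob(n_hom - nbb, h, nbb)
      p
    }, 1)
    nbb <- which.max(ll) - 1L
    row[hom_idx] <- rep(c("AA", "BB"), c(n_hom - nbb, nbb))
    calls[i, ] <- row
  }
  expressed <- stats::setNames(counts$expressed[1:6], counts$snp_id[1:6])
  list(genotypes = genotype_table(calls, groups), expressed = expressed)
}

# log probability of a genotype configuration under HWE conditional on its
# own allele counts (Levene-Haldane kernel; used to pick plausible fills)
hwe_genotype_log_prob <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  n_a <- 2 * nAA + nAB
  n_b <- 2 * nBB + nAB
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(nAB + 1) - lgamma(nBB + 1) +
    nAB * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
}
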