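---
title: "Quantifying differential allelic expression from Sanger peak heights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential allelic expression from Sanger peak heights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daequant)
```

## The measurement model

Differential allelic expression (DAE) compares the expression of the two
alleles of a gene *within* heterozygous individuals. Because both alleles
share one nucleus, one RNA extraction and one sequencing reaction, trans
effects and technical batch effects cancel, which makes DAE far more robust
than between-individual expression comparisons at small sample sizes.

The raw observation for one sample, template and sequencing direction is the
pair of fluorescence peak heights $(h_1, h_2)$ of the two alleles at the
variant position of a Sanger chromatogram. The per-measurement statistic is
the natural-log allelic ratio

$$ r = \ln(h_1 / h_2), $$

with $h_1$ the height of the designated (forward-strand) reference allele.
Three systematic effects sit on top of the biological signal:

1. **Strand orientation.** A reverse-direction read reports the complementary
   bases, so its alleles are complemented back to forward-strand bases
   before anything else; if that leaves the alternate allele in the
   numerator, $r$ is negated. Orientation is idempotent.
2. **Assay (dye) bias.** Incorporation and detection efficiencies differ by
   dye, base context and direction, so even a perfect 1:1 template gives
   $r \neq 0$. Genomic DNA (gDNA) from the same heterozygous individuals is
   a built-in 1:1 control: the mean oriented gDNA ratio $\bar g_d$ per
   direction $d$ estimates the bias, and every measurement of that direction
   is corrected as $\rho = r - \bar g_d$. After centering, the corrected
   gDNA ratios of each direction average exactly zero (machine precision),
   which is why a DAE table's gDNA column reads "0 (SD)".
3. **Direction replication.** Forward and reverse reads are technical
   replicates of the same template; per sample and template the corrected
   ratios are combined by averaging. A sample whose read fails QC in one
   direction still contributes its other direction, so the per-direction
   ("F", "R") and combined ("F&R") analysis sets can have different sample
   compositions — combined group means need not equal the average of the
   per-direction means.

Centering uses the cohort mean of the pooled gDNA measurements per
direction, not per-sample cDNA−gDNA pairing. Cohort-mean centering is what
produces a reportable gDNA distribution (mean 0, nonzero SD) as its own
comparison group; per-sample pairing would collapse that group to a
constant and discard samples missing one template. The gDNA reference pools
family and control donors, since assay bias is a property of the assay, not
of the cohort.

## Group comparison and multiplicity

Three groups are compared per SNP: cDNA of the affected family, cDNA of
controls, and the pooled gDNA. With group sizes of five to thirteen,
normality is indefensible, so inference is rank-based:

- **Global test:** Kruskal–Wallis on midranks with tie correction. The
  `exact` method enumerates all assignments of the pooled observations to
  the observed group sizes (complete Monte Carlo above an enumeration cap);
  `asymptotic` uses the $\chi^2_{k-1}$ reference; `auto` switches to exact
  for total $n \le 12$.
- **Post-hoc:** pairwise Wilcoxon rank-sum tests. Exact p-values enumerate
  the $\binom{n_a+n_b}{n_a}$ subsets of midranks; the two-sided p doubles
  the smaller tail (capped at 1). The alternative convention — summing
  outcomes as extreme in both tails — is noted in the function
  documentation; tail-doubling is used because it stays well defined for
  the asymmetric enumeration distributions that ties produce. `auto` uses
  exact for $n_a + n_b \le 20$.
- **Multiplicity:** the closed testing procedure. For exactly three groups
  every intersection hypothesis containing two pairwise nulls coincides
  with the global null, so the closure collapses to a simple gate: a pair
  is declared significant iff its own p-value *and* the global p-value are
  below $\alpha = 0.05$. Pairwise p-values are reported raw; the
  multiplicity control lives in the decisions. The implementation refuses
  designs with $k \neq 3$ rather than silently generalising. Under the
  null this gate controls the family-wise error rate at $\alpha$; the test
  suite verifies this empirically over 2000 simulated null studies at the
  design scale (6 family vs 7 control heterozygous cDNA samples, 13 pooled
  gDNA).

Stratified analyses (by sex, or by affection within the family) are plain
group relabelings followed by a re-run — no bespoke statistics.

## The upstream eligibility screen

DAE needs heterozygotes, and trustworthy genotypes. The screen reproduces a
three-stage cascade over candidate SNPs:

1. **Genotype QC:** SNP-wise call rate > 0.97, minor allele frequency
   > 0.05, and a Hardy–Weinberg exact test (Levene–Haldane, log-space) with
   p > 0.05 after Bonferroni correction across the full set of SNPs
   entering QC. The exact test is the right choice at a 28-sample scale,
   where the $\chi^2$ approximation is unreliable; the $\chi^2$ variant is
   available via `screen_config(hwe_test = "chisq")`. HWE is computed on
   the pooled cohort: with a single multi-generation family in the sample
   there is no defensible kinship correction, and this caveat is
   intentional rather than hidden.
2. **Heterozygote filter:** at least `min_het_per_group = 3` heterozygous
   cell lines in each of the two groups. The source design is ambiguous
   between a threshold of three and four; at the published per-group counts
   both thresholds select the same six SNPs, so the package defaults to 3
   and exposes 4 via configuration rather than resolving the ambiguity.
3. **Expression gate:** intersection with externally supplied flags for
   whether the transcript is detectably expressed in the assayed cells — a
   wet-lab fact the package can only consume, never derive.

The packaged 28-sample fixture reproduces the published cascade
12 → 6 → 4. Its heterozygote counts per group are the published ones; all
other genotype calls are synthetic fill (the most probable homozygote split
under HWE), which the fixture's name and documentation state explicitly.

## The synthetic-data generator

No raw chromatograms are publicly available for this design, so every
pipeline stage is validated against a generator with recorded ground truth.

**Peak tables.** For each sample, template and direction the true log
ratio is $t = \theta_{\text{group}} + b_{\text{direction}}$ (gDNA uses
$\theta_{\text{gDNA}} = 0$ by default: a heterozygote's genomic ratio is
1:1). The reference-allele fraction is $p = e^t/(1+e^t)$ and the heights
are $h_1 = L\,p\,e^{\varepsilon_1}$, $h_2 = L(1-p)e^{\varepsilon_2}$ with
independent $\varepsilon \sim N(0, \sigma^2)$. Noise is multiplicative
because Sanger peak intensities are positive and heteroskedastic; the
induced noise on $r$ is additive Gaussian with variance $2\sigma^2$.
Defaults mirror the study scale: 6 family and 7 control heterozygous
lines, $\theta_{\text{family}} = +0.42$, $\theta_{\text{control}} = -0.34$
(realistic demonstration values, not ground-truth claims), $\sigma = 0.2$,
dye biases $b_F = 0.1$, $b_R = -0.15$. The biases are exactly removed by
centering for any magnitude — one of the tested invariants.

**Traces.** Chromatograms are sums of Gaussian peaks at a fixed basecall
spacing, with the two allele channels superposed at the variant and an
optional folded-normal baseline. With `peak_sd ≤ spacing/4` the extraction
recovers configured amplitude ratios within 2%. The generator emits the
plain-text trace dialect only; AB1 support is read-only.

**Genotypes.** Control genotypes are multinomial under HWE at a drawn MAF,
with an optional fixation-index-style disequilibrium for calibration
studies. Family genotypes are gene-dropped through a fixed ten-member,
three-generation pedigree template (the published family's scale; its exact
structure is not public, so the template is an explicit stand-in).

**Seeding.** One root seed; every draw uses a named substream derived from
it, so adding a new stochastic component never perturbs existing streams,
and a fixed configuration regenerates byte-identical output.

What the generator does *not* emulate: dye blobs, mobility shifts,
polymerase slippage, true biological within-group effect heterogeneity, or
linkage between SNPs. Passing tests therefore demonstrate correctness of
the computation under the stated model, not robustness to every real-world
chromatogram pathology.

## Numerical and interface choices

- All indices are 1-based (basecall index, trace row, variant position), as
  everywhere in R.
- Peak height = channel maximum within ±0.5 × local inter-peak spacing of
  the call (local spacing = mean distance to the neighbouring calls). The
  point-intensity alternative is deliberately not the default: the local
  maximum is robust to small basecall-position jitter. The off-target QC
  scan uses ±0.25 × spacing so neighbouring-peak tails do not masquerade
  as contamination.
- QC thresholds (`min_signal = 5` × flanking baseline median,
  `max_offtarget = 0.5` × minor allele height, context purity ≥ 0.6) are
  configurable defaults; the source design states that trace QC existed
  but not its criteria.
- Flank matching for variant location is exact; ambiguous matches are an
  error asking for longer flanks, never a fuzzy match.
- "Mean zero after centering" is asserted at 1e-12; exact-test tail
  comparisons use an absolute 1e-9 guard against floating-point rank sums.
- Zero peak heights make $r$ undefined: such measurements are dropped with
  a message, never imputed.

## Problem sizes used in validation

The test suite enumerates rank-test null distributions exhaustively for
total $n \le 10$ (200 random tied cases against independent brute-force
oracles), checks the HWE exact test against a recurrence oracle for every
genotype configuration with $n \le 30$, estimates the closed procedure's
FWER from 2000 null studies at the design scale, and verifies parameter
recovery in 500 replicates at $n = 50$ per group with $\sigma = 0.3$
(tolerance $3\sigma/\sqrt{n}$). The analysis scripts use 500 null studies
and 200 power replicates; `scripts/acceptance.R` recomputes the cascade,
centering residual, closure decisions, FWER, effect recovery and trace
round-trip from scratch at the same scales.

## Known limitations

- The closed-testing shortcut is hard-wired to three groups.
- HWE on a cohort containing one extended family is approximate by design.
- Cohort-mean gDNA centering treats assay bias as direction-specific but
  SNP-invariant within a direction only because each SNP is centered by its
  own gDNA measurements; cross-SNP normalisation is out of scope.
- The combined analysis set's per-sample direction-availability rule is a
  reconstruction of common practice; with all directions present it reduces
  to the plain average.
- AB1 parsing covers the records needed for quantification (`DATA9-12`,
  `FWO_`, `PLOC`, `PBAS`); it is not a general ABIF toolkit.
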