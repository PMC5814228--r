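---
title: "Inferring a miRNA–mRNA interactome from paired expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a miRNA-mRNA interactome from paired expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircor)
```

## The problem and the model

MicroRNAs repress mRNAs post-transcriptionally, so in a case/control
tissue study a real regulatory pair should show (i) differential
expression of both partners and (ii) negative correlation of their
expression across the same samples. Sequence-based prediction databases
supply candidate pairs but disagree with each other and over-predict;
expression data alone finds anti-correlated pairs but cannot tell direct
regulation from co-regulation. `mircor` intersects the two evidence
streams and is built around three statistical components.

**Differential expression.** miRNA sequencing counts are normalized with
median-of-ratios size factors — sample $j$'s factor is the median over
zero-free features of $x_{gj}$ divided by the feature's geometric mean
across samples (the median is taken on the log scale, which is identical
to the linear-scale median whenever the reference set has odd size) — and
transformed as $\log_2(x_{gj}/s_j + 1)$. Microarray-style mRNA inputs are
assumed to arrive already on a log2 scale with one row per gene. Each
feature is fit with a two-group linear model: effect
$\hat\beta_g = \bar y_{case} - \bar y_{ctrl}$, pooled residual variance
$s_g^2$ on $d_g = n - 2$ degrees of freedom. Because cohorts of this kind
are small ($n = 12$ in the emulated design), per-feature variances are
noisy; they are shrunk toward an empirical-Bayes prior. Writing
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the scaled-F sampling
model implies $\mathrm{Var}(e_g) = \psi'(d_g/2) + \psi'(d_0/2)$, so the
excess of the observed variance of $e_g$ over $\psi'(d_g/2)$ yields $d_0$
by inverting the trigamma function (monotone Newton iteration), and the
mean of $e_g$ locates $s_0^2$. With the trend option (default on), the
prior location follows a locally weighted regression of $e_g$ on mean
log2 expression (span 0.5, configurable), so low- and high-abundance
features shrink toward different priors; $d_0$ then comes from the fit
residuals. Non-positive excess variance is not an error: the prior
degrees of freedom become infinite and every variance collapses to the
trend value, which is logged. The moderated statistic
$\tilde t_g = \hat\beta_g / (\tilde s_g\sqrt{1/n_1 + 1/n_2})$ is referred
to $t_{d_0+d_g}$ (normal limit when $d_0 = \infty$; at $d_0 = 0$ the
classical equal-variance t-test is recovered exactly, which the test
suite checks against `stats::t.test`). DE features are those with
Benjamini–Hochberg FDR strictly below 0.05.

**All-pairs correlation.** Every DE miRNA × DE mRNA pair is scored with
Pearson correlation on the log2 values across samples, p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and BH
correction applied once over the full pair universe. Correction comes
first and the $r < 0$ filter second; a one-sided negative test and
Spearman correlation are available as configuration, since rank-based
association is more robust when log2 values are heavy-tailed. The
computation streams over blocks of mRNA features, so a universe of a few
million pairs fits comfortably in desktop memory; blocked and unblocked
results are identical by construction and by test.

**Database intersection and enrichment.** Each surviving pair gains one
0/1 flag per prediction database and their sum (`dat_sum`); the
interaction table keeps pairs with negative significant correlation and
`dat_sum >= min_dbs` (1 by default; equal to the number of databases for
the high-confidence subset). Over-representation of a target set against
a GMT collection uses the upper-tail hypergeometric probability computed
in log space (log-binomials plus log-sum-exp), which agrees with exact
combinatorial enumeration to 1e-10 for universes up to 60 and stays
finite for genome-sized ones.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_de`, `fdr_cor`, `fdr_enrich` | 0.05 | strict BH thresholds per stage |
| `log2_offset` | 1 | pseudo-count in $\log_2(x/s_j + \text{offset})$; 1 maps zero counts to 0 |
| `trend`, `span` | TRUE, 0.5 | mean–variance trend for the variance prior |
| `cor_method`, `cor_sided` | pearson, two | correlation statistic and sidedness |
| `min_dbs` | 1 | databases required to support an interaction |
| `enrich_universe` | expressed | hypergeometric universe: all expressed mRNAs, or DE only |

Identifier handling is deliberately minimal: species prefixes
(`hsa-` etc.) are stripped and the `miR` stem case-folded, but arm
suffixes (`-5p`/`-3p`) and the passenger-strand star (`*`) are preserved
— `miR-148a` and `miR-148a*` are different mature species and must never
merge. Gene symbols are matched by exact string equality after
uppercasing; no synonym resolution is attempted, so inputs must share a
vocabulary.

## What the synthetic generator emulates

`generate_dataset()` reproduces the *structure* of a small unbalanced
paired profiling study: 9 cases vs 3 controls; miRNA counts drawn
negative-binomial (dispersion 0.15) around uniform log2 baselines
U(3, 9) with per-sample library factors U(0.7, 1.4); mRNA log2
intensities Gaussian (sd 0.5) around baselines U(5, 12); 31% of miRNAs
and 20% of mRNAs carry a group effect whose magnitude is Gamma(shape 2)
with mean 1.5 log2 units and uniformly random sign. Planted regulatory
edges connect only opposite-direction DE pairs, and each target is
lowered by `coupling` (default 0.8) times the per-feature standardized
log2 normalized abundance of its regulator — standardization makes the
sign of the induced correlation independent of the regulator's count
noise level. Prediction databases take a configurable fraction of the
planted edges (defaults 0.40/0.70/0.55, mimicking databases of very
different sizes), share a common core of edges (15% of the truth) so
their overlap is low but nonzero, and add 1000/3000/2000 false pairs
drawn uniformly from non-edges; the achieved mean pairwise Jaccard is
reported rather than guaranteed. The gamma effect-size distribution is a
testability choice — it produces both easy and borderline features — and
is not claimed to match any specific tumour biology.

Deliberately *not* modelled: batch effects, count outliers, probe-level
artifacts, miRNA family structure (shared seed sequences), correlated
co-regulation of non-target genes, and any sequence information. Passing
recovery tests therefore demonstrate that the statistical machinery is
calibrated and powerful under a clean generative model, not that the
pipeline is robust to every failure mode of real tissue data.

## Numerical and design choices

- **Strict thresholds.** All FDR comparisons use `<`, so a feature or
  pair sitting exactly on 0.05 is excluded.
- **Degenerate inputs.** Constant expression features are removed before
  testing (counted in the log); constant vectors in the correlation stage
  yield an undefined-correlation marker and their pairs leave both the
  table and the BH universe, again counted.
- **Tie-breaking.** Interaction ranking sorts by FDR, then correlation
  (more negative first), then `(mirna_id, mrna_id)` lexicographically, so
  output order is fully deterministic.
- **"Originally predicted" counts** in the reduction report are taken
  against the database union restricted to the DE mRNA universe, making
  numerator and denominator comparable; an unrestricted mode exists. A
  miRNA with zero raw predictions is flagged and excluded from the
  average reduction.
- **BH before the negative filter.** The pair universe is corrected as a
  whole and negatives are selected afterwards; filtering first would
  make the FDR level depend on the (data-dependent) negative fraction.
- **Seeding.** Every stochastic component (generator, gene-set
  simulator) takes a mandatory seed; the pipeline threads one seed from
  its config, and identical seeds give byte-identical run directories.

## Problem sizes used by the checks

The recovery suite runs the generator defaults (300 miRNAs × 2000 mRNAs,
200 planted edges, 20 seeds) for calibration — under a null
configuration the selected fraction stays near the nominal level — and
for the core precision property: on every seed, the interaction set is
more precise against the planted truth than the raw database union. The
reproduction script (`scripts/acceptance.R`) runs the study-scale design
(1733 miRNAs × 18570 mRNAs, 1500 planted edges) end to end and reports
the funnel, summary fractions and precision/recall it computes.

## Known limitations

- Exactly two groups; no covariates, pairing or multi-factor designs.
- Pearson/Spearman marginal correlation only — no partial correlation or
  adjustment for copy number, methylation or immune infiltration.
- Gene identifiers must already be collapsed to one row per gene.
- Detection power at $n = 12$ is modest: under the default effect-size
  mixture a substantial fraction of weak planted effects is invisible,
  so recall of planted edges is well below 1 even though precision is
  high. The tests quantify, not hide, this.
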