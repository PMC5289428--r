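---
title: "Models and methods in transqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in transqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transqtl)
```

# Scope

`transqtl` implements the statistical machinery of a germline-variant /
tumor-expression association study on archival (FFPE) breast-cancer
material: per-SNP gene-level eQTL scans with empirical-Bayes moderated
statistics and per-SNP false discovery rate control, a paired
tumor/adjacent-normal interaction scan, a gene-set "functional QTL"
(fQTL) statistic with genotype-permutation FDR, a cross-platform
receptor-status concordance check, and the sample-level QC operators
such studies rely on. Because the motivating data (clinical FFPE arrays
plus consortium genotypes) cannot be redistributed, the package ships a
synthetic-study generator with a planted-effect truth table; every
claim the package makes about error control or power is demonstrated on
that generator, at stated conditions, by the test suite and the
acceptance script.

# The eQTL model

For SNP $s$, gene $g$, and samples $i$ within one tissue stratum, the
scan fits

$$ y_{ig} = \beta_{0sg} + X_i^\top \beta_{1sg} + \beta_{2sg} D_{is} + \epsilon_{isg}, $$

where $y_{ig}$ is normalized log-scale expression, $D_{is} \in [0,2]$ is
the minor-allele dosage (hard calls or imputed), and $X_i$ holds age at
diagnosis (years), year of diagnosis, assay-plate indicator dummies and,
optionally, expression-PC scores from the QC step. The dosage effect
$\beta_{2sg}$ (log-expression units per allele) is the parameter of
interest. Strata are ER-positive tumors, ER-negative tumors, all
tumors, and adjacent normals; ER-missing samples are excluded from ER
strata only.

## Moderated statistics

Gene-wise residual variances $s_g^2$ on $d_g$ residual df are shrunk
toward a prior by an empirical-Bayes step. Assuming
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d}/d$ with a scaled
inverse-chi-square prior $\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, the
marginal of $\log s_g^2$ has closed-form mean and variance in terms of
digamma/trigamma functions. `estimateVariancePrior()` moment-matches:

* $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,
* $\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$, solved by
  Newton inversion of the trigamma function,
* $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$.

When the observed spread of $\log s^2$ does not exceed the pure
sampling spread the prior df are infinite (full shrinkage): $s_0^2$ is
the common variance when the $s_g^2$ are literally identical, otherwise
their mean. Fewer than 10 usable genes is an error — with so few
variances the hyperparameters are not meaningfully estimable.

The moderated t for coefficient $j$ is
$\tilde t = \hat\beta_j / (u_j \tilde s)$ with
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ on $d_0 + d$ df
(normal tails at $d_0 = \infty$); the moderated F for a coefficient set
$J$ replaces the numerator by the quadratic form
$\hat\beta_J^\top C_{JJ}^{-1} \hat\beta_J / |J|$,
$C = (X^\top X)^{-1}$. At $d_0 = 0$ both reduce exactly to their
classical OLS counterparts, which the tests verify against brute-force
normal-equation and nested-model-RSS oracles. Tests are two-sided
throughout.

## Per-SNP FDR

Benjamini-Hochberg adjustment is applied *within each SNP's gene list*,
separately per stratum — each SNP's scan is its own model family, with
its own variance prior. `bhAdjust()` is the textbook step-up
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1); ties need no
special handling. Records at $q \le 0.10$ are flagged by default.

## Paired tumor/normal interaction

For subjects contributing both tissues the model adds subject fixed
effects (dummies), a tissue indicator, and the tissue-by-dosage
product; the product coefficient — how the allelic effect differs
between tumor and normal tissue — is tested with the same moderated-t
machinery and per-SNP BH. Because germline dosage, age and year are
constant within subject they are linearly aliased with the subject
dummies; the design builder drops aliased columns and logs them. Plate
is retained when a subject's two samples landed on different plates.

## Cis/trans annotation

A record is *cis* when SNP and gene share a chromosome and the SNP lies
within 1 Mb (configurable) of the nearest gene boundary, *trans*
otherwise. The window default is a deliberate design choice: common
practice uses 0.1–1 Mb, and any such window classifies associations
separated by several megabases as trans.

# The fQTL model

The gene-set statistic asks whether a variant shifts the expression of
a functionally related group of genes as a whole. Expression is first
standardized per gene to Z-scores (mean 0, sample SD 1, $n-1$
denominator; constant genes are dropped with a warning). For gene set
$i$ with genes $j$ and samples $k$, the Z-scores are stacked into one
response vector and a single OLS is fit:

$$ y_{ijk} = \beta_0 + \beta_1 \mathrm{YrDx}_k + \beta_2 \mathrm{AgeDx}_k + \beta_3 D_k + \epsilon_{ijk}. $$

$\beta_3$ is the increase in mean set-specific Z-score per risk allele;
its t statistic has $mn - 4$ df for a set of $m$ genes. The model
treats genes within a set as repeated measures with a common variance —
this is what buys power relative to gene-by-gene scans, and it is also
the model's key assumption. Plate dummies and PC scores are *not* in
the default design (the set-level model adjusts for year and age only);
an `extraCovariates` argument adds them. Sets need at least 5
resolvable genes (`minSize`); unresolvable identifiers are dropped with
a count.

Computationally the stacked fit never materializes the long vector:
because the design repeats across genes, $X^\top X = m X_0^\top X_0$
and $X^\top y = X_0^\top \sum_j z_j$, so per-set sufficient statistics
reduce the fit to a 4-by-4 solve. This makes the permutation loop cheap.

## Genotype-permutation FDR

Nominal p-values from the stacked t are anticonservative whenever
genes within a set are correlated or nuisance structure (batch,
receptor status) sits outside the year+age design, so significance is
assessed by permutation: in each of $B$ rounds the sample-to-genotype
assignment is permuted once — one shared permutation across all SNPs,
preserving both the expression correlation structure and the
correlation among SNPs — and all (SNP, set) statistics are recomputed.
For a record with observed $|t| = t^*$,

$$ \widehat{\mathrm{FDR}}(t^*) = \frac{\frac{1}{B} \sum_b \#\{|t|_{\text{perm},b} \ge t^*\}}{\#\{|t|_{\text{obs}} \ge t^*\}} \wedge 1, $$

with the permutation null pooled across sets and SNPs within a stratum
(pooling maximizes null resolution at fixed $B$); monotonicity down the
ranked list is enforced by a running minimum. Per-SNP independent
permutations are available behind a flag. This plug-in tail-ratio
estimator (no "+1" correction) is mildly anticonservative when very few
records carry signal, because the discovery count in the denominator is
then dominated by the true effects; the acceptance checks therefore
evaluate realized false-discovery proportion with an explicit
Monte-Carlo margin rather than asserting exact attainment of the
nominal level.

# Cross-platform adequacy (concordance)

To ask whether an FFPE-based platform retains biological signal, each
platform's genes are scored by a moderated F (3 numerator df) for
differences in mean expression across the four ER/PR hormone-receptor
groups, with dummies for `+-`, `-+` and `++` against the `--`
reference. The joint F is invariant to which group is the reference
(verified property). Per-platform sample sizes — hence denominator df —
differ and are preserved. Concordance between platforms is the
Spearman correlation of the two F vectors over shared gene identifiers
(case-sensitive exact matching, at least 3 required).

# Quality control operators

* **Control-probe AUC.** Per sample, the Mann–Whitney AUC separating
  positive from negative control-probe signals (ties half-credit);
  samples *strictly below* 0.55 are removed. The boundary sample at
  exactly 0.55 is retained. Filtering never reorders retained samples.
* **Replicate concordance.** Per technical-replicate group, the minimum
  pairwise Pearson correlation of expression profiles; constant columns
  are an error.
* **PC batch adjustment.** Sample-space PCs of the row-centered matrix
  are screened (first 50 by default) for association with assay batch by
  one-way ANOVA. Every associated PC ($p < \alpha$, default 0.05) is
  either subtracted as its rank-one reconstruction (`mode = "clip"`) or
  returned as covariate scores (`mode = "covariates"`); both modes are
  offered because either is a defensible reading of standard practice,
  and the mode is recorded in the report. Clipping is idempotent: a
  second pass at the same $\alpha$ removes nothing further.

# The synthetic-study generator

`simConfig()` defaults encode the study design the package targets:
376 subjects, two thirds with a paired adjacent-normal specimen, 71
SNPs at minor allele frequencies 0.015–0.50 under Hardy–Weinberg
genotype frequencies, nine assay plates, ER-positive proportion 0.79
among tumors, diagnosis ages 50–79 and years 1990–2004, log2-scale
baselines around 7 with unit Gaussian noise. Gene count defaults to
2,000 — a desk-scale stand-in for the array's ~26,000 transcript
clusters chosen so that full calibration studies run in seconds per
replicate; all calibration claims below state their problem sizes.

Expression is additive on the log scale: baseline + per-gene age/year
coefficients + per-(gene, plate) batch shifts + a per-(subject, gene)
baseline shared by a subject's tumor and normal samples (this is what
makes subject fixed effects the correct paired analysis) + per-gene
tumor/normal shifts + ER/PR receptor-group shifts on tumors + planted
effects + i.i.d. Gaussian noise. Planted effects come in three types,
each recorded in the bundle's truth table: additive dosage effects on
single genes, tumor-only (tissue-by-dosage) effects, and set-level
shifts applied to every gene of a set (stated in Z-score units and
injected as that multiple of the noise SD — with nuisance variance
present the realized standardized effect is slightly smaller, which
biases calibration checks toward conservatism, never optimism).
Control probes are Gaussian with a per-sample positive-negative
separation $\Delta$, so the expected AUC is $\Phi(\Delta/\sqrt 2)$.
Gene and SNP coordinates are scattered over 22 synthetic autosomes so
cis/trans classification sees both same- and different-chromosome
pairs.

What the generator does **not** emulate: linkage disequilibrium among
SNPs, probe-level microarray artifacts, RNA degradation gradients,
heavy-tailed or heteroscedastic noise, and gene-gene co-expression
beyond the shared nuisance terms. Passing calibration tests on this
generator therefore shows the machinery is correct under its stated
assumptions, not that real FFPE data meet them.

# Numerical and design choices

* OLS is solved via Cholesky of $X^\top X$ after a QR rank check;
  aliased design columns are an error at the core level (named in the
  message) and a logged drop at the scan level where aliasing is
  structural (paired designs).
* Saturated fits ($d = 0$) are kept with undefined $s^2$ rather than
  erroring; moderation supplies the variance.
* Missing expression values are handled per gene by complete-case
  refitting, with per-gene $n$ and df recorded. The joint moderated F
  requires a shared design and refuses per-gene complete-case fits.
* `priorZero()` realizes the no-shrinkage limit with the smallest
  positive double as $d_0$, which is algebraically exact in the
  posterior-variance formula.
* Monomorphic SNPs within a stratum are skipped and logged, not
  errored — rare alleles routinely vanish from small strata.
* Dosage is coded as minor-allele count; recoding $2 - D$ flips the
  sign of every dosage coefficient and changes nothing else (verified
  property).
* Determinism: every stochastic operation takes a mandatory seed; the
  writers emit full-precision (17 significant digit) numerics so
  identical runs produce byte-identical files and round trips are
  exact.

# Problem sizes used by the calibration checks

The shipped checks run, per replicate: eQTL calibration on 40 SNPs ×
2,000 genes at $n = 300$ with 5% of pairs carrying a 0.3-SD allelic
effect (20 replicates); fQTL calibration on 20 SNPs × 50 sets of 10–50
genes over 1,500 at $n = 300$ with 3 planted set effects of 0.3
Z-units and $B = 500$ permutations (20 replicates); parameter recovery
at $n$ = 120–300 over 20 seeds; null calibration on 2,000 tests per
stratum; concordance on 17 genes across two platforms over 20 seeds.
These sizes were chosen once as realistic desk-scale analogues of the
motivating study's dimensions.

# Known limitations

* The fQTL equal-variance repeated-measures assumption is a modelling
  convenience; the permutation FDR absorbs most, but not all, of its
  violation — with very few true effects the plug-in estimator can
  exceed the nominal level by a few percentage points (see above).
* The eQTL scans fit one SNP at a time; no conditional or multi-SNP
  modelling, no LD-aware interpretation.
* PC batch adjustment assumes batch effects live in a low-dimensional
  linear subspace.
* Gene-set analysis ignores relationships among sets (no ontology
  traversal); overlapping sets yield correlated records.
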