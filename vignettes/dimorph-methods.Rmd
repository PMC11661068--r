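---
title: "Models and methods in dimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dimorph)
```

`dimorph` integrates bulk proteomics and transcriptomics of one tissue to
ask whether molecular structure differs between male and female donors.
This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the known limits.

## The latent factor model

Each study $s$ (a proteome of $n_s$ samples, a transcriptome of $n_s$
samples) is observed on a common panel of $p$ genes. After per-feature
centring and scaling within each study, a sample is modelled as

$$x = \Phi f + \Lambda_s l + e, \qquad
\Sigma_s = \Phi\Phi^\top + \Lambda_s\Lambda_s^\top + \Psi_s,$$

with shared loadings $\Phi$ ($p \times K$) common to all studies,
study-specific loadings $\Lambda_s$ ($p \times J_s$), and diagonal
specific variances $\Psi_s$. Factor scores $f, l$ are standard normal and
independent of the noise $e \sim N(0, \Psi_s)$. The model's assumptions —
Gaussian data, linear shared structure, diagonal residual covariance — are
exactly what the synthetic generator produces, so fitting on simulated
data measures estimation error, not model misfit.

**Fitting.** The model is fitted by expectation/conditional maximization:
one E-step computes the joint posterior moments of $(f, l)$ per study;
conditional M-steps then update $\Phi$ (pooled across studies, each
feature row solved with weights $n_s/\psi_{sj}$), each $\Lambda_s$, and
each $\Psi_s$. The observed-data log-likelihood is recorded every
iteration and is non-decreasing by construction; iteration stops when the
relative change falls below `msfa_tol` (default `1e-6`) or at
`msfa_max_iter` (default 10000). Specific variances are floored at
$10^{-6}$ to prevent Heywood collapse; floor hits are counted and
reported in `glance()`.

**Identifiability and reporting basis.** The likelihood identifies $\Phi$
only up to rotation within its column space. During fitting the
block-lower-triangular pattern (zeros above the diagonal of the leading
$K \times K$ block, and of each $\Lambda_s$'s leading block) pins a unique
representative. That representative's axes are, however, arbitrary with
respect to anything interpretable — which of $K$ fitted axes carries a
class signal depends on which genes happen to sit in the leading rows. The
reported `phi` is therefore the principal-axis form of
$\hat\Phi\hat\Phi^\top$: eigenvectors scaled by square-root eigenvalues,
ordered by decreasing shared variance, each column's largest-magnitude
loading made positive. This is deterministic, uses no sample labels, and
leaves every $\Sigma_s$ (hence the likelihood) unchanged; the constrained
representative stays available as `phi_constrained`. No varimax-style
rotation is applied — loadings are interpreted raw. A supervised rotation
(aligning an axis to the sex contrast before testing it) was considered
and rejected: it would make the subsequent sex test circular.

**Initialization.** The shared block starts from the leading singular
vectors of the concatenated standardized data and is rotated (not
truncated) into block-lower form; zeroing the constrained entries instead
perturbs an otherwise exact start and can trap ECM at a boundary fixed
point when the data are near noiseless. Specific blocks start from
per-study residual SVDs, $\Psi_s$ from the residual diagonal.

**Scores and testing.** Factor scores are Bartlett weighted least
squares, $\hat f = (\Phi^\top\Psi_s^{-1}\Phi)^{-1}\Phi^\top\Psi_s^{-1}
\tilde x$, computed with the shared loadings and the scored study's
$\Psi_s$; study-specific factors are treated as noise at scoring time.
Scores are pooled across studies, sign-aligned (a factor whose
point-biserial correlation with the male indicator is negative and at
least `relevance_r = 0.3` in magnitude is flipped — the relevance gate
keeps irrelevant factors' arbitrary signs untouched), and tested with a
sex × factor ANOVA plus per-factor male-minus-female contrasts from the
cell-means model. Contrasts are Holm-adjusted by default — conservative
and assumption-free across the $K$ contrasts; a single-step
multivariate-$t$ adjustment is available via `adjust = "single-step"`.
Factors with adjusted $p <$ `q_cut` (default 0.1) are flagged.

## Moderated two-group testing

With four donors per sex, per-protein variance estimates are unstable.
The moderated test pools them: residual variances $s_g^2$ with $d_g$
degrees of freedom are modelled as scaled-$F$ draws around a prior
$(d_0, s_0^2)$, estimated by matching the mean and variance of
$\log s_g^2$ to their digamma/trigamma expressions, with the trigamma
equation inverted by Newton iteration to $10^{-8}$. Posterior variances
$(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yield t statistics with $d_g + d_0$
df. Setting `prior_df = 0` recovers the ordinary t exactly; `prior_df =
Inf` pins every variance at $s_0^2$ — both limits are tested. Differential
calls use the joint post-hoc filter $|{\rm lfc}| > 1$, BH-adjusted
$p < 0.05$.

## Enrichment

The running-sum statistic walks the ranked list; a set member at rank $i$
adds $|r_i|^w / \sum_{j \in S} |r_j|^w$ and a non-member subtracts
$1/(N - |S|)$; the enrichment score is the deviation of largest magnitude
(a positive value wins an exact-magnitude tie, for determinism). The
default weight $w = 1$ is the classic weighted form; $w = 0$ makes the
statistic rank-only and invariant to monotone score transforms. Nulls come
from `gsea_nperm` gene-label permutations (default 10000) — appropriate
because every input here is a pre-ranked statistic; permutations are
cached per set size. NES divides the ES by the mean |null ES| of matching
sign; nominal p-values carry a +1 pseudo-count so no permutation p is
zero. Minimum set size defaults to 25 for expression and fold-change runs
and 5 (`gsea_loading_min_size`) for factor-loading runs on small panels.
Ties in scores are broken by feature label before the scan.

Over-representation uses the upper-tail hypergeometric against an
explicit universe — the genes that actually entered the differential
comparison, not a genome-wide default. Marker sets are built per
subpopulation as genes whose within-group mean exceeds the group's
`quantile_cut` (default 0.95) quantile; the supported
variance-stabilization is log2 of size-factor-normalized values plus a
pseudocount, so membership near the quantile boundary can differ from
stabilizations with stronger low-count damping.

## Preprocessing rules

* **Stage order** is log2 → gene-group dedup → completeness filter →
  replicate merge. The order of filtering relative to merging is genuinely
  ambiguous in practice; both work here, the canonical order is fixed for
  reproducibility and each stage is exported separately.
* **Deduplication** ships two policies because both rules are defensible:
  `first_term_highest_abundance` keeps the row with the highest mean
  observed intensity among rows sharing a first term;
  `exact_single_term_preferred` lets a single-symbol row beat composite
  rows, falling back to abundance. The default is the former.
* **Completeness** is inclusive at the boundary: "present in less than
  80% of samples" is removed, so a feature observed in exactly 80% stays.
* **Missing values** are ignored in means throughout; nothing is imputed.
* **Quantile normalization** replaces each column's order statistics with
  the row-wise means of sorted columns; ties are assigned in
  first-occurrence order. It requires a complete matrix and says so.

## The synthetic generator

`sim_params()` defaults describe the study design the package targets: a
402-gene shared panel; a proteomic study of 16 samples (8 donors, 4 F +
4 M, two tissues each, 2 technical replicates at 0.2 SD technical noise, 5%
missing completely at random, 10% composite gene-group labels); a
transcriptomic study of 50 complete samples; $K = 3$ shared factors with
the second and third carrying a 2-SD male shift in factor scores; one
30-gene pathway planted on the last sex factor plus 20 random decoy sets;
uniform specific variances on $[0.2, 0.8]$ and 30% loading sparsity.
Magnitudes that the design itself does not fix (noise scales, sparsity,
planted-set size) were chosen once as values a practitioner would call
realistic and are config-exposed, not revisited.

Sex enters through factor-score mean shifts, not loadings — the readout
is "factor scores separate by sex", matching how such analyses are
interpreted. RNA-like counts are produced by exponentiating the Gaussian
signal (log-normal counts) and travel through TPM → quantile
normalization → log2 inside the pipeline, keeping one latent model for
both studies.

What the generator does **not** emulate: batch effects, peptide/spectrum
level noise, intensity-dependent (left-censored) missingness (MCAR is the
tested default; real DIA dropout is abundance-biased), donor pairing
between the two tissues beyond shared factor scores, and annotation
ambiguity beyond first-term collisions. Passing recovery tests therefore
show correctness of the estimators under the stated model, not robustness
to these real-data features.

## Numerical choices

* ECM convergence: relative log-likelihood change below `1e-6`;
  monotonicity asserted to `1e-8` slack in tests.
* $\Psi$ floor `1e-6`; correlation-matrix inversion in KMO falls back to
  a ridge (`1e-6`) with a warning when features outnumber samples.
* PC1 and factor-loading signs: the largest-magnitude loading is positive.
* Ranked lists: descending score, ties by label; deterministic everywhere.
* Permutation p-values: $(b + 1)/(m + 1)$.
* Degenerate inputs have defined behaviour: double log-transform errors;
  empty completeness results warn; a single factor in the sex test reduces
  to a two-group comparison with a warning; a single shared phospho site
  reduces to a two-group comparison; zero-variance features are named in
  errors.

## Problem sizes and statistical limits

The test suite and the acceptance script run at deliberately modest
sizes: 100 random two-study fixtures ($p$ 30–60) for ECM monotonicity; a
$p = 60$, $n = (200, 100)$ benchmark for recovery; 2000 features for
moderated-t calibration; 200 sets × 2000 permutations for GSEA
calibration; 200 simulated membrane studies for the phospho analysis;
and 20 full pipeline runs at the default panel with one sex-shifted
factor and $n = 8$ per sex per study.

Two limits are worth stating plainly, because they are statistical, not
implementation, bounds — the package's estimates match reference
maximum-likelihood factor analysis on identical data:

* **Covariance recovery at $n = 100$.** The implied $\Sigma_s$ of the
  smaller benchmark study lands at a Frobenius relative error around
  0.24 against the generating covariance; a dedicated ML factor analysis
  of that study alone attains the same value, and the raw sample
  covariance is worse (≈0.28). More samples, not different code, is what
  improves it.
* **Which axis carries the sex signal at $n = 32$.** With 16 samples per
  study the fitted shared *subspace* contains the true sex axis almost
  perfectly (projection > 0.95), but identifying *which* direction within
  a $K = 3$ subspace is the sex one is information-limited: the axis's
  excess score variance (2 vs 1) is about two standard errors of a
  variance estimate at $n = 32$, and a 2-SD two-group mixture sits exactly
  at the threshold where it stops being detectably bimodal. Consequently
  the end-to-end pipeline concentrates the sex signal on a single factor
  in most, but not all, seeded runs; the rest smear it over two factors.
  Score-covariance and independent-component rotations were measured and
  do no better than the principal-axis basis. With the transcriptome at
  its design size ($n = 50$) the identification is correspondingly easier.

## Known limitations

Beyond the generator's idealizations above: the factor-level sex test
pools scores across studies and ignores the donor pairing between ganglia
and nerve-root samples (a per-study stratified test is the natural
extension); the moderated test models sex only, with no covariates; GSEA
uses gene-label permutation, which treats genes as exchangeable and is
anti-conservative under strong inter-gene correlation; and ortholog or
identifier conversion is out of scope — inputs are expected to share one
symbol space, with any mapping applied by the user beforehand.
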