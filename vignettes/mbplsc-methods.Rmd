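---
title: "Multiblock PLS-C for grey-white matter structural coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock PLS-C for grey-white matter structural coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbplsc)
```

## The model

`mbplsc` implements a group-stacked multiblock partial least squares
correlation (MB-PLS-C) for two-group neuroimaging designs. For each group
$g$ with $n_g$ participants, three cross-correlation blocks are computed
from the column-standardised (within group) grey-matter matrix
$X_g \in \mathbb{R}^{n_g \times p}$, white-matter matrix
$Y_g \in \mathbb{R}^{n_g \times q}$ and covariate matrix
$C_g \in \mathbb{R}^{n_g \times c}$:

* $A_g = \mathrm{corr}(X_g, Y_g)$ ($p \times q$): the grey-white coupling
  of interest;
* $B_g = \mathrm{corr}(X_g, C_g)$ ($p \times c$) and
  $D_g = \mathrm{corr}(C_g, Y_g)$ ($c \times q$): covariate-imaging
  coupling, so that shared covariate variance loads onto its own
  components instead of contaminating the grey-white ones;
* optionally $E_g = \mathrm{corr}(C_g, C_g)$ ($c \times c$), off by
  default (`analysis_config(include_cov_cov = FALSE)` zeroes it), since
  the covariate-covariate correlations carry no imaging information.

Per group these are arranged as $\begin{bmatrix} A_g & B_g \\ D_g^\top
\text{-side} \end{bmatrix}$-style bordered blocks, and the per-group
matrices are stacked **vertically**, giving the
$G(p + c) \times (q + c)$ matrix $M$. Stacking rows per group while
sharing columns encodes the core modelling commitment: each latent
component has *group-specific grey-matter saliences* but a *single shared
white-matter salience pattern*. A full singular value decomposition
$M = U \Sigma V^\top$ yields, for component $i$:

* left saliences $u_i$: one grey-matter subvector per group plus the
  grey-side covariate rows;
* right saliences $v_i$: the shared white-matter pattern plus
  white-side covariate columns;
* explained inertia $\xi_i = 100\,\sigma_i^2 / \sum_j \sigma_j^2$;
* block contributions
  $100 \, u_i[R_b]^\top M[R_b, C_b] \, v_i[C_b] / \sigma_i$ for each
  block $b$ (rows $R_b$, columns $C_b$), which sum to 100 per component
  and attribute the component's singular value to the blocks.

Signs are fixed by making the largest-magnitude entry of each left
singular vector positive; saliences are otherwise sign-indeterminate.

Participant latent scores are the projections of the within-group
standardised data onto the saliences of their group
(`participant_scores()`); covariate rows are excluded from the score so
that scores measure imaging coupling only.

## Assumptions

* Correlations are meaningful per group: each group needs at least four
  participants and no zero-variance feature (`validate_dataset()` treats
  both as fatal).
* Features are approximately interval-scaled; Pearson correlation is the
  default (`cor_method = "pearson"`, Spearman available).
* The white-matter pattern is assumed common across groups (the stacking
  above); group differences express themselves in the grey-matter
  saliences and are quantified by the NSSD (below).
* Cognition is analysed *post hoc* against latent scores, not included in
  the decomposition.

## Inference

**Permutation test.** Within each group, rows of the white-matter block
are permuted, breaking the grey-white and covariate-white couplings while
preserving all marginal distributions. The omnibus statistic is the total
inertia $\sum_i \sigma_i^2$; per-component p-values compare each observed
$\sigma_i$ against the permuted singular values after orthogonal
Procrustes alignment of the permuted right singular vectors to the
observed solution (Schönemann's closed form, rotation
$R = \tilde U \tilde V^\top$ from $\mathrm{svd}(F^\top V)$), which
resolves component reordering and axis rotation under permutation.
P-values use the add-one convention $(1 + \#\{\text{null} \ge
\text{obs}\}) / (B + 1)$, so the smallest attainable p-value is
$1/(B+1)$. Because within-group permutation leaves each block's column
statistics unchanged, the permuted correlation blocks are computed from
pre-standardised matrices via cross-products, making $B = 1000$
permutations on study-sized problems a matter of seconds.

**Bootstrap.** Participants are resampled with replacement within group;
each replicate's solution is Procrustes-aligned (rotation and sign) to
the original before accumulating per-entry salience distributions.
Percentile 95% intervals are reported; a salience is *significant* when
its interval excludes zero. Replicates with zero-variance columns are
discarded and counted; runs with fewer than 100 usable replicates are
flagged unreliable. Note the percentile intervals quantify sampling
variability of the estimator; singular-vector estimates carry an
attenuation bias at modest $n$ (component mixing), so the intervals are
not guaranteed to cover population saliences at the nominal rate — the
package's tests check instead that the bootstrap SD tracks the true
sampling SD across independent cohorts.

**NSSD.** The normalised between-group structural salience difference
contrasts grey-matter patterns: each group's grey-matter salience
subvector is L2-normalised, then differenced elementwise. It is zero at
equality, antisymmetric under group swap, and scale-invariant.

**Monte Carlo cross-validation.** Each split stratifies by group (default
75% training), refits on the training partition and projects test
participants using *training* standardisation statistics. The tracked
component is taken by rank within each training fit; matching it to the
full-sample solution would leak test information through the component
selection and bias the out-of-sample correlation upward under the null
(this is verified by a calibration test pooling splits across independent
null datasets). A group's coupling is *generalisable* when the
normal-theory 95% interval of the mean across-split correlation excludes
zero — note splits of one dataset are correlated, so this flag is a
heuristic, not a calibrated test.

**Cognition association.** For each (group, component) family, latent
scores (grey and white) are correlated with each cognition variable,
using Pearson when both variables pass a Shapiro-Wilk gate and Spearman
otherwise; Benjamini-Hochberg adjustment is applied within the family of
$2 k_{\mathrm{cog}}$ tests. As a worked example, the smallest of eight
p-values equal to 0.006 adjusts to 0.048. Group differences in a given
correlation are tested with Fisher's z,
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

**Pattern connectivity.** Given a streamline-bundle table (endpoint
region pairs, traversed tracts, weights), the weight of a (region set,
tract set) pattern is the sum over bundles with *both* endpoints in the
region set and at least one traversed tract in the tract set, each bundle
counted once. Significance comes from a size-matched null: random
patterns with the same number of regions and tracts drawn uniformly from
the label universes, with the add-one p-value convention. An exhaustive
enumerator over all size-matched patterns (`exhaustive_pattern_null()`)
serves as an oracle on small universes.

## The synthetic generator and its calibration

`generate_dataset()` plants a known latent structure so every inferential
claim above can be tested against ground truth:

* loading vectors are sparse (default 20% support) with equal-magnitude
  $\pm 1$ entries, normalised to unit length. Equal magnitudes give a
  crisp nonzero/zero truth for significance-mask tests;
* the shared and group-differential vectors occupy **disjoint supports**,
  so the two planted components are exactly orthogonal and separately
  identifiable — with overlapping random supports the planted components
  are not the singular vectors of the noiseless model, and recovery
  tests would measure an identification gap rather than estimation error;
* the factor scores are orthogonalised **in sample** against the
  covariates and each other (regression residuals, re-standardised).
  Without this, incidental factor-covariate correlations of order
  $1/\sqrt{N}$ are amplified by the effect sizes and mix the planted
  components;
* the differential factor enters grey matter with opposite polarity per
  group (`diff_polarity = c(1, -1)`) and white matter with a common sign,
  matching the stacked model's semantics; its recovered per-group
  grey-matter saliences therefore anticorrelate (negative cross-group
  congruence);
* cognition column 1 is linked to the differential white-matter latent
  score in the second group only (`cognition_link = c(0, 0.5)`);
* outputs are affinely rescaled to plausible units (thickness around
  2.5 mm, FA around 0.45, cognition around 100 ± 15), which leaves all
  correlations untouched.

Default effect sizes (`shared_effect = 4`, `diff_effect = 2`,
`noise_sd = 0.5`, $n = 71$ per group, $p = 68$, $q = 48$) were calibrated
once, up front, so that recovery is informative rather than trivial or
hopeless: across 25 generator seeds the matched components' Tucker
congruences with truth all exceeded 0.94, while halving the sample or
doubling the noise makes recovery visibly degrade. The defaults are
frozen study conditions; tests never adjust them to pass.

## Numerical choices

* Full SVD via LAPACK (`svd()`); components are trimmed to
  $\min(G(p+c), q+c)$.
* Tucker congruence (cosine similarity) matches components across
  refits, subsamples and seeds.
* All stage seeds derive from the single configuration seed with fixed
  offsets (permutation, bootstrap +1, convergence +2, CV +3, connectivity
  +4), so a pipeline run is reproducible end to end and reports are
  byte-identical across reruns (`config_hash()` excludes the output
  directory for the same reason).
* Exact Spearman p-values are used below $n = 20$, the t-approximation
  above.

## Problem sizes and runtimes

The shipped test-suite exercises the stack at these scales (single CPU):

* reduction oracle vs plain PLS-C: 20 datasets of $30 \times (8, 5)$,
  agreement to $10^{-10}$, seconds;
* permutation calibration: 200 null datasets ($n = 30$ per group,
  $p = 20$, $q = 15$, $B = 200$), omnibus rejection rate within the
  binomial band $[0.025, 0.085]$, under a minute via the fast
  permutation path;
* recovery: 50 study-sized datasets ($n = 71$, $p = 68$, $q = 48$),
  congruence $\ge 0.90$ and negative cross-group congruence in
  $\ge 90\%$ of repeats, minutes;
* connectivity oracle: Monte Carlo vs exhaustive null on a
  $4 \times 3$ universe within $\pm 0.02$ at $B = 10^4$, seconds.

## Limitations

* Two-group designs only; the stacking generalises to $G > 2$ but the
  NSSD and group-comparison helpers assume a pair.
* The shared white-matter pattern is a modelling assumption, not a
  finding; severely group-divergent white-matter structure would be
  forced into grey-matter salience differences.
* Percentile bootstrap intervals inherit the estimator's attenuation
  bias (see above).
* The permutation scheme treats participants as exchangeable within
  group; family structure or site effects would need restricted
  permutations that are not implemented.
* The generator plants linear, homoscedastic structure; it cannot probe
  robustness to outliers or nonlinear coupling.

## A minimal session

```{r example, eval = FALSE}
gen <- generate_dataset(synth_config(seed = 1))
cfg <- analysis_config(n_permutations = 500, n_bootstrap = 300, seed = 1)
model <- fit_mbplsc(assemble_multiblock(gen$dataset, cfg))
model$xi[1:3]                        # percent explained inertia
perm <- permutation_test(gen$dataset, cfg, model)
perm$p_components[1:3]
boot <- bootstrap_saliences(gen$dataset, cfg, model, components = 1:2)
head(boot$table)
nssd(model, 2)                       # group contrast on component 2
```
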