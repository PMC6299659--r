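---
title: "Models and design of the diallelGS genomic-selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the diallelGS genomic-selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Conifer breeding by progeny testing takes 20-30 years per cycle, most of it
waiting for field trials. Genomic selection (GS) replaces the progeny-test
phenotype with a marker-based prediction of the breeding value, potentially
halving the cycle. Whether that pays off depends on how accurately marker
models predict breeding values under the population structures a breeding
program actually has: full-sib family blocks planted over multiple sites,
strong genotype-by-environment interaction (G x E) for growth, weak for wood
properties, and a modest effective population size set by a few dozen
parents.

`diallelGS` implements that evaluation end to end for a two-site
control-pollinated progeny trial laid out as a partial diallel: a synthetic
trial generator, genotype QC, pedigree and genomic relationship matrices,
REML variance components and BLUP breeding values, Bayesian whole-genome
regressions, kernel regression, and a cross-validation engine over the
experimental factors (method, training/validation ratio, family structure,
site scenario, marker subsets). Because the motivating trial's raw data are
not public, every analysis runs on simulated trials whose statistical
structure matches the published design; printed-table arithmetic
(heritability from variance components, relative efficiency from
accuracies) is reproduced exactly from the published numbers.

# Models

## Joint-site animal model

For a single trait measured on different trees at two sites,

$$y = X\beta + W b + Z a + e,$$

with fixed grand mean and site effect ($\beta$), random post-block-within-
site effects $b \sim N(0, I\sigma^2_b)$, additive genetic effects $a$, and
site-specific residuals. Under the *unstructured* covariance the additive
effects of the same genotype expressed at the two sites are treated as two
correlated traits,

$$\mathrm{var}\!\begin{pmatrix}a_1\\a_2\end{pmatrix} =
\begin{pmatrix}\sigma^2_{a1} & \sigma_{a12}\\
\sigma_{a12} & \sigma^2_{a2}\end{pmatrix}\otimes A,$$

where $A$ is the pedigree numerator relationship matrix (or $G$, the
genomic one). The *type-B genetic correlation*
$r_B = \sigma_{a12}/\sqrt{\sigma^2_{a1}\sigma^2_{a2}}$ measures G x E:
$r_B \approx 1$ means the same genotypes win at both sites. Its departure
from 1 is tested with a one-tailed likelihood-ratio test whose null lies on
the boundary, so the reference distribution is the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (the package reports
$p = \tfrac12 P(\chi^2_1 \ge \mathrm{LRT})$, hence $p = 0.5$ at a zero
statistic). A *homogeneous* variant with a common additive variance plus a
site-by-additive interaction term is available for heritability reporting.

Narrow-sense heritability is reported as
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ — the denominator excludes the
post-block variance, matching how progeny-trial variance-component tables
print additive and residual columns. For the homogeneous joint model the
site-by-additive variance is likewise excluded by default (a flag includes
it); this matches the printed arithmetic of the tables the package
reproduces.

## Relationship matrices

`a_matrix()` implements the tabular recursive method (founders unrelated
and non-inbred). `g_matrix()` implements
$G = (M-P)(M-P)^\top / (2\sum_i p_i(1-p_i))$ with $M$ the 0/1/2
minor-allele dosage matrix and, under the default `vanraden` convention,
$P$ columns equal to $2p_i$. The alternative `shifted` convention
uses $2(p_i - 0.5)$, a form sometimes printed alongside 0/1/2 coding even
though it actually centres a -1/0/1 coding; it is provided behind a flag
for comparability and is not the default. Allele frequencies are computed
from all genotyped samples present in the matrix, and markers are oriented
to the minor allele first (which leaves the `vanraden` G invariant).

## REML

Variance components are estimated by direct maximisation of the restricted
log-likelihood over an unconstrained parameterisation (log variances, the
additive cross-site correlation through atanh; the unstructured 2 x 2
additive covariance is built from its Cholesky factor so it stays valid).
Nelder-Mead with restarts is used rather than average-information updates:
the likelihood itself is made cheap enough that a derivative-free search is
both simpler and more robust near boundaries (e.g. a zero block or additive
variance).

The cost reduction comes from the covariance structure, computed through
the Woodbury identity in one of three ways:

* **Two-generation diallel + pedigree kinship.** Among progeny whose
  parents are all founders, $A = 0.5\,I + 0.25\,PP^\top$ with $P$ the
  progeny-by-parent incidence matrix — diagonal plus rank-(number of
  parents). After caching per-site crossproducts of the block and parent
  incidence blocks, one likelihood evaluation costs
  $O((n_{blocks} + 2\,n_{parents})^3)$ — about a millisecond at 88 blocks
  and 55 parents — independent of the number of trees. A joint-site
  unstructured fit at ~2600 trees converges in a second or two.
* **Single site + generic dense kinship.** One eigendecomposition of $K$
  among the phenotyped trees; in the rotated basis the covariance is
  diagonal plus a rank-$n_{blocks}$ block term, so each evaluation is
  $O(n\,n_{blocks}^2)$.
* **Dense fallback** (joint scope with a generic $G$): a Cholesky
  factorisation of the full covariance per evaluation; used at reduced
  problem sizes.

The three paths agree to numerical precision on shared cases (tested).
Convergence is declared by the optimizer's own relative-tolerance rule
(reltol 1e-10, maximum 2000 evaluations per restart); standard errors for
heritability and type-B come from the delta method on a numerical Hessian
of the restricted likelihood. Breeding values for every individual in the
kinship — including unphenotyped founders and validation trees — are
recovered at the converged components as
$\hat a = \mathrm{Cov}(a, y)V^{-1}(y - X\hat\beta)$, which coincides with
Henderson's mixed-model equations; `solve_mme()` exposes the literal block
system and is tested against a direct GLS oracle, and the two routes are
cross-checked against each other.

For joint-site reference ("true") breeding values the per-site EBVs from
the unstructured pedigree model are averaged; for within-site and
cross-site validation the corresponding per-site EBV column is used. A
single-site fit cannot carry a G x E term, so "within-site reference EBVs"
are taken from the joint unstructured fit's site-specific column — the
closest well-defined reading of using single-site values that acknowledge
G x E.

## Adjusted phenotypes

Marker models are fit to $y' = y - \hat b_{block}$, centred and scaled to
unit variance within site. Standardising per site removes the fixed site
effect and puts both sites on one scale so joint training sets can be
pooled. In cross-validation the block effects and the standardisation are
re-estimated from the training trees only and applied to them; the
validation-side $y'$ used for predictive ability is the full-data
adjustment, which defines the evaluation target but never enters training.

## Whole-genome regressions

`fit_brr()` and `fit_blasso()` are exact Gibbs samplers (Rcpp) for
$y' = \mu + X a + e$ with markers coded -1/0/1:

* **BRR**: $a_j \sim N(0, \sigma^2_m)$ with a common marker variance;
  $\sigma^2_m$ and $\sigma^2_e$ have scaled-inverse-$\chi^2$ full
  conditionals. With variances fixed (degenerate priors) the posterior
  mean is the ridge solution, which the tests verify against the closed
  form.
* **BLASSO**: the Park-Casella hierarchy $a_j \sim N(0, \tau^2_j
  \sigma^2_e)$, $1/\tau^2_j$ inverse-Gaussian given the current effect,
  and $\lambda^2$ with a Gamma full conditional. This is the conditional-
  on-$\sigma^2_e$ form that keeps the posterior proper and is what the
  standard whole-genome-regression software implements; the published
  model statement leaves the scale of the marker-specific variances
  unspecified.

Default priors are weak: 5 degrees of freedom, scales chosen so the prior
mode splits the phenotypic variance evenly between the genetic and
residual components; the LASSO's $\lambda^2$ prior mode is $2p$. Chain
presets: `paper` (150,000 iterations, 50,000 burn-in, thinning 1000 — 100
retained samples, mirroring the long field-scale chains) and `desk`
(15,000 / 5,000 / 10 — 1000 retained), the default everywhere in this
package. `convergence_check()` provides Geweke-style z-scores (spectral
variances from an AR fit) and optional trace plots.

GEBVs for validation trees are assembled as
$\hat g_i = \sum_j Z'_{ij}\hat a_j$ over the -1/0/1 codes
(`gebv_from_effects()`); the intercept is irrelevant to correlations and
excluded.

## RKHS

`gaussian_kernel()` builds $K_{ij} = \exp(-h\,d_{ij})$ on squared
Euclidean genotype distances. The distances are divided by their
off-diagonal mean by default: over tens of thousands of markers the raw
$d_{ij}$ are in the thousands and $\exp(-0.25\,d)$ underflows to zero, so
a bandwidth of $h = 0.25$ is only meaningful on a normalised distance
scale. The literal unscaled form stays available via
`scale_distance = FALSE`. `fit_rkhs()` samples genetic values
$a \sim N(0, K\sigma^2_a)$ by regressing on the scaled eigenvectors of $K$
(an exact reparameterisation), which reuses the BRR Gibbs sampler and
yields predictions for unphenotyped individuals through their kernel rows.

## Cross-validation engine

`cv_scenario()` declares one experiment cell (model, trait, scope, split
rule, marker subset, replicates); `run_scenario()` executes it. Splits are
true partitions (asserted), replicate seeds are `seed + replicate` and
recorded in every row. Scopes: within one site; cross-site (train on one
entire site, validate on the other — the split rule is moot); joint
(pooled sites on adjusted phenotypes). Relatedness splits resolve
"half-sib" in a diallel — where every parent acts as both dam and sire —
by designating the first parent of each family as its dam: validation
families keep a shared dam in training, and training families carrying a
validation family's sire are discarded so cross-set relatives are half
sibs at most. The unrelated split partitions parents into two groups and
discards straddling families, so no parent appears on both sides; pedigree
BLUP then has exactly zero information about the validation set, and its
predictions are identically zero (reported as accuracy 0 with a
`degenerate` flag — the correlation itself is undefined for a constant
vector).

Marker subsets are chosen on training data only: `random`, or
`largest_positive` — rank by the signed single-marker regression estimate
of the adjusted phenotype and keep the top $m$ (markers monomorphic in
training are excluded).

Metrics: **accuracy** is the Pearson correlation between validation GEBVs
and the reference EBVs; **predictive ability** the correlation with
adjusted phenotypes; **relative efficiency** the ratio of GS accuracy to
pedigree-BLUP accuracy computed from cell means (one RE per cell, matching
how a single ratio is printed next to replicate-averaged accuracies); **RE
per year** multiplies by the cycle-length ratio, by default 25 / 12.5
years. Reported tables round half-up at 2 decimals; raw precision is kept
in the CSVs.

# The synthetic trial generator

The generator emulates the study conditions: 55 founder parents, 128
distinct full-sib families, 5-20 progeny per family per site across 2
sites (the package-wide experiments use 8-12, giving ~1280 trees per
site), 44 post-blocks per site with randomized single-tree plots. Founder
genotypes are i.i.d. Bernoulli draws at marker-specific frequencies from
the configured MAF range; progeny are gene-dropped (one allele from each
parent, markers unlinked). Per trait, a subset of markers is causal; their
per-site effects are bivariate normal with correlation equal to the
trait's type-B target, so G x E is controlled directly. True breeding
values are centred dosages times effects, rescaled so the realised
additive variance among each site's trees hits $h^2\sigma^2_p$; residuals
and i.i.d. block effects are added accordingly. Trait presets give a
low-heritability growth trait with strong G x E (height: $h^2 = 0.15$,
$r_B = 0.45$) and moderate-heritability wood traits with weak G x E
(Pilodyn 0.40/0.90, velocity 0.50/0.85, MOE 0.45/0.90), on field-realistic
unit scales.

Deliberate simplifications, and what they imply for the tests:

* **Markers are unlinked**; there is no within-contig LD decay. Structural
  conclusions that rest on relatedness (full-sib vs half-sib vs unrelated
  ordering; method agreement on polygenic traits) transfer; anything that
  depends on fine-scale LD (absolute marker counts needed to plateau, the
  exact unrelated-set accuracy) does not.
* **Causal markers are genotyped** (captured-QTL regime); non-causal
  markers are neutral. With a desk-scale panel this makes marker-effect
  estimation relatively easier than in a 116k-marker low-LD setting, so
  simulated accuracies are not comparable to the published field values —
  which is why the acceptance checks are structural orderings and
  parameter recovery, never absolute accuracy targets.
* **Block variance defaults to 10% of phenotypic variance and the fixed
  site offset to half a phenotypic SD**; the published design reports
  neither magnitude, and both choices are in the range a field trial of
  this kind shows. Site effects are constant offsets, removed exactly by
  the per-site standardisation.
* One global integer seed drives everything; per-stage streams are derived
  deterministically from it, so every artifact is reproducible from the
  configuration alone.

# Numerical choices and degenerate inputs

Variances are optimised on the log scale, so they are bounded away from
zero but can approach it freely (a simulated-null heritability estimates
at ~1e-8); the unstructured additive covariance cannot leave the valid
cone by construction. Matrix inversions of relationship matrices retry
once with a 1e-6 ridge before failing with a condition-number diagnostic
(a rank-deficient G from a small marker panel routinely needs this).
Kernel eigenvalues below 1e-8 of the maximum are truncated; a kernel with
large negative eigenvalues is rejected. Ratio splits round the training
size half-up; k-fold sizes differ by at most one. Markers that are
monomorphic in a training set keep a zero effect (Bayesian models) or are
excluded from ranking (marker selection). A replicate failure inside a
scenario marks the row failed and the scenario continues; more than 20%
failures is an error.

# Problem sizes used by the shipped analyses

The test-suite and acceptance-script runs use desk scales chosen to keep a
full run interactive on one CPU: parameter recovery uses the full design
(55 parents / 128 families / ~1280 trees per site) with a 600-marker,
500-QTL genome over 30 replicates; the structural cross-validation suite
uses 40 parents / 90 families / ~1450 trees with 3000 markers (1000
causal); the Bayesian-vs-BLUP agreement check uses an 800-marker panel.
The `analysis/` scripts run the same pipeline at the full trait set and a
finer experiment grid. All of these are configuration values, not limits
of the implementation: the structured REML path is size-independent in the
number of trees, and the samplers scale linearly in markers x individuals
x iterations.

# Known limitations

No dominance or epistasis; no selection over generations; no spatial
adjustment beyond post-blocks; no multi-trait models; single-kernel RKHS
only; LD-based imputation and LD pruning are out of scope (mean or
Hardy-Weinberg random imputation stand in). The published 5.9% imputation
rate and the 77k "independent SNP" count depend on the real data and are
not reproduced.
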