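---
title: "Immunosignature discovery, validation and refinement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunosignature discovery, validation and refinement: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Random-sequence peptide microarrays measure the binding of serum
antibodies to on the order of 10^5 peptides at once.  The resulting
*immunosignature* — the pattern of binding intensities across the array —
can act as a disease fingerprint.  `immunosig` implements a complete
case/control signature pipeline for such data: preprocessing of raw
fluorescence values, an ensemble of six feature selectors run on a
Discovery partition, set-algebra construction of candidate peptide
signatures, AUC-based evaluation on a held-out Validation partition, and a
final per-peptide refinement step across multiple cohort contrasts.  A
synthetic-data generator with a planted signature stands in for serum
array data, so every stage can be exercised and tested at desk scale with
planted ground truth.

## The synthetic-data model

`simulate_abundances()` draws, on the log2 scale, for peptide $p$ on array
$a$ of subject $s$:

$$y_{pa} = b_p + \delta_p \,[s \in \text{cases}] + \gamma_{p,B(a)} + \varepsilon_{pa},$$

with

* $b_p \sim N(\mu_0, \sigma_0)$ — a per-peptide baseline binding level
  (default $\mu_0 = 9$, $\sigma_0 = 1.5$, i.e. raw intensities centred
  around $2^9 = 512$ with a heavy right tail after exponentiation);
* $\delta_p = \pm\,e \cdot \sigma_0$ on a random subset of "planted"
  signature peptides (default 100), where $e$ is `effect_size` (default
  1.5) and the sign is negative for a configurable fraction
  (`effect_sign_mix`, default 0.5) of planted peptides — antibody binding
  can go up or down in cases;
* $\gamma_{p,B} \sim N(0, 0.3)$ — a per-peptide, per-batch shift; the
  Discovery and Validation partitions are separate assay experiments and
  carry distinct batch labels;
* $\varepsilon_{pa} \sim N(0, \log_2(1 + \text{cv}))$ — technical
  replicate noise with raw-scale coefficient of variation `cv` (default
  0.1).

Raw values are $2^{y}$, rounded to integers and clipped to
$[0, 65535]$ — the range of a 16-bit digitizer.  Arrays listed as outlier
replicates have their values permuted across peptides, which destroys
within-pair concordance while leaving the marginal distribution intact;
this gives the replicate-QC test a well-defined target.

Two modelling decisions deserve emphasis:

* **Effect-size unit.**  The planted shift is expressed in units of
  $\sigma_0$, the spread of per-peptide baseline levels, giving
  $\delta \approx 2.25$ log2 units (a four- to five-fold change) at the
  default effect size.  Differential antibody binding in immunosignature
  data is of this order — serology signals are strong relative to the
  technical noise of the platform.  This choice also makes the planted
  block detectable by *unsupervised* selectors: a planted eigen-signal
  must clear the Marchenko–Pastur noise bulk of a
  $10^4 \times 43$ matrix before any variance-driven method can see it,
  which requires the shift to be several times the within-group noise SD.
  A generator that scaled effects to the technical noise would make
  unsupervised recovery information-theoretically impossible at these
  dimensions while leaving supervised selectors unaffected — a regime that
  cannot reproduce an ensemble analysis in which both branches contribute.
* **No subject-level biological variability.**  Within a group, subjects
  share the same expected immunosignature; all within-group variation is
  technical (replicate noise, rounding, saturation).  Real serum samples
  of course vary biologically between subjects; the generator therefore
  overstates attainable AUCs and test power relative to real data.
  Passing recovery tests demonstrate that the pipeline machinery is
  correct — selectors find what was planted, set algebra and refinement
  behave as specified — not that real ME/CFS serum would yield these
  AUCs.  The generator also models no sequence-dependent binding, no
  spot-level artifacts, and log-normality is a stand-in, not an empirical
  claim about array intensity distributions.

## Preprocessing

* **Control peptides** are averaged per array (reported for QC) and
  removed from the analysis matrix.  The control summary is not used to
  rescale samples.
* **Replicate QC**: each duplicate pair is scored by the Spearman rank
  correlation of its two arrays over log2 analysis values; a pair whose
  concordance falls below `min_concordance` (default 0.8) is removed
  whole.  Rank correlation is scale-free, robust to saturation, and
  collapses to ≈ 0 for the permutation-style corruption being modelled.
* **Merging**: surviving pairs are averaged element-wise on the raw
  scale.  Singletons are removed unless exempt (the US control cohort is
  run as exempt singletons by design).
* **Normalisation**: each sample is log2-transformed and centred at its
  own median.  Dividing raw values by the per-sample median *before* the
  log only zeroes the log-scale median when the peptide count is odd; for
  even counts the two central peptides differ and the median of logs is
  the log of their geometric midpoint.  Centring on the log scale makes
  the median-zero invariant exact (tolerance 1e-9 in the tests) and is
  identical to the raw-scale formula for odd counts.  Zero raw values are
  replaced by 0.5 (half the minimum detectable count) before the log.

## Feature selectors

Three unsupervised selectors run blind to group labels and return ten
lists each; three supervised selectors return one list each.

* **Sparse PCA** (`sparse_pca_lists`): soft-thresholded power iteration in
  the penalized-matrix-decomposition style, with the threshold set each
  iteration to the $(k{+}1)$-th largest score so each component has
  exactly `k_features` (default 100) nonzero loadings; components are
  extracted by multiplicative deflation.  Initialisation is spectral, so
  the algorithm is deterministic.
* **Sparse IPCA** (`sparse_ipca_lists`): the leading principal subspace is
  rotated by symmetric FastICA (cubic, kurtosis-seeking nonlinearity) so
  that each rotated loading vector is maximally non-Gaussian; the
  `k_features` largest-|loading| peptides are kept per component.
  Sparse, spiky loading patterns are exactly the high-kurtosis directions
  this rotation seeks, which is what makes it useful when several planted
  patterns mix within the leading subspace.  Components are ordered by
  the excess kurtosis of their loadings.
* **Gene shaving** (`gene_shaving_lists`): repeatedly computes the first
  principal component of the current peptide set, shaves off the
  `shave_fraction` (default 10%) of peptides least aligned with it, and
  scores every set in the nested sequence by the variance ratio
  $R^2 = \mathrm{Var}_\text{between}(\bar{x}) / \overline{\mathrm{Var}}_\text{within}$
  of the *sign-aligned* cluster mean ("super-peptide": members negatively
  aligned with PC1 are flipped before averaging, so up- and down-regulated
  peptides reinforce rather than cancel).  The cluster size is chosen by
  the gap statistic — observed $R^2$ minus its mean over
  `n_permutations` (default 20) row-permuted matrices — and the matrix is
  orthogonalised with respect to the retained cluster's mean profile
  before the next cluster is sought.  Cluster sizes are selected
  automatically, unlike the fixed-support sparse selectors.  For speed the
  implementation maintains the $n \times n$ sample Gram matrix and
  downdates it as rows are shaved, so PC1 is exact at every step at
  $O(n^2)$ cost per step plus two passes over the submatrix.
* **Moderated t** (`moderated_t_select`): per-peptide two-sample t with
  empirical-Bayes variance moderation
  $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on $d_g + d_0$
  degrees of freedom.  The hyperparameters $(s_0^2, d_0)$ are estimated by
  log-scale moment matching (digamma/trigamma inversion) on variances
  winsorised at their 5th/95th percentiles — a minimal robustification
  against outlier variances; the unwinsorised path is cross-checked
  against the reference empirical-Bayes fit in the test suite.  Setting
  $d_0 = 0$ reproduces the ordinary pooled-variance t exactly.  The list
  keeps peptides with BH-adjusted $p \le$ 0.05.
* **Random forest** (`random_forest_select`): a 1000-tree classification
  forest; peptides are kept when their Mean Decrease Gini importance
  reaches a threshold, by default the 99.7th percentile of importances
  from one refit with permuted labels — an estimate of the upper tail of
  chance importance.  The forest is fitted with a fast single-threaded
  implementation; the test suite checks its importance ranking against
  the classic reference implementation.
* **Elastic net** (`elastic_net_frequency_select`): 100 runs, each
  dropping two cases and two controls at random (39 of 43 Discovery
  samples per run), fit an elastic-net-penalised logistic model
  (mixing parameter 0.5) with internal cross-validation for the penalty.
  A peptide's selection frequency is the fraction of runs with a nonzero
  coefficient at the selected penalty; the list keeps frequencies ≥ 10%.
  The internal CV uses 5 folds over a 30-value penalty path down to 5% of
  the largest penalty, with a relaxed convergence threshold — settings
  chosen once so that 100 runs complete comfortably at desk scale; the
  frequency ranking is insensitive to them.

All stage and run seeds derive from one master seed through a documented
counter scheme (`derive_seed`), so the entire ensemble is reproducible
from a single integer.

## Panels and candidate signatures

The study this pipeline models reviewed the ten lists of each
unsupervised method and kept the best-separating ones.  `assemble_panel`
operationalises that review: each list is scored by the AUC of its
signature score on the Discovery data, and the best list plus any list
within 0.02 AUC of it — at most `max_lists` (default 2) — are unioned into
the method panel.  Supervised lists pass through unchanged.

`build_candidate_signatures` combines the six panels:
CPS001 = GS ∩ (RL ∪ RF ∪ EN); CPS002/CPS003 = union/intersection of the
unsupervised panels; CPS004/CPS005 = union/intersection of the supervised
panels; CPS006/CPS007 = union/intersection of all six.  Empty signatures
are flagged excluded rather than dropped.  The alternative
GS ∩ RL ∩ RF ∩ EN definition of CPS001 is computed and reported but not
carried forward (it was considered and dropped for yielding too small a
panel).

## Scoring and evaluation

The signature score of a sample is the mean over signature peptides of
the sign-adjusted processed abundance.  Per-peptide signs come from the
first principal component of the peptide-standardised signature
submatrix; zero loadings count as +1.  PC1's overall sign is
mathematically arbitrary, so a single global orientation is resolved with
the known group labels: the implementation picks the orientation whose
AUC is ≥ 0.5 (ties broken by the case-minus-control mean).  Orienting on
the AUC rather than the mean difference guarantees the reported-AUC ≥ 0.5
invariant exactly, which a mean-based rule does not in edge cases.

AUC is the Mann–Whitney statistic (ties count one half), checked against
an exhaustive pair-counting oracle in the tests.  Two further views
support validation:

* `pc1_weight_auc` ranks all peptides by |PC1 weight| of the full
  peptide-standardised matrix and computes the AUC of signature
  membership against that ranking — values near 1 mean the signature's
  peptides dominate the primary axis of sample separation.  By default
  the PCA uses the evaluated partition only.
* `cluster_view` projects samples on the first two PCs of the
  row-standardised signature submatrix and cuts an average-linkage
  dendrogram on correlation distance into two clusters, all blind to
  labels; labels enter only the reported Rand index.  Correlation
  distance with average linkage is the standard choice for
  expression-style heatmaps; both are configurable.  Constant peptide
  rows (SD 0) are dropped with a warning.

## Refinement

`refine_signature` Welch-tests (unequal variances, Satterthwaite degrees
of freedom) every signature peptide in four cohort contrasts — discovery
Canadian cases vs controls; validation Canadian cases vs controls;
Norwegian cases vs validation-Canadian controls; Norwegian cases vs US
controls — and keeps peptides with $p < 0.05$ in **all four**.  P-values
are unadjusted by default: the conjunction across four independent-sample
comparisons is itself the stringency mechanism (a null peptide survives
with probability ≈ $0.05^4$); a per-comparison BH option exists but is
off by default.  Comparisons use processed values, consistent with every
other analysis stage.

## Numerical choices and degenerate inputs

* Eigen/singular vectors get a deterministic sign (largest-|entry|
  positive), so PCA-derived quantities are reproducible and data negation
  flips scores exactly.
* Tie-breaks: the gap statistic prefers the smaller cluster on ties;
  AUC ties count 0.5; zero PC1 loadings take sign +1.
* Degenerate inputs fail loudly: empty signatures, single-class labels,
  groups smaller than two, subjects with more than two replicates,
  non-positive sample medians, and peptide ids missing from the library
  or matrix are all explicit errors.
* Rank deficiency: sparse PCA/IPCA return fewer lists with a warning when
  the matrix cannot support the requested components; gene shaving caps
  the cluster count at the peptide count.

## Problem sizes

The package defaults run the full pipeline at 10,000 analysis peptides
(plus 200 controls) with 100 planted peptides under the 84-subject
multi-cohort design — large enough for the high-dimensional effects that
matter (noise eigenvalue bulk, BH multiplicity, stability selection) and
small enough that a complete run takes under a minute on one core.  The
test suite exercises recovery across 20 independent simulated studies at
this scale; unit and property tests use matrices from a handful to a few
thousand peptides.  The full-scale 125,000-peptide library (122,926
analysis features) is generated and checked structurally, but the
discovery analyses are not run at that width by default.

## Known limitations

* The generator's subjects are exchangeable within group; there is no
  subject-level biological variance, no age/sex structure, and no
  cohort-specific effects beyond the assay batch shift.
* The panel-selection rule is an automated stand-in for a human review of
  list separation; with real data the reviewed choice could differ.
* "Robust" variance-prior estimation is winsorisation-based; other
  robustifications are possible and the hyperparameters are exposed.
* The pipeline evaluates signatures; it does not estimate generalisation
  error of the selectors themselves (no nested cross-validation), and no
  clinical covariates or response outcomes are modelled.
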