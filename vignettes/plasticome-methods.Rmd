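---
title: "Methods: quantifying gut microbiota plasticity in longitudinal 16S cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gut microbiota plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(plasticome)
```

## The problem

Weight-loss interventions produce very different outcomes in otherwise
similar people, and attention has turned to whether the gut microbiota
predisposes some individuals to succeed on a particular diet. Beyond a
static snapshot of community composition, a candidate predictor is the
*plasticity* of a person's microbiota: how much its composition moves from
day to day, and how much it shifts over the first weeks of a new diet.
`plasticome` implements the full analysis stack for this question on
longitudinal 16S rRNA amplicon sequence variant (ASV) data: per-subject
plasticity statistics, the supporting alpha- and beta-diversity machinery,
phylogenetic clustering of ASVs, a variance-stabilized moderated
differential-abundance pipeline with within-subject correlation,
Prevotella/Bacteroides (P/B) ratio classification, ordination, and
PERMANOVA — together with a synthetic-cohort generator so that every stage
is testable end-to-end without any sequencing data.

The assumed sampling design is two diet arms (a carbohydrate-restricted and
a fat-restricted arm), with each subject contributing a handful of daily
stool samples in a pre-diet window ("BL") and again about ten weeks into
the intervention ("W10"), sequenced across several lanes. Subjects carry a
12-month weight-loss outcome, classified as unsuccessful (US, < 3% of
baseline weight lost), moderately successful (MS, 3–10%, boundaries
inclusive) or very successful (VS, > 10%).

## Plasticity

Plasticity is a per-subject statistic: the mean pairwise beta-diversity
between a subject's samples.

* **Daily plasticity** (`BLvBL`, `W10vW10`): for a subject's samples within
  one window, sorted by collection day, only *consecutive* pairs enter the
  mean — a three-sample series contributes pairs (1,2) and (2,3), never
  (1,3). "Consecutive" means successive in collection order, not
  calendar-adjacent, so subjects whose samples sit a few days apart still
  contribute. Subjects with fewer than two samples in the window are
  excluded rather than imputed.
* **Cross-period plasticity** (`BLvW10`): the mean over the full bipartite
  set of (pre-diet, 10-week) pairs.

Each subject contributes a single averaged value per pairing and metric;
group comparisons (US vs VS, via the two-sided Wilcoxon rank-sum test, run
separately per diet) and covariate correlations (Spearman) operate on these
subject-level means, never on individual sample pairs. Whether the
consecutive-pairs rule also applies in the 10-week window is not externally
fixed; the same estimator is used in both windows for symmetry.

Five bounded metrics are provided. Presence/absence structure is captured
by Jaccard dissimilarity and unweighted UniFrac; abundance structure by
Bray-Curtis, normalized weighted UniFrac, and the Jensen-Shannon
divergence. Jensen-Shannon uses log base 2 so its range is [0, 1] and the
divergence itself (not its square root) is reported; weighted UniFrac is
the normalized variant so that all five metrics share the [0, 1] scale.
Plasticity distances default to per-sample proportions; the
asinh-of-normalized-counts scale is reserved by default for ordination,
where variance stabilization matters most, but either analysis can use
either scale via the `scale` argument.

## Rarefied phylogenetic alpha-diversity

Faith's phylogenetic diversity (PD) is the total branch length spanned by
the tips observed in a sample; it grows with sequencing depth, so samples
are compared at a common interpolated depth $m$ via the exact expectation
under subsampling without replacement:

$$E[\mathrm{PD}_m] \;=\; \sum_b L_b\left(1 -
  \frac{\binom{N-n_b}{m}}{\binom{N}{m}}\right),$$

where $N$ is the sample's depth and $n_b$ the reads descending from branch
$b$. Binomial coefficients are computed on the log scale, so deep samples
pose no numerical problem. The default depth of 11,000 reads reflects a
typical minimum post-filter library size; samples below $m$ are reported
missing — interpolation only, never extrapolation. PD counts the branches
on root-to-tip paths of observed tips; a root subtending edge, if present
in the file, is excluded.

## Phylogenetic clustering of ASVs

Exact-sequence denoising yields very sparse tables. To gain overlap between
subjects, ASVs are grouped by cutting the phylogeny at a height $h$
(default $h = 0.1$ substitutions/site, which for ~233-bp V4 amplicons
corresponds to roughly 96.8% identity — the neighbourhood used to delimit
genera; see `height_to_identity()`). Maximum-likelihood trees are not
ultrametric, so "cutting at height $h$" is realized as average-linkage
agglomerative clustering of the patristic (tip-to-tip path length) distance
matrix, cut at merge height $h$. Average linkage is monotone, so partitions
refine as $h$ decreases; cluster labels are assigned deterministically from
each cluster's lexicographically first member. This convention is
documented as the package's realization, not asserted as the only possible
reading of tree cutting on a non-ultrametric tree. Aggregation sums member
columns and conserves per-sample totals exactly.

Features entering differential-abundance testing must be detected in at
least 10% of the subjects on the focal diet (ceiling rule at the boundary).
Prevalence is counted at the *subject* level — a feature is "in" a subject
if any of that subject's samples has a positive count — because replicate
daily samples would otherwise inflate per-sample prevalence.

## Differential abundance

The stack mirrors a limma-style moderated linear-model analysis, adapted to
sparse 16S counts:

1. **Size factors** by the *poscounts* median-of-ratios rule: each
   feature's reference is the geometric mean of its *positive* counts, and
   each sample's factor is the median of count/reference over the features
   where the sample is positive, rescaled to geometric mean 1. This keeps
   structural zeros from dragging references to zero.
2. **Variance-stabilizing transform**: $y = \sinh^{-1}(\text{count}/s_j)
   = \log(x + \sqrt{1+x^2})$, which is defined at zero (the point of
   preferring it over a log) and close to $\log(2x)$ for abundant taxa.
3. **Precision weights** (voom-style): per-feature OLS residual standard
   deviations against the design are lowess-smoothed (span 0.5, 3
   robustifying iterations) on the square-root scale as a function of mean
   transformed abundance; each observation's predicted square-root SD is
   interpolated at its fitted value — clamped at the trend endpoints, the
   known failure mode of mean-variance trends at extreme abundances — and
   inverted to a fourth-power weight. A floor of $10^{-4}$ on the predicted
   scale guards degenerate zero-variance features.
4. **Consensus within-subject correlation**: repeated daily samples are
   modelled with a compound-symmetry block per subject. Per feature, the
   intra-block correlation is estimated from OLS residuals by solving the
   two exact moment equations that account for the hat-matrix projection
   (raw residual cross-products are attenuated by $I - H$ and would bias
   the estimate low); the consensus is the tanh of the 10%-trimmed mean of
   the per-feature atanh correlations, clipped to $(-0.99, 0.99)$. All
   blocks singleton returns 0 with a warning.
5. **Moderated GLS fit**: per feature, generalized least squares with the
   consensus compound-symmetry correlation and the voom weights. Residual
   variances are shrunk toward an empirical-Bayes prior $(d_0, s_0^2)$
   estimated by moment matching on $\log s^2$ (digamma/trigamma matching,
   with a Newton inverse-trigamma); the posterior variance is
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated $t$ has
   $d + d_0$ degrees of freedom. If the trigamma equation has no positive
   solution the prior collapses to $d_0 = \infty$ (pooled variance) with a
   warning.
6. **Design and contrasts**: both diets are fit jointly for shared variance
   moderation, with a diet × success cell-means design (so within-diet
   contrasts are single coefficient differences), a fixed effect for
   sequencing lane, and MS samples retained in the design even though only
   the VS − US contrast is tested per diet. The reported `logFC` is the
   contrast on the asinh scale, sign convention VS minus US (positive =
   more abundant in very successful subjects). A continuous mode replaces
   the cell means with per-diet intercepts and per-diet slopes on percent
   weight loss. Benjamini–Hochberg adjustment is applied within each diet's
   contrast, restricted to that diet's prevalence-retained features, at
   $\alpha = 0.05$.

## Community statistics

**P/B ratio.** Per sample, the Prevotella genus count sum over the
Bacteroides genus count sum, with a pseudocount of 1 substituted for
Prevotella exactly when it is zero (never added unconditionally) — about
half of subjects in Western cohorts carry no detectable Prevotella.
Samples with zero Bacteroides have an undefined ratio and are excluded with
a warning. Subject values are means over pre-diet samples; subjects are
dichotomized at a cutoff of 0.003 (boundary classed "high"), a threshold
suited to low-Prevotella cohorts. Ratios use raw genus count sums: library
size cancels in the ratio except through the pseudocount.

**Ordination and PERMANOVA.** Principal coordinates analysis is classical
scaling (negative eigenvalues dropped and counted), by default on
Bray-Curtis distances of asinh-transformed normalized counts. PERMANOVA
partitions squared distances (Anderson's partition) and permutes labels
with an explicit seed, $p = (1 + \#\{F^{perm} \ge F\})/(n_{perm}+1)$,
default 999 permutations. Labels are permuted at the sample level by
default; a `strata` argument permutes whole subjects for repeated-measures
layouts. `vegan::adonis2` is used as an independent cross-check in the test
suite, never as the implementation.

**Rank statistics.** The Wilcoxon rank-sum test is exact for combined
$n \le 20$ without ties (plasticity group sizes make exactness affordable)
and the tie/continuity-corrected normal approximation otherwise; Spearman
correlation is exact for $n \le 10$ and $t$-approximate above.

## The synthetic-cohort generator

The generator (`sim_config()` / `simulate_cohort()`) emulates the
*statistical structure* the analyses assume; no public generative model
exists for such cohorts, so all distributional choices are stand-ins,
documented here and fixed:

* global mean composition from a symmetric Dirichlet (concentration 0.5,
  giving realistic dominance and sparsity);
* per-subject baseline: log-composition plus i.i.d. Normal(0,
  `sigma_subject`²) per-taxon offsets — subject individuality;
* per-day Normal(0, `sigma_plasticity`²) perturbations about the subject
  centroid, exchangeable across days rather than a random walk: day-to-day
  variability is treated as a subject-level *trait*, which makes the
  plasticity estimand well-defined;
* a W10 shift of magnitude `delta_diet_shift` along a fixed unit direction
  per diet, scaled by each subject's dietary change relative to the arm
  mean;
* pre-diet differential taxa shifted by ±`da_effect` on the log scale
  between VS and US subjects (MS halfway), injected only into taxa
  abundant enough (expected count ≥ 20 at the median depth) that the
  log-scale shift equals the labelled asinh-scale effect;
* multiplicative per-lane taxon bias on the log scale, applied before the
  count draw, so the lane fixed effect in the model has something real to
  remove;
* counts Multinomial(depth, softmax(η)) with log-normal depths; per-sample
  totals equal the drawn depth exactly;
* half the subjects carry no Prevotella at all, mirroring observed
  carriage; weight loss is drawn per arm (Normal with means 8.4% and 6.3%,
  SD 7.7%) and redrawn until all three success categories occur; dietary
  recalls for the restricted component are drawn around published
  arm-level means.

Defaults are 32 subjects per arm, 1,000 taxa, 3 days per window, 7 lanes,
and a log-normal depth with mean ≈ 73,700 and SD ≈ 33,400 reads — the
scale of a real daily-sampling 16S cohort. `sigma_subject = 0.8` and
`sigma_plasticity = 0.5` were fixed a priori by two design requirements:
within-subject distances must sit clearly below between-subject distances
(subject individuality dominates daily turnover), and an asinh-scale
effect of ~1.5 between success groups of ~10 subjects per arm must be
detectable in principle — a subject-level log-abundance SD much above 1
would make any such cohort design hopeless, which is not the regime these
studies operate in.

What the generator does **not** emulate: real taxonomic covariance
structure (taxa are perturbed independently), compositional interactions,
phylogenetic signal in abundances (the tree is independent of the
composition), zero-inflation beyond the multinomial, day-of-week or
dietary-intake drivers of variability, and realistic taxonomies beyond the
two genera the P/B ratio needs. Tests passing on synthetic cohorts
therefore validate the *estimators and their calibration under the stated
model*, not the biological conclusions one would draw from real data.

## Numerical and convention choices

* TSV is the single file dialect (tab-delimited, UTF-8, `.` decimal), with
  samples as rows and ASVs as columns; missing genus is the empty string.
* Strict integer validation on count tables; errors name the offending
  (sample, ASV) cell.
* Success boundaries 3% and 10% are assigned to MS (the conventional
  "3–10%" reading, with strict inequalities for US and VS).
* Missing individual dietary recalls are dropped from means, not imputed.
* `cut_tree` tie-breaks and cluster numbering are deterministic
  (lexicographic first member).
* The P/B boundary value (exactly 0.003) is classed "high" — arbitrary but
  fixed and tested.
* Whitening for the compound-symmetry GLS uses an eigendecomposition
  inverse square root per block size, cached; the design is re-checked for
  rank after weighting.

## Problem sizes in the test suite

The packaged tests exercise the estimators at sizes chosen to be
informative yet quick: parameter recovery for plasticity uses cohorts of
40 subjects × 6 samples × 500 taxa at depth 10,000 (5 seeds);
differential-abundance calibration uses 200 features and 30 subjects per
diet × 2 replicate days (20 null cohorts, 10 with 20 injected taxa at
effect 1.5); oracle comparisons (subsampling PD, least-squares
equivalence, planar PCoA recovery, the 4-point PERMANOVA pseudo-F) run at
hand-checkable sizes.

## Known limitations

* A single consensus within-subject correlation is shared across features
  whose true correlation varies with abundance (counting noise dilutes the
  subject effect for rare taxa). The most abundant features are therefore
  slightly under-whitened, which mildly inflates the far tail of the
  moderated statistics — in null simulations the raw type-I error is
  calibrated (≈ 0.05), but isolated |t| ≈ 4 events occur slightly more
  often than nominal. This is inherent to the consensus design; a
  per-feature shrunk correlation would be the remedy but a different
  method.
* Empirical-Bayes moment matching assumes the scaled inverse-chi-square
  variance model; genuinely outlying variance features are shrunk like all
  others (no robust down-weighting).
* The weighted UniFrac normalization and the plasticity count scale are
  conventions (normalized variant; proportions), made explicit and
  configurable rather than asserted as universal.
* Cohort-scale biological findings (specific differentially abundant
  clusters, cohort p-values) require real sequencing data; nothing here
  claims to reproduce them from simulation.
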