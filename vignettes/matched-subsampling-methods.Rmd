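---
title: "Matched-control subsampling and compositional analysis: methods"
author: "micromatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-control subsampling and compositional analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cross-sectional microbiome surveys recruited through citizen science are
large but unbalanced: one age group (often teenagers sampled through
schools) dominates, health conditions of interest occur in a few dozen
donors, and geography, gender and age are all confounded with the variables
one wants to test. Comparing a 40-donor condition group against 1500
unmatched controls answers the wrong question. micromatch implements the
design such studies call for: draw matched controls repeatedly, run every
statistic once per draw, and report the consensus across draws.

# Compositional geometry

Amplicon counts are compositional: only relative information is meaningful,
and per-sample sequencing depth is arbitrary. All multivariate analyses
therefore operate in Aitchison geometry. Counts $x$ are mapped per sample to
centered log-ratios,
$$\mathrm{clr}(x)_i = \ln(x_i + c) - \frac{1}{p}\sum_j \ln(x_j + c),$$
with pseudocount $c = 1$ by default (the conventional choice for amplicon
tables; it is exposed as a parameter and pinned by the tests, because the
limit $c \to 0$ matters for the closed-form identities). Beta diversity is
the Euclidean distance between CLR vectors (the Aitchison distance). Two
consequences the package relies on:

* the distance is invariant to per-sample depth rescaling (exactly so in the
  small-pseudocount limit; the tests verify it at $c = 10^{-9}$), and
* the distance matrix embeds exactly in principal-coordinate space — no
  negative eigenvalues — so the dispersion analysis never needs the
  imaginary-part correction (which is nevertheless implemented for foreign
  distance matrices, with squared corrections floored at zero).

UniFrac distances are also provided for phylogeny-aware replication:
unweighted (fraction of branch length unique to one of the two samples) and
the normalized weighted variant. A caveat found and pinned by the test
suite: *normalized weighted* UniFrac is not a metric — its per-pair
normalization can violate the triangle inequality (we observed violations
of ~0.02 on random fixtures) — so only Aitchison and unweighted UniFrac are
asserted to be metrics.

# Matched-control subsampling

For a binary variable the engine draws, `n_reps = 100` times, an equal
number of cases and controls: `min(cap, |yes|, |eligible controls|)` of
each, with `cap = 100`. Controls are drawn stratified on the joint gender ×
region × age-bin distribution of the drawn cases, relaxing to nearest-age
within gender × region (then nearest-age overall) when a stratum is
exhausted. Each repetition logs a matching report (Kolmogorov–Smirnov age
p, chi-square gender and region p); the reports are recomputed per
repetition, not once globally. Eligibility rules:

* samples missing age or gender are never used;
* samples with any chronic disorder are excluded from *both* groups, except
  that carriers of the tested disorder form the case group;
* controls must come from regions in which cases were collected.

For age analyses, samples are binned into 13–20, 20–30, 30–40, 40–50,
50–60 and >60 years. Balance across bins is achievable only over gender ×
region cells occupied in every bin; the engine restricts to those cells,
fixes one target composition (the pooled mix over them), and sizes each
bin's draw by its availability relative to that composition. Realized
per-bin sizes are therefore constant across the 100 repetitions and differ
between bins only through availability — the same qualitative pattern as in
large real cohorts, where a dominant teen bin still contributes only as
many samples per draw as the scarcest bin's balanced composition allows.
The same ensembles serve tests with age as a continuous covariate, which is
why an even, balanced age spread matters. Chronically ill samples are
excluded from the age ensembles as well, so age effects are estimated in
the disorder-free population.

Randomness: one master seed; per-repetition seeds are derived by a counter
and stored in the ensemble for replay.

# Multivariate tests

**PERMANOVA.** Sequential (order-of-entry) partitioning of the
Gower-centered distance matrix, with the variable of interest first and
gender, age and log town population after (town population enters as a
numeric log-scaled proxy of location/lifestyle; a design choice, since a
categorical town term would be nearly saturated). Significance is by free
permutation of sample labels, observed statistic included in the null set,
999 permutations by default. Computation is delegated to `vegan::adonis2`;
the test suite checks it against an exhaustive-enumeration oracle (p = 0.1
on the canonical 6-sample two-group fixture) and against classical one-way
ANOVA F on 1-D Euclidean data. A marginal-SS mode (`by = "margin"`) is
available; note marginal tests no longer decompose the total sum of
squares.

**Homogeneity of dispersion.** Each group's spread is summarized by the
distances of its samples to the group's spatial median in
principal-coordinate space, compared across groups by one-way ANOVA
(`vegan::betadisper(type = "median")`). The spatial median minimizes summed
Euclidean distance; the tests verify it against a grid-search oracle to
1e-3. Small groups overfit their own median, which biases their distances
downward and inflates type-I error when group sizes differ; the
small-sample bias adjustment is therefore on by default. With it, the null
rejection rate on simulated cohorts is 5.0% (it is ~13% without, at 10 vs
50 group sizes).

**anosim.** Rank-based similarity analysis over family units (twins,
siblings, partners, parents–children, grandparents–grandchildren, any
family) and classmates (units = school ids, treated exactly like family
units). Only samples with at least one partner of the requested
relationship — units of two or more — enter. R is the normalized difference
of mean between-unit and within-unit ranks, invariant under monotone
distance transforms; ties get average ranks.

**Twins vs siblings.** Two-sided Mann–Whitney test of within-twin against
within-sibling Aitchison distances; exact when sample sizes permit, checked
against full enumeration in the tests.

# Trend models and consensus

Differential abundance across age (or any focal covariate, including oral
pH) uses ordinary linear models on CLR abundances and diversity measures —
a Gaussian identity-link model is the coherent reading of a "generalized
linear model" once responses are real-valued CLR values — with gender, age
and log population as covariates. Age can enter through an orthogonal
degree-2 polynomial, the minimal basis that detects a parabolic trend as a
single 2-df term. Per-term p-values are type-II (`car::Anova`), hence
invariant to term order (tested).

Consensus across the ensemble: within each subsample, focal-term p-values
are Benjamini–Hochberg adjusted across the responses of that batch (the
FDR family is the batch of responses tested together within one subsample;
this is configurable, since other families are defensible); each response
is then summarized by the mean adjusted p and the number of subsamples
significant at 0.05. Direction labels: majority coefficient sign
(`increase`/`decrease`), or for quadratic age fits a shape label —
`parabolic` when the quadratic term is significant with an interior vertex,
`late-rise` when the fitted curve is flat below age 50 but rises overall.
Subsample fits that fail are excluded and counted.

# Co-occurrence networks and uniqueness

Taxa with fewer than 15 counts in fewer than 20 samples are removed first
(sporadic taxa generate spurious associations); for tables under 100
samples the sample threshold rescales proportionally, with a warning.
Networks are sparse conditional-dependence graphs on CLR values. Two
backends:

* `mb`: per-taxon lasso regressions over a regularization path with StARS
  stability selection (50 random 80% subsamples, target instability 0.05;
  the sparsest penalty whose monotonized instability stays within target);
  strength is the symmetrized coefficient.
* `pcor`: partial correlations from the inverse of the CLR covariance,
  thresholded on absolute value — orders of magnitude faster, used when
  hundreds of networks must be fit across an ensemble. Because CLR rows sum
  to zero the covariance is singular along the constant direction; the
  inverse is taken on the informative eigenspace only (plus a small ridge),
  otherwise that null direction floods every partial correlation.

Both backends inherit CLR's depth invariance, and edge sets are invariant
to taxon order (tested). A compositional caveat, pinned by a test: with
very few taxa each CLR value is nearly the negative sum of the others, so
per-taxon regressions degrade; network analyses should run on tables of a
few dozen taxa or more.

The uniqueness score compares variables by their *universally reproducible,
exclusive* associations: for variable $v$, the core is the set of edges
present in every one of $v$'s subsample networks (strictly — an edge in 99
of 100 networks does not count); against another variable $w$, the score
sums, over core edges absent from all of $w$'s networks, the mean absolute
strength across $v$'s networks. Edge identity is the unordered taxon pair,
sign-insensitive by default (a sign-sensitive mode exists). Per variable we
report both the sum and the mean over pairings, plus the spread, since
either aggregate is defensible. Choosing the partial-correlation threshold
for ensemble use should track the subsample size: we size it so that noise
edges are familywise-rare per network (e.g. 0.6 at ~45 samples and ~35
taxa), which makes the strict all-subsamples core a reliable filter.

# The synthetic cohort generator

The generator exists so every stage can be validated by parameter recovery.
It emulates: a teen-heavy six-bin age distribution (default weights
964:41:28:85:46:42, the shape of a school-recruited cohort with condition
subgroups); mutually exclusive chronic disorders (cystic fibrosis, Down
syndrome, celiac — honoring the exclusion rule that treats them as one
stratum) alongside independent lifestyle flags; family units of 2–3 with
labelled relationships and schools for the under-20s, both sharing latent
compositional components; pH decreasing and BMI increasing with age; and a
quadratic dispersion curve, minimal at age 45 (values ≈1.6 at age 13, 0.9
at 45, 2.0 at 85), so middle-aged samples are the most homogeneous and
seniors the most variable.

Counts follow a logistic-normal–multinomial: latent log-composition =
per-taxon baseline (log-normal rank-abundance, sd 1.5) + linear age trend
on the CLR scale + additive condition shifts + family/classroom components
+ heteroscedastic noise; softmax; multinomial at fixed depth (column sums
are exact). Effects are planted additively on the CLR scale — the same
scale the analysis models operate on — which is what makes recovery
well-posed; a Dirichlet-multinomial would not give that identification.
Condition-exclusive *dependencies* (for network validation) are planted as
shared latent factors over taxon pairs, active only in flagged samples, and
drawn from the abundant 60% of taxa so the planted edges survive rare-taxon
filtering. Ages are uniform within bins (only bin counts are meaningful
study conditions); twins share no stronger component than siblings, because
the phenomenon being emulated is shared environment, not genetics.

What the generator does *not* emulate: read-level error, chimeras,
contamination, batch effects, realistic phylogenetic signal in the
abundances (the tree is random with exponential branch lengths), or
realistic co-morbidity beyond the chronic-exclusivity rule. Passing
recovery tests therefore demonstrates the statistics are implemented and
calibrated correctly, not that they would behave identically on real
sequencing artifacts.

# Validation scenarios and problem sizes

The validation experiments (in the test suite and the acceptance script)
use these scales, chosen so each check has clear power at desk scale:

* **Type-I control**: 800 null cohorts (no planted effects, flat
  dispersion, units off) of 60 samples × 20 taxa; PERMANOVA, dispersion
  ANOVA, anosim and per-term trend rejections must all lie in 5% ± 2%
  (199 permutations).
* **Age structure**: 300 samples × 80 taxa, extreme-enriched bin weights
  (2:1:1:1:1:2), linear CLR trends on 15 taxa of 0.025 per year — sized so
  continuous-age PERMANOVA explains ≈2–4% of variance, the effect scale
  such cohorts report — with unit effects off to isolate the age
  structure. Checks, over 10 seeds with 100-subsample ensembles: one-vs-rest
  PERMANOVA significant for the extreme bins only; smallest
  distance-to-median in 40–50; quadratic diversity fits beating linear.
  With a linear trend, one-vs-rest deviations are linear in bin centers, so
  concentrating significance in the extremes requires the extreme bins to
  carry weight — hence the enriched weights in this scenario.
* **Trend recovery**: 400 samples × 60 taxa; 6 increases planted on the
  rarest genera and 6 decreases on the most abundant (two passes of the
  generator with the same seed, so baselines are identical); all 12 must be
  recovered with correct direction and ≥80/100 significant subsamples, with
  no null genus reaching consensus significance.
* **Dispersion direction**: default conditions (smokers' dispersion ratio
  0.85); flagged group must come out more homogeneous with ANOVA p < 0.05
  in ≥9/10 seeds.
* **Network uniqueness**: 900 samples × 40 taxa; two taxon-pair factors
  (sd 3) exclusive to smokers; smoking must rank strictly first among four
  variables in ≥4/5 seeds (10-subsample ensembles, cap 45, threshold 0.6).

# Known limitations

* The matching algorithm is stratified sampling with nearest-age
  relaxation, not propensity scores or optimal pair matching; with very
  sparse strata the realized balance degrades gracefully but is only
  logged, not enforced.
* The `pcor` network backend trades statistical efficiency for speed; its
  threshold is a tuning constant that should scale with subsample size.
* Consensus direction labels for weak, non-significant responses are
  essentially noise; read them only alongside `mean_adjusted_p` and
  `n_significant`.
* Alpha diversity is computed at the ASV level by default (configurable);
  no rarefaction is applied anywhere, by design.
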