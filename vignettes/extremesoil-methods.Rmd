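---
title: "Methods: models, simulators and design choices in extremesoil"
author: "extremesoil authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models the package implements,
what the synthetic-data generators do and do not emulate, the numerical
choices that affect results, and the design decisions taken where more
than one defensible option existed.  It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# The experimental design

The design object encodes a factorial microcosm experiment: countries
(10 by default), replicate sites nested in country (3), disturbance
treatments (control 18 °C/60% WHC, drought 18/10, flood 18/100, freeze
−20/60, heat 35/60; moisture is percent of water-holding capacity) and
sampling occasions S1–S4 at 0, 1, 8 and 26 days after the end of the
disturbance.  One microcosm exists per cell (600 at the default shape)
plus one pre-experiment "initial" sample per site.

Sample identifiers are deterministic concatenations
(`country_site_treatment_sampling`), so repeated builds are bit-identical
and all tables join reproducibly.

**Exclusions** are declarative rules rather than hard-coded filters.  The
shipped defaults remove ten Russian microcosms at S2 (all assays) and two
Spanish replicate sites for sequencing assays.  Two judgement calls are
worth recording:

* The ten affected Russian pots are not individually identified in the
  study description, so the rule removes two whole replicate sites at S2
  (2 sites × 5 treatments = 10 records).  This keeps the rule declarative
  and idempotent; any other choice of ten records is equally consistent
  with the available information and can be configured.
* The Spanish rule is marked `stage = "analysis"`: the samples were
  sequenced (so the *sequenced* amplicon count is 30 initial + 590
  microcosms = 620) but are dropped from analyses.  The published
  retained counts differ slightly between sources (574 vs 576, because
  two further individual samples are excluded but not named); the
  package takes no position — the exclusion list is user-extensible and
  neither number is asserted anywhere.

**Split spaces.**  Site-level grouped cross-validation holds out one site
per country; countries with fewer than three retained sites contribute
their remaining sites to every training set and never appear in test sets
(with the default sequencing exclusions Spain retains one site, leaving
nine complete countries and 3⁹ = 19,683 splits).  Country-level splits
are all subsets of a given size with their complements (C(10,6) = 210).

# Synthetic data

The generators exist so that every downstream method can be tested
against known truth.  They are first-class, tested code, and every
planted quantity is returned in a ground-truth ledger; downstream
recovery tests read truth only from that ledger.

**Taxon counts.**  Baseline proportions are lognormal; country and site
effects are multiplicative lognormal intercepts per taxon.  A planted
response strategy is an (impact, slope) pair per taxon × treatment:
the *realised* expected proportion of a targeted taxon in a disturbed
sample is its control composition plus `impact + slope · day`, with the
remaining taxa rescaled so compositions sum to one.  Planting on the
realised proportion scale (rather than adding before renormalisation)
makes the planted displacement directly comparable to the fitted
treatment coefficient, which is the package's response variable.
Counts are drawn by gamma-perturbing the composition (dispersion
parameter `overdispersion`; the limit 0 is multinomial sampling) and
drawing a multinomial of the drawn lognormal library size — a
negative-binomial count scheme conditioned on its total, so each sample's
counts sum exactly to its library size.  Requested library sizes below 1
are an error, not a silent clip.

Desk-scale defaults (200 taxa, ~10k reads/sample, country/site intercept
SDs 0.30/0.15, dispersion 0.002) were chosen once for testability — the
study the design emulates does not report per-taxon effect magnitudes —
and the recovery suites run at the sizes stated below.

**Phylogeny and effects.**  A random coalescent tree; planted effects are
the mixture `σ(√λ·b + √(1−λ)·z)` of a Brownian realisation `b` (unit tip
variance) and white noise `z`, so λ = 1 gives pure Brownian structure and
λ = 0 none.

**Functional profiles.**  A nested 4-level hierarchy (protein → level3 →
level2 → level1; 50 proteins by default, deterministic round-robin
membership).  Compositions are Dirichlet-multinomial around site-specific
bases; a planted shift adds a signed displacement to one category in one
treatment (distributed over the category's proteins proportionally to
their baselines), optionally decaying linearly to zero by the final
sampling to emulate resilience.  Metagenome samples exist at S1 and S4
only, matching the design's sequencing plan (280 samples at full scale).

**Covariates and responses.**  Twenty site-level properties in the
canonical families (4 temperature, 4 precipitation, 8 carbon/nitrogen,
3 water-holding, pH) are generated from two latent country axes (climate,
fertility) plus site noise, which produces realistic within-family
correlation.  True resistance per (site, treatment) is a stated linear
function of standardized properties with one product interaction — by
default heat resistance rises with the mean-annual-temperature analogue
(with a temperature × moisture interaction), drought with temperature and
dryness, flood with moisture, freeze falls with temperature — plus
Gaussian noise on the emitted responses.

**Marker reads.**  A toy circular genome (20 kb default) carries a
replication-initiator open reading frame at the origin and a 28-bp
dimer-resolution site at the antipodal terminus.  Read start positions
follow the symmetric two-replichore steady-state law, coverage ∝
2^(ρ(1−2d)) with d the normalised circular distance from the origin, so ρ
is the log2 peak-to-trough (origin:terminus) ratio.  Reads wrap the
circle, land on either strand, and receive independent substitution
errors (0.5% default).

What the generators do *not* emulate: taxonomic assignment and raw
amplicon read processing, chimeras, compositional correlations between
taxa beyond the shared renormalisation, genome collections with multiple
replicons or skewed termini, and real covariate distributions.  Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated generative assumptions, not performance on any real dataset.

# Community statistics

Hellinger transform, single-draw rarefaction (the analysis a rarefied
table feeds is a single draw, with the seed recorded in the output, not
an average over draws), Bray–Curtis, PERMANOVA and Mantel are implemented
directly; `vegan` serves as an independent cross-check in the tests, not
as the implementation.

Numerical and procedural choices:

* PERMANOVA uses sequential (Type-I) sums of squares on the Gower-centred
  inner-product matrix; terms enter in column order.  Whether the
  original analyses used sequential or marginal partitioning is not
  documented; sequential is the default and the term order is the
  caller's.  Permutations shuffle raw sample labels freely; a `strata`
  argument restricts them within groups when wanted.  p-values use the
  add-one convention `(1 + #{F* ≥ F})/(1 + n_perm)`, so the smallest
  attainable p is 1/(1+n_perm).
* The Mantel statistic is the Spearman correlation of lower triangles;
  the permutation core exploits the fact that a simultaneous row/column
  permutation permutes the triangle as a multiset, so ranks are computed
  once.  Two-tailed by default.
* Resistance/resilience scores require a unique same-site, same-sampling
  control; missing pairs are skipped with a warning.  The `−log(BC + ε)`
  variant uses ε = 1e−6 to keep a perfect-overlap pair (BC = 0) finite;
  the choice only affects that boundary case.
* A pair of all-zero profiles has undefined Bray–Curtis dissimilarity:
  an error in strict mode (default), NaN in permissive mode.

# Per-taxon models and strategies

The response is relative abundance against the *un-rarefied* library
size (rarefaction is reserved for beta-diversity; subsampling a count
that then divides its own depth would only add noise).  The REML fit uses
`nlme` with random intercepts for country and site-in-country and a
residual variance structure combining a constant-plus-proportional term
in 1/√depth (sampling noise scales with inverse root depth) with a
per-sampling-occasion multiplier.  Wald p-values are reported uncorrected
at α = 0.05 — the convention for this screening step — and a flag enables
BH adjustment for users who want it.

The strategy grid maps the 3 × 3 sign/significance outcomes onto eight
responsive classes ({positive, negative} × {stable, resilient,
diverging}, plus late_positive/late_negative when only the slope is
significant), full resistance when nothing is significant, and a separate
model-failure label for non-converged fits.  The mapping is total and
exhaustive (property-tested).  The taxonomy is a plain table, deliberately
pluggable: published descriptions of "ten" strategies cannot be
unambiguously reduced to a sign/significance grid, and the package does
not guess the two classes the grid does not produce.

# Phylogenetic signal

The PGLS likelihood uses V(λ) with off-diagonal shared path lengths
scaled by λ and tip depths kept on the diagonal; the mean structure is
intercept-only (whether any further predictors were used upstream is not
documented; intercept-only is the conservative reading).  σ² and the mean
are profiled analytically; λ is located by a 21-point grid pre-scan —
the profile can be multimodal on small trees — followed by bounded
refinement, with explicit boundary checks at 0 and 1.  The confidence
interval is profile-likelihood based (χ²₁ cutoff), clipped to [0, 1]; a
flat profile (star phylogeny) correctly yields [0, 1].  Non-converged
taxa are excluded listwise before signal estimation.

# Functional models

One mixed model per category: arcsine-square-root proportions of each
protein under the category, fixed effects `treatment * day`, random
intercepts for site-in-country and for the nested sub-hierarchy below
the category (collapsing gracefully when a category has a single
protein).  Per-country heteroscedasticity is approximated by one
re-weighting pass (per-country residual variance → weights), because
exact Gaussian observation-level random effects per country are not
identifiable as variance components alongside a free residual variance.
Degrees of freedom for Wald tests use the residual-count approximation.

Dunnett-style control contrasts are adjusted by seeded Monte-Carlo on
the estimated joint t distribution (2×10⁵ draws by default; the
adjusted p is floored at the Monte-Carlo resolution and never reported
below the raw p).  FDR (Benjamini–Hochberg, via `stats::p.adjust`) is
applied across the categories *within* a hierarchy level — the family is
"multiple models at this level" — not across levels.

# Growth metrics

The origin search is a translated seed-and-extend: a read hits when any
of its six reading frames shares an exact 12-residue seed with a marker
peptide and the ungapped BLOSUM62 extension of that seed reaches 40.
The terminus search accepts any 28-bp window within 4 mismatches of a
marker motif on either strand.  These thresholds emulate, at toy scale,
the e-value cutoffs a translated aligner would apply at full scale; both
are configurable, and both scanners are validated against brute-force
all-offset oracles in the tests.  Reads are counted at most once per
mode ("reads with ≥1 qualifying match").

The relative growth statistic applies a symmetric pseudocount of 0.5 to
all four counts — zero terminus hits do occur in small simulations — and
is exactly zero when treatment and control ratios agree.

The growth mixed model starts from all interactions of treatment,
sampling day and the bacterial/fungal community displacements, with
site-in-country intercepts and treatment-specific residual variances,
and is reduced by backward elimination respecting marginality.  The
elimination criterion is BIC by default: with AIC, a null three-degree-
of-freedom interaction survives often enough that the marginality
cascade retains nuisance terms in a large fraction of null replicates,
whereas BIC's log(n) penalty prunes them consistently while retaining
strong planted effects.  `criterion = "AIC"` restores the classical
behaviour.  The minimal model is refitted by REML.

# Prediction

Properties are z-scored with the sample (n−1) standard deviation over
the full table — matching the usual practice of standardizing once
before cross-validation; this mildly leaks scale information across
splits, and a `within` mask enables train-only standardization for users
who prefer it.  The regressor is a contract (`fit(X, y)` /
`predict(model, X)`).  Two backends ship:

* `rangerRegressor()` — a random regression forest (500 trees, mtry =
  ⌊p/3⌋, bootstrap rows), the analysis default.
* `linearRegressor()` — ordinary least squares, optionally with a
  user-stated formula.  Its role is diagnostic: a forest is piecewise
  constant and cannot extrapolate a linear surface to held-out sites, so
  even a noiseless linear response leaves it far from R² = 1.  The
  machinery-recovery checks therefore plant a linear response and
  cross-validate a linear learner whose model class contains it: any
  shortfall from R² = 1 would then indict the splitting or scoring
  logic, not learner capacity.

Fitting all 19,683 site-level splits is possible but not the default;
a seeded subsample (`split_budget`, default 200) is drawn when the split
space exceeds the budget, and the number used is reported.  Test R² is
1 − SS_res/SS_tot with SS_tot around the test-set mean, so negative
values indicate predictions worse than that mean.  The property-response
map uses Spearman correlations with average ranks on ties, rows ordered
by complete-linkage clustering of the correlation profiles; fully tied
cells are flagged rather than given a value.

# Pipeline

`runPipeline()` derives every stage seed deterministically from the
global seed and the stage name, writes all outputs as TSV/Newick/JSON
under the output directory, and records seeds and outputs in a manifest;
identical configurations give byte-identical outputs.  The thin CLI
wrapper (`inst/scripts/extremesoil.R`) exposes the stages as
subcommands.

# Problem sizes used by the tests

The statistical suites run at reduced, stated sizes chosen for
single-CPU execution: permutation-test calibration uses 500 null
datasets of 20 samples × 5 features with 199 permutations; per-taxon
recovery uses 100 replicate simulations of the full 600-microcosm design
with 50 taxa and a planted displacement of 0.05; λ recovery uses 100
trees of 100 tips per regime; growth recovery uses 8 treatment/control
pairs of 20,000 simulated 150-bp reads from a 20-kb genome (planted
log2 peak-to-trough difference of 1); grouped cross-validation checks
use 100–120 sampled splits of the full design.  The acceptance script
recomputes the same quantities at similar sizes.

# Known limitations

* The per-taxon and functional models are Gaussian on (transformed)
  proportions, as in the analysis they implement; they are not count
  models, and very sparse taxa will simply fail to converge and be
  flagged rather than rescued.
* The Dunnett adjustment conditions on the estimated contrast
  covariance; uncertainty in the variance parameters themselves is not
  propagated.
* Pagel's λ is estimated with an intercept-only mean; trends correlated
  with tree depth would bias it.
* The origin/terminus scanners are exact-seed based; marker variants
  more than (k−1) residues diverged from every database entry within any
  window cannot seed a hit, which at full scale is the role of a
  sensitive translated aligner.
* The generators share no taxa across the taxon and functional tables;
  cross-table analyses on synthetic data treat them as independent.
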