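---
title: "Diversity accounting for fish mucosal microbiomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity accounting for fish mucosal microbiomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucodiv)
```

`mucodiv` quantifies how much microbial diversity is associated with a wild
marine fish relative to its environment, and which environmental and
biometric variables drive it. This vignette is the package's own account of
the statistical machinery: the models, the assumptions they lean on, the
parameters worth knowing about, what the synthetic-data generator does and
does not emulate, and the places where the design was genuinely open and a
choice had to be made.

## Limit-of-detection gating and rarefaction

Low-biomass samples (a swab of gill mucus carries far less DNA than a
sediment grab) can produce read-outs dominated by reagent contamination.
The package derives a minimal trustworthy read count from dilution series
of extraction-positive controls: for each control, the total reads and the
fraction of reads assigned to the expected control taxa. That fraction
rises with depth along a saturating curve, modeled here as a four-parameter
Hill sigmoid on the log10-read axis:

$$ f(x) = f_0 + \frac{f_1 - f_0}{1 + (m/x)^h}, \qquad x = \log_{10}(\text{reads}) $$

with floor $f_0$, ceiling $f_1$, midpoint $m$ (log10 reads) and slope
$h > 0$. The cited limit-of-detection methodology does not pin down a
single functional form; the Hill family has the right shape, four
interpretable parameters, and a closed-form inverse, which keeps the
exclusion threshold testable against brute-force integer scans. The fit is
least squares via Levenberg–Marquardt (`minpack.lm::nls.lm`), chosen
because it converges cleanly even on noise-free points where `nls`'s
singular-gradient guard trips. If the fit fails or the points are
degenerate (no spread), the curve falls back to monotone linear
interpolation of the empirical points and says so.

The exclusion threshold is the smallest **integer** read count where the
fitted curve reaches the target fraction (default 0.9); rounding is always
upward so the guarantee is conservative. A target equal to the fitted
ceiling is refused for a smooth sigmoid (the crossing lies beyond any
representable depth) but resolves to the smallest attaining depth on an
empirically saturated curve.

Rarefaction is subsampling **without replacement** — the amplicon-literature
meaning of the word — so each retained sample's counts are jointly
multivariate hypergeometric and sum exactly to the depth. Samples below
depth are dropped and reported, never padded. The draw is seeded and the
caller's RNG stream is restored afterwards. We rarefy once with a recorded
seed rather than averaging repeated rarefactions; the accumulation and
saturation functions expose permutation averaging where that is the
scientifically relevant smoothing.

## Alpha and beta diversity

Shannon diversity is reported in bits (log base 2, the dominant convention
in amplicon toolchains; the base is an argument). Faith's phylogenetic
diversity is the total branch length of the union of root-to-leaf paths of
the present features, **root-inclusive** — the branch connecting the
present subtree to the root counts. Presence means at least one read in
the rarefied table.

Unweighted UniFrac is the fraction of that path-union branch length unique
to exactly one of two communities; weighted UniFrac sums branch length
times the absolute difference of the fractions of each community's reads
descending through the branch, with an optional normalization to [0, 1].
The **raw** weighted form is the default; whether a given study normalized
is often unstated, so both forms are first-class and a run's choice is
recorded in its configuration.

The implementation computes per-branch descendant abundances by a single
postorder accumulation per sample, then combines samples pairwise (for
unweighted UniFrac the pairwise step is one branch-length-weighted inner
product, so full distance matrices are a single matrix multiplication).
Correctness is established two independent ways: per-branch brute-force
enumeration oracles (exact agreement at 1e-12 on hundreds of random trees)
and the `phyloseq` / `picante` implementations (1e-10 on random tables).

When a table and tree disagree, `align_table_tree()` drops table features
missing from the tree (with a count — features that failed phylogenetic
placement are discarded, not imputed) and prunes tree leaves missing from
the table. Pruning collapses unary nodes by summing their branch lengths,
and basal edges removed above the new root are accumulated into the stem
(`root.edge`), so **no retained leaf changes its root-to-leaf path
length**. The stem is counted by Faith's PD and treated as shared by both
communities in UniFrac.

## Diversity accounting

All accounting statistics operate on the rarefied table, so presence sets
are depth-comparable; the host-versus-seawater comparison is meaningless
otherwise.

- **Gamma richness**: distinct features across a sample selection.
- **Accumulation / saturation**: cumulative richness as samples are added,
  either in chronological order or averaged over seeded random orderings;
  the saturation n is the smallest step reaching a fraction (default 0.9)
  of pooled richness, computed per ordering then averaged. Both the
  per-sample and per-event granularities are available to the caller via
  the ordering argument; neither is privileged.
- **Host:seawater ratio**: richness of the union of one fish's gill, skin
  and digesta sets over the paired seawater sample's richness. These three
  outward-facing sites form the default union; the gastrointestinal sites
  are excluded by default but the set is configurable. When an event holds
  several fish the one with the lowest sample id among complete-site fish
  is selected — an arbitrary but deterministic rule, chosen because the
  original selection rule for multi-fish events is not documented
  anywhere we could follow.
- **Uniqueness partition**: per environment (fish union, seawater,
  sediment), the fraction of its features found in no other environment,
  computed per event and then averaged. Event-wise averaging (rather than
  pooling all events first) is the reading most consistent with "average
  contribution" phrasing; the per-event table is returned so the pooled
  variant is one `tapply` away.
- **Core microbiome**: features present in at least a fraction (default
  0.30, inclusive) of a sample type's samples. Each member is reported
  with its median relative abundance across **all** samples of the type,
  zeros included — a deliberately conservative convention (the alternative,
  median over positive samples only, inflates rare members); it is stated
  here prominently because the two conventions differ a lot at 30%
  prevalence.
- **Group prevalence**: a user-supplied feature set (e.g. all sOTUs of a
  pathogen) is summed per sample before prevalence and median relative
  abundance are computed.
- **Relative abundance** is reads over rarefaction depth; an exact zero
  stays zero in data exports and is replaced by a display floor (default
  1e-5) only in log-scale plot exports, so detection limits remain visible
  without corrupting the data files.

## Driver analysis

Per body site and alpha metric, an OLS model with intercept on eight
covariates — age (yr), fork length (mm), mass (kg), condition factor,
chlorophyll a (µg/l), pressure (dbar), salinity (PSU), temperature (°C) —
is admitted only if the full-model residuals pass Shapiro–Wilk normality
and the fit passes the classical (non-studentized) Breusch–Pagan score
test against fitted values, both at p > 0.05. The score-test variant
matches `car::ncvTest` (the test suite asserts equality); it is computed
directly in the package because `lmtest::bptest`'s formula re-evaluation
misbehaves inside package frames. Faith's PD is typically right-skewed and
is log-transformed before gating. Samples missing any covariate (e.g. an
instrument failure leaving chlorophyll unrecorded) are dropped as complete
cases and reported — missing is NA, never zero. Collinearity among the
biometric covariates (age is derived from length; mass correlates with
both) is intrinsic to the design; it is **reported** through variance
inflation factors with a warning above 10, not silently corrected, since
coefficient signs on the original scales are the quantity of interest.

PERMANOVA partitions a distance matrix's variation by covariates: from the
Gower-centered inner-product matrix $G = J(-\tfrac12 D^{(2)})J$, sequential
(Type I) sums of squares are obtained by projecting onto the growing
design, $SS_j = \mathrm{tr}(H_jG) - \mathrm{tr}(H_{j-1}G)$, giving a
pseudo-F per term; significance comes from free permutation of design rows,
$p = (1 + \#\{F^\ast \ge F\})/(1 + n_\text{perm})$, seeded. Sequential SS
makes covariate order part of the analysis; the order is therefore part of
the configuration and recorded in output. No permutation strata are used.
Default 999 permutations — the conventional choice when the count is not
otherwise documented. Two identities anchor the implementation: exact
agreement with `vegan::adonis2` (by = "terms") and collapse to classical
one-way ANOVA F on Euclidean distances of a univariate response.

Exposure gradients are tested nonparametrically: all pairwise distances
from each mucosal site to a reference (seawater, sediment) are pooled per
site and compared across sites with Kruskal–Wallis.

## Biometrics

Age is inverted from fork length through the von Bertalanffy growth
function $L(A) = L_\infty(1 - e^{-k(A - t_0)})$. Stock assessments
sometimes publish **two growth coefficients** (juvenile and adult); the
parameter object supports an optional second regime with the switch age,
kept continuous at the split by solving for the second regime's $t_0$. No
default parameter values ship: growth parameters are population-specific
and must come from the relevant stock assessment. Fulton's condition
factor uses the standard $K = 100\,m[\mathrm{g}]/L[\mathrm{cm}]^3$
convention, with the constant and units explicit, plus a plausibility
warning above K = 5 (almost always a unit mix-up).

## The synthetic-study generator

`generate_study()` emulates the *design* of a year-long pier survey: 38
chronological sampling events, five fish per event sampled at gill, skin,
digesta, GI and pyloric ceca, one paired seawater and one paired sediment
sample per event, seasonal covariates (sinusoidal temperature peaking in
late summer, lognormal chlorophyll a with spring spikes, stationary
salinity and pressure), fish biometrics drawn through the growth model,
and an eight-point titration series.

Its central design idea is **planting at the presence-set level**. Feature
pools are split into environment-exclusive and pairwise-shared blocks;
each sample's feature set is constructed from them, and every planted
feature receives at least one read, so presence is deterministic even
though counts are random. Set-based statistics (gamma, uniqueness, ratios,
core membership, group prevalence) therefore have exact, noise-free ground
truth, while count-based statistics (Shannon, UniFrac, GLM coefficients)
have stochastic ground truth — that separation is what makes the recovery
tests decisive. Concretely:

- the selected fish's gill+skin+digesta union in ten designated events is
  sized to an exact ratio preset (mean 3.2, range 1.7–5.2) against a
  100-feature seawater set;
- gill and skin share a per-event draw from the fish–water pool with the
  seawater sample, digesta shares with sediment — the exposure gradient;
- per-type core blocks are included in every sample of their type;
- one bloom feature is present in skin/digesta/GI in summer-month events at
  3% relative abundance, emulating a seasonal pathogen;
- counts are Dirichlet-multinomial (symmetric concentration 0.3, matching
  amplicon-like overdispersion) on top of the one-read floor, at a uniform
  depth of 5000 reads per sample, so the generated study is
  depth-comparable by construction and rarefaction at that depth is the
  identity;
- skin Shannon diversity carries a planted linear covariate effect
  (temperature +0.12 bits/°C, chlorophyll a −0.25 bits per µg/l, residual
  sd 0.25 bits): a per-sample target entropy is realized by solving a
  geometric abundance series for the ratio whose entropy matches, then
  allocating reads by largest remainder. The one-read floor adds a small
  near-constant entropy offset (slope of realized on target ≈ 0.98), which
  lands in the intercept and leaves slope recovery intact.

What the generator does **not** emulate: taxonomy (features are abstract
ids), sequence-level error or chimeras, uneven sequencing depth, reagent
contamination structure in real controls, spatial heterogeneity within a
body site, or fish-to-fish covariance beyond shared event covariates.
Passing recovery tests on these data therefore demonstrates correctness of
the accounting machinery, not robustness to every failure mode of real
amplicon data — most notably, the exact-recovery results depend on the
uniform-depth construction, and real studies should expect rarefaction to
perturb presence sets.

## Numerical choices and problem sizes

- UniFrac/PD oracle equivalence is exact to 1e-12; cross-package agreement
  to 1e-10 (tree serialization rounds branch lengths at 12 significant
  digits, which bounds disk round-trip agreement).
- The PERMANOVA permutation loop evaluates each permuted pseudo-F from the
  precomputed hat matrices and the permuted Gower matrix; null calibration
  in the tests uses n = 30 samples, 999 permutations, 500 replicates
  (type-I error within [0.03, 0.07] at α = 0.05).
- The titration recovery check uses binomial noise with 200 assessed reads
  per control and 20 replicate fits; the recovered threshold is summarized
  by the replicate median, whose error against the analytic crossing is
  typically 1–8%. A single 8-point replicate at that noise level has ~25%
  one-sigma scatter, so no per-replicate guarantee is made.
- GLM recovery simulations run at n = 150 with planted slopes
  (temperature +0.5, chlorophyll −0.8, σ = 1) on covariates taken from a
  generated study, so the collinearity structure is realistic.
- Default study size (1026 samples × 1411 features) generates in about a
  second; the full test suite runs in about a minute.

## Known limitations

- Rarefaction to depths far below the generator's uniform depth will break
  the exact-recovery properties by construction (presence becomes
  stochastic); this is a property of rarefaction, not of the estimators.
- The Hill-sigmoid family is an assumption; titration curves with
  non-monotone artifacts will trigger the interpolation fallback, whose
  threshold is only as good as the empirical grid.
- The GLM is a single full additive model per site/metric — no
  interactions, model selection or mixed effects; event-level covariates
  shared by the fish of an event are treated as independent observations,
  as in the emulated workflow.
- PERMANOVA uses free permutation; designs needing restricted permutation
  (repeated measures, strata) are out of scope.
- `uniqueness_by_event()` and `host_env_ratio_events()` evaluate one fish
  per event by a deterministic selection rule; other selection rules can
  shift the averages by a few points.
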