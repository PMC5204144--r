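---
title: "Methods: demographic traits and phylogenetic signal from forest censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic traits and phylogenetic signal from forest censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodem)
```

phylodem turns repeated forest-census records into genus-level life-history
traits and asks how strongly those traits track the phylogeny. This vignette
is the package's account of the models it fits, the parameters that matter,
the numerical choices made where a choice was genuinely open, and what the
synthetic-data tests do and do not establish about real inventory data.

## The data model and selection filters

The pipeline consumes four inputs: a stem-level census table (one row per
stem per census, with diameter at the point of measurement, POM height,
alive flag, tape-measure flag, and an optional second reading when the POM
moved), a plot table (coordinates, elevation, annual precipitation, a
dimensionless environmental-stress covariate E, and area), a species-level
wood-density table, and a rooted genus-level phylogeny with branch lengths.
Dates are handled as decimal years so census intervals are plain
differences; the neglected leap-year effect is orders of magnitude below
diameter measurement noise.

Plot selection keeps lowland moist forest: annual precipitation at least
1300 mm yr⁻¹ and elevation below 500 m. Plots whose census record spans
less than 2 years stay in the dataset for size and wood-density traits but
are excluded from growth and mortality estimation, which need repeated
measurements. Stems not identified to genus are dropped. Every exclusion is
written to a log with a reason code, and the kept set plus the log
reconstruct the input exactly — a property the tests assert. The
precipitation bound is applied inclusively (`>= 1300`); all filter bounds
are configurable in `run_config()` and recorded in the run manifest.

## From censuses to stem summaries

When a stem's POM moves at a census, the record carries readings at both
heights and the effective diameter at that census is their arithmetic mean,
so growth across the change is not confounded with the change in
measurement height. Per census interval, the annualised growth rate is the
difference in effective diameter divided by the interval length; the same
differencing is done on basal area, π(D/200)², and on above-ground biomass.
Biomass uses the pan-tropical diameter–wood-density–E equation

  ln AGB = −1.803 − 0.976 E + 0.976 ln ρ + 2.673 ln D − 0.0299 (ln D)²

for trees and a diameter-only power law, ln AGB = −3.3488 + 2.7483 ln D,
for palms. Both sets of coefficients live in `allometry_params()` rather
than in code, carry provenance strings, and can be replaced wholesale; only
D varies within a stem, so biomass growth isolates diameter growth on the
biomass scale. The (ln D)² term makes the tree equation non-monotone at
diameters far beyond anything a census contains; no clamping is applied.
Wood density is matched species-first with a genus-mean fallback, and the
source of each match is flagged.

Stems leave the growth estimation (but not the size or wood-density
estimation) when (i) their mean diameter growth is negative, (ii) any
single interval exceeds 8 cm yr⁻¹ (recording error), (iii) they are palms,
which lack secondary growth, or (iv) any diameter in the series was not
tape-measured. The negative-growth rule uses the stem mean while the
8 cm yr⁻¹ rule applies to single intervals — the two filters are aimed at
different error processes.

## Genus trait estimates

Potential size is the 95th percentile of the per-stem maximum size within a
genus, on each of the three scales, for genera with at least 20 stems.
Quantiles use linear interpolation with h = (n − 1)p + 1 (the default in
most scientific software); the choice matters only in the last decimal of
small genera and is fixed package-wide. Mean growth averages stem-level mean
rates; maximum growth is the 95th percentile of stem-level maximum rates;
both apply the same 20-stem threshold after the exclusions above. Two
composite traits multiply the genus potential size (diameter and basal
area) by genus mean wood density.

Mortality assumes exponential survival over each stem's monitoring span t
(first to last census; recruits enter at their first record): a stem
survives with probability exp(−m t), with log-hazard
ln mᵢ = α_g + β zᵢ, where zᵢ is the standardized log initial diameter and β
is shared across genera. This Bernoulli likelihood is exactly a binomial
GLM with complementary-log-log link and offset ln t, and is fitted with
`stats::glm`; the equal-time, no-covariate case collapses to the closed
form −ln(s̄)/t, which the tests verify to 10⁻⁸. Genera need 100 stems; a
genus with no observed deaths sits on the likelihood boundary and is
reported as 0 % yr⁻¹ with a boundary flag rather than entering the joint
fit with a divergent intercept. The reported rate is 100 × the mean fitted
per-stem hazard. Whether a plot random effect belongs in this model was an
open design question; it is omitted here (the plot term is handled by the
separate adjustment below) and the choice is recorded in the output
metadata.

Because plots differ systematically, genus values confound taxon identity
with location. The optional adjustment fits
log(value) ~ 0 + genus + (1 | plot) by maximum likelihood with lme4 and
reports genus effects at the average plot; for percentile traits the plot
intercepts are subtracted from log stem values *before* the genus quantile
is taken. A single plot, or a singular fit, degrades to unadjusted values
with a warning. Adjusted and unadjusted values are both kept, and
`adjustment_concordance()` reports their Kendall τ. Back-transforming genus
effects from the log scale yields geometric-mean-type values; with
log-scale stem noise of sd σ they sit a factor exp(σ²/2) below arithmetic
means, which cancels in rank-based comparisons and is irrelevant to signal
estimates, which are location/scale invariant.

Intrageneric standard errors come from species-level trait values computed
with the same estimators (species need 5 stems for size/growth values, 20
for mortality — genus thresholds would leave almost no genus with two
species-level estimates): the genus SE is sd/√k over its k ≥ 2 species
values, and genera with k < 2 receive the mean of the computable SEs. The
imputation is flagged per genus.

## Phylogenetic signal

The phylogenetic covariance C has entries C[i,j] equal to the shared
root-to-tip path length of tips i and j. Blomberg's K compares the ratio of
the ordinary trait variance around the GLS (phylogenetic) mean to the
C-weighted variance against the value of that ratio expected under Brownian
motion on the same tree:

  K = [MSE₀ / MSE] ÷ [(tr C − n/(1ᵀC⁻¹1)) / (n − 1)].

K is 1 in expectation under Brownian motion, exactly 1 on an equal-depth
star phylogeny for any non-constant trait (an identity the tests assert to
10⁻¹⁰), and falls toward 0 as trait values decouple from the tree. K is
invariant to affine transforms of the trait, so the lognormal links used by
the generator, or unit changes, do not move it.

Measurement error — here, intrageneric variation — dilutes K. The
error-aware variant estimates the Brownian rate σ² by maximum likelihood
under covariance σ²C + diag(se²) and computes K on the working covariance
C + diag(se²)/σ̂², discounting poorly estimated tips. σ² is estimated by
full ML rather than REML, for determinism and simplicity; the σ̂² → 0
boundary (signal indistinguishable from noise) is an error, not a silent
zero. Simulations in the test suite confirm the correction pulls K back
toward 1 when Brownian traits are observed with known noise.

Significance uses tip randomization: trait values (jointly with their
standard errors — the pair belongs to the genus) are shuffled across tips
1000 times by default, and the observed K is significant when it falls
outside the 2.5–97.5 percentile band of the permuted values. This is
two-sided by construction; no multiple-testing correction is applied across
traits. Each result records its seed, and the type-I rate of the whole
procedure is checked by simulation (500 null datasets) to sit at 5 % ± 2 %.

Pagel's λ multiplies the off-diagonal of C and is estimated by ML over
[0, λ_max], where λ_max is the largest value keeping C(λ) positive
definite, found by bisection on a Cholesky test (it is computed per tree —
slightly above 1 for ultrametric trees — never assumed to be 1). The
optimizer is a bounded scalar search with tolerance 10⁻⁶; because such a
search does not evaluate the interval ends, both boundaries are checked
explicitly before reporting. A likelihood-ratio test against λ = 0
accompanies the estimate, alongside the permutation machinery available for
K, since either significance convention may be wanted.

## Phylogenetic PCA

Traits are standardized to ordinary mean 0, variance 1 (sample sd), so each
contributes equally; the phylogenetic structure enters afterwards through
the GLS mean and the evolutionary covariance
S = (Z − 1a)ᵀ C⁻¹ (Z − 1a)/(n − 1), whose eigenvectors are the axes and
whose eigenvalue shares are the variance proportions. Using the ordinary
mean for standardization and the phylogenetic mean inside the PCA follows
the source convention for this analysis; both steps are explicit in the
code. Scores are the centred data projected on the loadings. Loadings are
unit-norm with each column's largest-magnitude element made positive, a
deterministic sign convention across platforms. With C = I (equal-depth
star tree) the whole construction reduces to ordinary PCA, element-wise to
10⁻¹⁰ in the tests. The default trait set for the PPCA is wood density,
potential diameter, maximum diameter growth and mortality, over
complete-trait taxa only; PPCA axes are treated as derived traits without
intrageneric SEs, so their signal estimates use the plain K.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth.
Its defaults describe a desk-scale analogue of a lowland Amazonian plot
network: ~1-ha plots censused three times over a decade (baseline dates
2000/2005/2010, jittered per plot by up to ±0.5 yr so intervals are
irregular), stems entering at the 10 cm diameter floor with truncated
lognormal initial sizes (median 15 cm), mean diameter growth 0.25 cm yr⁻¹
with 0.15 cm yr⁻¹ stem-level scatter, hazards near 2 % yr⁻¹ with a size
slope of −0.2 on standardized log diameter, wood density 0.60 ± 0.12 g cm⁻³
across genera with 0.05 within, 0.1 cm diameter measurement noise, a 2 %
per-census POM-change probability, a 5 % palm fraction, and a 0.1 %
non-tape fraction. Genus-level trait values evolve on a pure-birth
phylogeny (Brownian by default; λ-rescaled and tip-shuffled models are
available) and map onto positive rates through a mean-preserving lognormal
link. Plot effects are log-scale offsets (sd 0.2) applied multiplicatively
to growth, consistent with the log-scale adjustment model. Truth tables
carry every generating value, and recovery tests compare against generated
truth, never against hard-coded numbers.

What passing tests show — and do not. The generator draws growth noise and
measurement error as Gaussians, hazards as exactly exponential, and plots
as exchangeable random offsets. Real inventory data have heavier-tailed
measurement error, size- and time-varying growth, spatially structured
environments, and taxonomic error, none of which are emulated. Recovery and
calibration results therefore validate the estimators under their assumed
model, not the assumptions themselves.

## Problem sizes and numerical settings

The test suite runs the calibration experiments at the sizes reported here:
500 Brownian replicates on a 200-tip pure-birth tree for the K calibration
(mean K within ±0.05 of 1); 500 null datasets with 1000 permutations each
on a 64-tip tree for the type-I rate; 100 replicates per λ ∈ {0, 0.5, 1} on
300-tip trees (mean λ̂ within ±0.1); 5000 stems for mortality recovery; and
a 100-genus, 10-plot, 3-census end-to-end run. These sizes were chosen so
the Monte-Carlo error of each check is several times smaller than the
tolerance it asserts. Matrix work goes through Cholesky factorizations
throughout; singular covariances, constant traits, zero-length intervals
and all-excluded datasets raise errors rather than propagating NaNs.

## Known limitations

Genus means treat congeneric species as exchangeable; the intrageneric SE
captures their spread but not species-level covariance with the
environment. The mortality model has no plot term and assumes a
time-constant hazard over each stem's monitoring span. The spatial subset
mode selects plots by great-circle distance only. Trees with basal
polytypic roots are accepted as rooted (a star phylogeny is a legitimate
input); genuinely unrooted binary trees cannot be distinguished from rooted
ones in Newick and are the user's responsibility. None of the numerical
results in this vignette or the README are asserted anywhere except where
the tests or the acceptance script compute them at run time.
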