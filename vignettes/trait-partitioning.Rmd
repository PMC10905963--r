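---
title: "Partitioning CWM trait variation along water gradients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning CWM trait variation along water gradients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpart)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## From survey records to community-weighted means

A vegetation survey records, per (plot, subplot, species): the number of
individuals, the mean height (cm), and crown dimensions. Crown length
`L` and width `W` are converted to a projected per-individual area by the
ellipse convention, `π·(L/2)·(W/2)`, and summed over individuals; this is
the standard field approximation for canopy coverage and the only
geometry the package supports (no allometric modelling).

Within a subplot, each species' relative abundance `Ar`, relative height
`Hr` and relative coverage `Cr` are its shares of the subplot totals, and
its importance value is their mean, `IV = (Ar + Hr + Cr)/3`, so all four
columns sum to one per subplot. Subplots with a single species are
excluded — a community-weighted quantity is not defined there — and
subplots with zero total abundance, height or coverage are rejected with
a diagnostic rather than silently propagating `0/0`.

Community-weighted means come in two flavours:

* `CWM_specific = Σ IVⱼ · traitⱼ` with subplot-specific trait values;
* `CWM_fixed   = Σ IVⱼ · mean(traitⱼ)` with species-level fixed means.

The fixed mean of a species is its *unweighted* average over all subplots
where it was measured. Fixed means are computed over the retained
(multi-species) subplots; computing them over all surveyed subplots is a
defensible alternative, but it would make the fixed means depend on
communities excluded from every downstream analysis, so the package uses
retained subplots throughout. The intraspecific component is defined as
`CWM_specific − CWM_fixed`, so the identity
`specific = fixed + intraspecific` holds exactly by construction, not to
a tolerance.

When a species carries importance in a subplot but lacks a trait value,
the default policy drops that subplot for that trait: renormalizing the
remaining IVs changes the weights away from the survey and mixes a
composition change into what is supposed to be a trait change. The
renormalizing variant is available (`missing = "renormalize"`) for data
sets where dropping would be too costly.

Height plays a double role: the per-species mean height within the
subplot both feeds `Hr` and serves as the trait `H`. This is deliberate
and documented here to avoid a second, conflicting definition.

## Environment: SWD, habitats, levels

The surface-water disturbance index of a plot is `SWD = ln(Σᵢ wᵢ)` over
the occurrence frequencies `wᵢ ∈ [0, 1]` of the surface-water raster
cells within 1 ha of the plot point. The log is undefined for plots where
overflow was never observed (`Σ wᵢ = 0`); such plots are kept at a
sentinel one unit below the smallest finite SWD and flagged. The sentinel
preserves the ordering (driest plot stays driest) and keeps all plots in
the analysis; any finite choice below the minimum is arbitrary, and one
unit on a natural-log scale (a factor e in summed frequency) is a
conservative gap. The index is invariant to cell order and to adding
zero-frequency cells.

Habitat types are K-means clusters of the standardized (z-scored,
denominator n−1) SWD and groundwater depth, clustered jointly — the two
variables define the habitat plane together. Defaults: `k = 3`, Lloyd's
algorithm, 50 restarts, best by total within-cluster SS, fixed internal
seed 20240215, bounded re-seeding if a restart returns an empty cluster.
Cluster indices are arbitrary, so labels are assigned by centroid
semantics: C is the high-SWD cluster; of the rest, A has the deeper
groundwater centroid, B the shallower. This makes labels a deterministic
function of the data rather than of the RNG.

For the two-way design, each water variable is separately cut into
`n_levels` ordinal levels from a Ward-linkage (Euclidean) dendrogram,
relabelled 1..n by increasing level mean. `n_levels = 3` per variable by
default: with ~19 plots, three levels is the finest split that keeps
several plots per level; the parameter is exposed and echoed in the
report.

## The decomposition

For a trait's CWM series over subplots, write `y_spec`, `y_fix`,
`y_int = y_spec − y_fix`. The total decomposition is

```
SS_spec = SS_fix + SS_int + SS_cov,
SS_cov  = 2 Σ (y_fix − ȳ_fix)(y_int − ȳ_int),
```

with each SS the centered sum of squares. The covariation term is
reported as the *signed remainder*, not halved and not folded into the
other components: a negative value is the substantive signal that
within-species shifts oppose the between-species turnover (communities
shift toward shorter species while surviving species grow taller, say).
Percentages are taken relative to `SS_spec`, so the three components sum
to exactly 100 for the total term. Sums of squares are used rather than
df-corrected variances; for percentages of a common total the two are
identical whenever the df are equal, and SS keeps the per-term identity
exact.

Under a factorial design (`~ sw_level * gw_level`), three parallel ANOVAs
are fitted — to `y_spec`, `y_fix` and `y_int` — with sequential (Type I)
sums of squares in the order the formula states. The design is unbalanced
in general, so term order matters; the order is configurable and echoed.
Per term, `ss_cov` is again the remainder, and a term's explanatory rate
for a component is that component's term SS divided by the *total* SS of
the specific CWM (one common denominator, so rates are comparable across
terms and components). Significance comes from the F tests of the
component ANOVAs; no p-value is attached to the covariation remainder
because none is defined for it. Degenerate designs are handled
explicitly: an empty factor cell drops the interaction with a warning;
aliased main effects are an error.

The subplot is the analysis unit; plot-level factors are broadcast to
subplots and no random plot effect is modelled. This keeps the
decomposition a pure sum-of-squares identity; a mixed-model extension is
out of scope.

## Habitat tests, regressions, factors

Habitat differences per trait use a gated test choice at α = 0.05:
Shapiro-Wilk per habitat group (all must pass) and Levene's test
(mean-centered, as in classic Levene) across groups. Both pass → LSD,
i.e. pooled-variance pairwise t tests, *deliberately unadjusted* — that
is what LSD is, and its letters must be read accordingly. Normal but
heteroscedastic → Tamhane's T2: pairwise Welch t with a Šidák-style
adjustment. Non-normal → Kruskal-Wallis omnibus with Dunn rank-sum
pairwise z tests. Groups too small for Shapiro-Wilk (n < 3) fall through
to Kruskal-Wallis with a warning. The omnibus test preceding LSD letters
is the ordinary one-way ANOVA (Welch's for T2). Letters come from the
insert-and-absorb algorithm and depend only on the significance pattern,
not on group order.

Regressions are OLS on z-scored variables, so the slope is the Pearson
correlation and slope² = R².

The factor analysis extracts `n_factors` (default 2, or the
eigenvalue-greater-than-one rule with `"auto"`) by principal components
of the trait correlation matrix, then applies a varimax rotation with
Kaiser normalization. Principal-component extraction is the most common
default in the software ecosystems this analysis is usually run in;
iterated principal-axis extraction is available behind
`method = "pa"`. Factor signs are fixed so each factor's largest loading
is positive; traits are assigned to the factor with the largest absolute
rotated loading. Communalities are rotation-invariant (checked to 1e-8 in
the tests) and the correlation matrix must be numerically nonsingular
(smallest eigenvalue above 1e-12).

## Piecewise SEM

Component models are OLS regressions, one per endogenous variable, on
z-scored data, so path coefficients are standardized effects. The DAG's
d-separation basis set contains one claim per non-adjacent variable pair,
`x ⫫ y | pa(x) ∪ pa(y)`, tested by adding `x` to the regression of the
endogenous (or topologically later) member. Pairs of exogenous variables
are excluded: SWD and GWD are allowed to correlate freely, and no
component model exists to test such a pair in. Claim p-values combine
into Fisher's `C = −2 Σ ln pᵢ` with `df = 2k`; a saturated DAG has
`C = 0` and fit p-value 1, and a claim p of exactly zero is reported as
infinite C with a flag.

Model selection uses `AIC = C + 2K` with `K` = paths + intercepts + error
variances — the piecewise-SEM convention, used because it compares DAG
topologies on the same data via their independence claims. It can order
models differently from a Gaussian-likelihood AIC; candidates fitted on
different complete-case row sets are refused rather than silently
compared. Soil predictors are screened for collinearity beforehand by
iteratively dropping the largest VIF until all are ≤ 10 (a conventional
threshold; exposed as a parameter). The default DAG skeleton per trait
component is: SWD → soil water content; {SWD, GWD, soil water content,
soil total N} → component; SWD and GWD exogenous. Indirect effects are
products of standardized path coefficients along directed chains, summed
over chains.

The SEM analysis unit is the subplot (plot-level water and soil variables
broadcast), consistent with the decomposition; with 19 plots alone the
component regressions would be underpowered for the default
five-predictor model.

## The synthetic generator

The generator emulates a 19-plot × 4-subplot design on a latent wetness
axis. Species have evenly spaced Gaussian niche optima on the axis;
expected abundance is `scale · exp(tw · (−(w − opt)²/2b²))` with
turnover weight `tw`, wetness `w`, breadth `b = 0.6`, topped with
lognormal noise and Poisson sampling. Species baselines for the five
traits (H, SPAD, LT, LNC, N/P) trend linearly along the optimum — tall,
low-nutrient, thick-leaved species at the dry end — and a second
species-level axis, orthogonal to the niche optimum, carries a SPAD/LT
trade-off so the trait correlation matrix has more than one dimension.
Within species, trait values drift along wetness with slope scaled by the
plasticity weight `pw`; by default the drift is aligned in sign with the
between-species trend (positive covariation), and
`make_negative_covariation()` flips it for nominated traits. Surface
water frequencies are drawn so `ln Σw` rises linearly with the
surface-water score; groundwater depth falls with its score; the two
scores are strongly but not perfectly coupled (coupling weight 0.6) so a
crossed two-way design remains realizable, with a fully independent mode
for design-focused tests. Soil water content tracks standardized SWD;
soil total N is independent of water; the remaining soil variables are
mildly water-correlated. Soil values are written per depth layer and
averaged back by the pipeline (full-profile means).

Trait measurement noise defaults to 2% of the between-species baseline
SD. The generator's purpose is validation against planted structure: a
pure-turnover scenario must show (almost) no intraspecific signal and a
pure-plasticity scenario no turnover signal, which requires measurement
noise well below both signals. Field data are far noisier; nothing here
asserts realism of noise levels, only of structure and value ranges.

The ground truth shipped with each dataset (`truth` element, or
`truth.json`) is obtained by pushing the *expected* construction —
noise-free abundances and trait values, deterministic presence at
expected count ≥ 0.5 — through the same CWM algebra, recording each
trait's interspecific and intraspecific SS and their ratio. Recovery of
that ratio from the noisy data is a stochastic property: the test suite
runs 100-replicate batteries and requires the per-trait *median* relative
error within ±20% at 200 subplots (50 plots) and ±50% at the field-sized
76 subplots. What passing these batteries shows is that the estimator
tracks planted turnover:plasticity structure at realistic design sizes;
it does not show robustness to the messiness of real surveys (missing
traits, observer effects, heteroscedastic noise, spatial autocorrelation
— none of which the generator emulates).

## Numerical choices, in one place

* Identities (`specific = fixed + intra`; per-term SS closure) are exact
  by construction; tests verify closure to 1e-8 relative.
* z-scores use the sample SD (n − 1); constant vectors are an error, not
  a silent zero.
* K-means: Lloyd, 50 restarts, iter.max 200, internal seed 20240215,
  ≤ 10 re-seeds on empty clusters.
* Ward levels: `hclust(..., "ward.D2")` on Euclidean distances; level
  ties broken by first occurrence.
* Varimax: Kaiser-normalized, eps 1e-10; sign fixed by each factor's
  largest loading; verified in tests against a 0.001-radian grid search
  of the rotation criterion.
* Fisher's C with k = 0 claims: C = 0, df = 0, p = 1.
* Degenerate inputs (single-species subplots, zero totals, empty factor
  cells, aliased designs, singular correlation matrices, cyclic DAGs,
  rank-deficient component models) all fail fast with named diagnostics.
* Test-suite problem sizes: oracle checks use 24-subplot designs
  (100 seeds), all DAGs on ≤ 5 nodes, 1000 null SEM simulations at
  n = 71, and the 100-replicate recovery batteries above — sizes chosen
  so each check has the power it needs while the whole suite stays quick
  to run.

## Known limitations

* No mixed-effects or permutation variants of the decomposition; the
  plot structure enters only through broadcast factors.
* LSD letters are unadjusted by design; users wanting family-wise control
  should read the Tamhane/Dunn branches or adjust externally.
* The piecewise SEM has no latent variables and no covariance-based
  global fit; exogenous correlations are left free, not modelled.
* The generator's single-axis default makes the trait correlation matrix
  strongly one-dimensional; factor-analysis behaviour on richer
  correlation structures is exercised with dedicated planted two-factor
  simulations rather than the community generator.
* Remote-sensing extraction of water frequencies, groundwater gap
  filling and all laboratory protocols are upstream of this package; it
  consumes their tabular outputs.
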