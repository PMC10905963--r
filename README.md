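# traitpart

Partitioning community-weighted mean (CWM) trait variation along water
gradients in desert wetland vegetation.

## The problem

Plant communities on surface-water / groundwater gradients change their
trait profile in two ways: the species present turn over (interspecific
variability), and individuals of the same species shift their traits
(intraspecific variability, plasticity). Separating the two — and tracing
them back to water and soil drivers — requires a chain of analyses that is
usually stitched together by hand. `traitpart` packages that chain:

- **Surface-water disturbance index.** For each plot,
  `SWD = ln(Σᵢ wᵢ)`, where `wᵢ` are the per-cell surface-water occurrence
  frequencies within 1 ha of the plot; plots with no observed overflow are
  floored one unit below the smallest finite SWD and flagged.
- **Habitat typing.** K-means on standardized SWD and groundwater depth
  (GWD), relabelled deterministically: A = low SWD / deep GWD, B = low SWD
  / shallow GWD, C = high SWD / shallow GWD. Ward clustering turns each
  water variable into ordinal levels for a two-way design.
- **CWM traits.** Species importance values
  `IVⱼ = (Arⱼ + Hrⱼ + Crⱼ)/3` (relative abundance, height, coverage)
  weight subplot-specific trait values (`CWM_specific = Σ IVⱼ·traitⱼ`) and
  species-level fixed means (`CWM_fixed`, the interspecific component);
  their difference is the intraspecific component, exactly.
- **Variance decomposition.** Sum-of-squares partitioning of
  `CWM_specific` into interspecific, intraspecific and covariation parts —
  in total, and per term of a sequential (Type I) two-way ANOVA over the
  clustered water levels. Negative covariation means within-species shifts
  run against the between-species turnover.
- **Trait statistics.** Gated habitat tests (Shapiro-Wilk + Levene →
  LSD / Tamhane's T2 / Kruskal-Wallis with Dunn) with compact letter
  displays; standardized regressions (slope = Pearson r); varimax-rotated
  factor analysis of the trait matrix.
- **Piecewise SEM.** Component OLS regressions over a DAG
  (SWD → soil water content → trait component, etc.), d-separation basis
  set, Fisher's `C = −2 Σ ln pᵢ` with `df = 2k`, and model selection by
  `AIC = C + 2K`.
- **Synthetic communities.** A generator with Gaussian niche turnover and
  within-species plasticity on a latent wetness axis, with known
  ground-truth interspecific:intraspecific SS ratios, so every stage can
  be validated against planted truth.

## Worked example

```r
library(traitpart)
rep <- run_pipeline(pipeline_config(seed = 1))

decomp_summary(rep$decomp_total)
#>      trait pct_fixed pct_intra pct_cov ratio_fixed_intra
#> H        H      59.8      5.25    35.0             11.39
#> SPAD  SPAD      63.4      4.26    32.3             14.90
#> LT      LT      65.9      3.65    30.5             18.05
#> LNC    LNC      57.5      5.95    36.6              9.66
#> N/P    N/P      57.5      5.96    36.6              9.65

rep$habitat_tests[["N/P"]]
#> Habitat-difference test (N/P)
#> test: KruskalWallis   omnibus p = 7.83e-15
#>  habitat  n     mean   median        sd letters
#>        A 16 16.15319 16.11101 0.1491047       a
#>        B 32 16.77412 16.76202 0.1795146       b
#>        C 28 17.57694 17.57849 0.2539681       c
```

Here the default synthetic scenario (19 plots × 4 subplots, turnover
weight 1, plasticity weight 0.5) is run end to end. `pct_fixed` /
`pct_intra` / `pct_cov` are the percentage contributions of species
turnover, plasticity and their covariation to the total variation of each
CWM trait (summing to 100 for the total term); `ratio_fixed_intra` is the
turnover:plasticity SS ratio. The habitat test shows N/P rising from the
dry, deep-groundwater habitat A to the flooded habitat C, with all three
habitats significantly distinct (letters a/b/c at P < 0.05).

The same functions run on field data: `read_survey()`, a long trait
table, a cell-frequency table and per-plot groundwater/soil tables plug
into `pipeline_config(inputs = list(...))`, or each stage
(`importance_values()`, `cwm_table()`, `trait_decomp()`, `fit_psem()`,
...) can be called directly.

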