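# pcrcal

Measure and mitigate PCR amplification bias in 16S rRNA amplicon studies
using calibration curves and Bayesian log-ratio linear models.

## The problem

PCR amplifies different bacterial templates with different efficiencies.
Over the 10–35 mid-to-late cycles of a typical 16S rRNA library prep, these
small per-cycle differences compound multiplicatively, so the sequenced
composition of a community can be skewed by factors of 4 or more relative to
the DNA that went into the reaction — enough to distort relative-abundance
estimates and alpha diversity.  `pcrcal` is for microbiome researchers who
want to quantify and remove this bias without building mock communities:
the only experimental addition is a *calibration curve* — a pooled aliquot
of study DNA split and amplified for a range of cycle numbers, sequenced
alongside the study samples.

## The model

If taxon *j* starts at abundance *a<sub>j</sub>* and is amplified with
per-cycle efficiency *b<sub>j</sub>*, then after *x* cycles its abundance is
*a<sub>j</sub> b<sub>j</sub><sup>x</sup>*.  In log-ratio coordinates defined
by a (D−1)×D contrast matrix Ψ this is a linear regression on cycle number:

```
η_i = Ψ log w_i = α + β x_i,    α = Ψ log a,   β = Ψ log b
```

The intercept α is the unamplified composition; the slope β is the
per-cycle bias.  To respect the counting noise and zeros of sequencing
data, the regression is embedded in a Bayesian multinomial logistic-normal
linear model:

```
Y_i ~ Multinomial(π_i),   π_i = C[exp(Ψ† η_i)]
η_i ~ N(Λ X_i, Σ),        Λ ~ MN(Θ, Σ, Γ),   Σ ~ IW(Ξ, υ)
```

where the design X carries group intercepts, the cycle number, and PCR
machine (batch) indicators.  Inference integrates Λ and Σ out analytically
(a matrix-t prior for η), finds the posterior mode of η by quasi-Newton
optimisation with analytic gradients, takes a Laplace approximation there,
and recovers Λ and Σ draws by conjugate matrix-normal / inverse-Wishart
updates.  No pseudo-counts are used anywhere; zeros are modelled by the
multinomial likelihood.  Study samples are corrected by the inverse
perturbation `φ⁻¹(Ψ log p_obs − β x)`, draw-wise, so the uncertainty in β
propagates into the corrected compositions.

## Worked example

Simulate a full calibration study (10 taxa, cycles 10–35, three aliquots
per cycle, plus 10 held-out mock communities amplified for 35 cycles),
estimate the bias, and correct a held-out community:

```r
library(pcrcal)
bundle <- simulate_mock_study(seed = 42)

cal    <- bundle$metadata$group == "calibration"
counts <- count_table(unclass(bundle$counts)[, bundle$metadata$sample_id[cal]])
bias   <- estimate_bias(counts, build_design(bundle$metadata[cal, ]), seed = 1)

glance(bias$fit)
#> # A tibble: 1 × 9
#>   n_taxa n_samples n_covariates n_draws log_marginal r2_mean r2_lower r2_upper
#> 1     10        78            2    2000       -5265.   0.857    0.844    0.866

head(tidy(bias, scale = "log2_fold", cycles = 35), 4)
#> # A tibble: 4 × 6
#>   taxon      mean  lower  upper excludes_zero scale
#> 1 taxon_1 -0.0737 -0.307  0.143 FALSE         log2_fold
#> 2 taxon_2  1.54    1.33   1.75  TRUE          log2_fold
#> 3 taxon_3 -2.12   -2.33  -1.91  TRUE          log2_fold
#> 4 taxon_4 -0.559  -0.775 -0.348 TRUE          log2_fold
```

The linear model explains ~86% of the variation in the simulated
calibration curve.  The tidy table gives each taxon's posterior log2 fold
change in proportion after 35 cycles: here taxon 2 ends up about
2^1.5 ≈ 2.9-fold over-represented and taxon 3 about 4.3-fold
under-represented, with credible intervals that exclude zero (`autoplot(bias)`
draws the forest plot).  Correcting a held-out community moves it an order
of magnitude closer (Aitchison distance) to its true composition:

```r
obs       <- closure(unclass(bundle$counts)[, "mock_01"] + 0)
corrected <- correct_composition(obs, bias, x = 35)
di <- distance_improvement(corrected, obs,
                           bundle$truth$mock_compositions[, "mock_01"])
c(corrected = di$mean_corrected, uncorrected = di$uncorrected)
#>   corrected uncorrected
#>   0.5123209   5.0366187
```

A command-line wrapper (`inst/cli/pcrcal.R`) exposes the same pipeline as
`simulate`, `fit`, and `correct` subcommands for shell use.

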