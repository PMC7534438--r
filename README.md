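# admixtract

Ancestry tract lengths around a positively selected introgressed allele.

## The problem

When a beneficial allele enters a population by admixture and then
sweeps upward in frequency (adaptive introgression — the *EPAS1*
haplotype that Tibetans acquired from a Denisovan-like population is
the canonical example), the unbroken segment of donor ancestry that
surrounds it is systematically longer than neutral admixture-dating
theory expects. Dating the admixture pulse from tract lengths while
ignoring selection therefore underestimates its age. `admixtract`
computes, deterministically, the full length distribution of the
ancestry tract containing the selected site, and provides a dating
workflow that accounts for selection.

The model: in backward time the selected-allele frequency follows the
logistic `ω(t) = 1/(1 + exp(st/2))` (or a conditioned mean trajectory
estimated by Wright–Fisher simulation when the admixture fraction is
too small for the mean-field approximation). Conditional on that
trajectory, the ancestry of two linked neutral sites is a six-state
time-inhomogeneous Markov chain `P'(t) = P(t) M(t)` combining
recombination (rates `r1`, `r2` in Morgans, weighted by `ω(t)`) and
coalescence within allelic backgrounds (rates `λ/ω(t)`, `λ/(1-ω(t))`,
`λ = 1/2Nₑ`). Integrating it from sampling to the admixture pulse
yields the along-genome hazard `τ₁₀(r)` that the donor tract ends at
distance `r`; the tract is the independent sum of its two sides, with
survival `S₁(r) = exp(-∫₀ʳ τ₁₀)`. A forward diploid Wright–Fisher
simulator with ancestry-junction tracking serves as an independent
validation oracle, and the neutral closed form
`E[L] = 2/[2Nₑ(1-ω₁)(1-e^(-T/2Nₑ))]` as the no-selection baseline.

## A worked example

```r
library(admixtract)

m <- tract_model(omega1 = 0.025, s = 0.01, T = 1000, two_ne = 10000)
m
#> Tract-length model under adaptive introgression
#> Adaptive-introgression scenario
#>   omega1 = 0.025 (admixture fraction), s = 0.01, T = 1000 generations, 2Ne = 10000 (logistic trajectory)
#>   expected tract length: 0.00260426 Morgans
#>   sd of tract length:    0.00173357 Morgans
#>   neutral expectation:   0.00215556 Morgans
```

A 2.5% pulse 1000 generations ago with `s = 0.01` leaves an expected
donor tract of ~0.0026 Morgans around the selected site — about 21%
longer than the neutral expectation for the same pulse. Doubling the
selection coefficient lengthens the expected tract by 41%
(`mean(tract_model(omega1 = 0.025, s = 0.02, T = 1000, two_ne = 1e4))`
gives 0.00367), while doubling the admixture proportion adds only 12%:
near a sweep, tract lengths are far more sensitive to selection than to
the admixture fraction.

Dating a Denisovan-like pulse (admixture fraction 0.06%, present-day
allele frequency 85%):

```r
date_introgression(omega1 = 6e-4, omega0 = 0.85, s = 0.01,
                   two_ne = 20000, traj_two_ne = 10000,
                   n_reps = 1e5, seed = 42)
#>      s    T tract_length neutral_length  rel_diff
#> 1 0.01 1466  0.001792153   0.0014157167 0.2658979
```

Under `s = 0.01` the observed frequency is reached ~1466 generations
after the pulse, and the expected tract is ~27% longer than a neutral
tract for that age — so reading the tract length with a neutral clock
would misdate the pulse substantially.

Other entry points: `conditional_mean_trajectory()`,
`expected_tract_length()`, `tract_length_sd()`,
`neutral_expected_tract_length()`, `simulate_admixture()` /
`sample_tracts()` / `empirical_summary()` (forward simulator),
`validate_model()` (simulator-vs-model comparison),
`run_expected_length()` / `run_distribution()` / `run_dating()` (TSV
workflows), and a thin command-line front end in `inst/cli/admixtract`.
The methods vignette (`vignettes/tract-length-model.Rmd`) documents the
model, its assumptions and every numerical choice.

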