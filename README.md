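# partialFIS

Exact distributions of the inbreeding coefficient F<sub>IS</sub> at a
biallelic locus in a finite, partially asexual population.

Many species reproduce through a mixture of clonal (asexual) and sexual
events. Population geneticists routinely read the balance of the two off
F<sub>IS</sub> — the deficit (positive) or excess (negative) of
heterozygotes relative to Hardy–Weinberg proportions — but classical
theory only predicts its *mean* under partial asexuality, while real
data deliver whole distributions across loci and populations. partialFIS
computes the **full exact distribution**: it treats the population's
genotypic configuration as a Markov chain and solves it, with no
diffusion or allele-pool approximation.

## Model

A population of `N` diploid individuals evolves in discrete
generations. Each offspring is clonal with probability `c` (copies one
uniform parent's genotype) or sexual with probability `1 - c` (random
union of gametes); every transmitted allele mutates reciprocally
(a ⟷ A) with probability `mu`. The genotypic state
`(n_aa, n_aA, n_AA)` (counts summing to `N`) evolves as a Markov chain
on `(N+1)(N+2)/2` states whose transition law is multinomial with
category probabilities

```
f' = c * T_asex(f) + (1 - c) * T_sex(f),        f = (n_aa, n_aA, n_AA)/N
```

For `mu > 0` the chain is ergodic and its stationary distribution `pi`
(solved exactly, `pi P = pi`) yields the stationary distributions of

```
Q_w = (n_aa + n_AA)/N          identity within individuals
Q_b = p^2 + q^2                identity in the allele pool, p = (2 n_aa + n_aA)/(2N)
F_IS = (Q_w - Q_b)/(1 - Q_b)   undefined at allele fixation
```

plus sign/fixation probabilities, four moments, state probability
rankings, and one-generation sign-transition fluxes.

## Worked example

Stationary analysis of a mostly-sexual population of 60 individuals with
weak mutation:

```r
library(partialFIS)

sp <- state_space(60)                              # 1891 genotypic states
tm <- transition_matrix(sp, c = 0, mu = 1e-8)      # exact multinomial chain
st <- stationary_distribution(tm)                  # pi P = pi, solved dense

sign_probabilities(st, sp)
#> P(F_IS < 0 | no fixation)  = 0.773781
#> P(F_IS >= 0 | no fixation) = 0.226219
#> P(allele fixation)         = 0.999987
```

Almost all unconditional stationary mass sits on the two allele-fixation
states (drift wins at `N mu = 6e-7`), but *conditional on remaining
polymorphic* the locus shows heterozygote excess (negative F<sub>IS</sub>)
77% of the time — even with no asexuality at all. Raising the rate of
asexuality pushes this higher and reshapes the whole distribution:

```r
st1 <- stationary_distribution(transition_matrix(sp, c = 1, mu = 1e-8))
sign_probabilities(st1, sp)$p_negative
#> [1] 1
d <- statistic_distribution(st1, sp, "fis")
d$probability[d$value == -1]
#> [1] 0.9999772
```

Under full asexuality and weak mutation, drift fixes heterozygotes:
conditional on polymorphism the distribution masses on F<sub>IS</sub> = −1
(every individual heterozygous). The dynamic counterpart — how often the
*sign* of F<sub>IS</sub> flips in one generation, averaged over all
states:

```r
sign_flux_summary(tm, sp)
#> Uniform-source one-generation F_IS sign flux (cells sum to 1):
#>              target
#> source        negative nonnegative
#>   negative    0.199036    0.156860
#>   nonnegative 0.363895    0.280209
```

Per-state statistics are exact rationals; e.g. in a population of 140:

```r
state_statistics(c(116, 24, 0), 140)$fis   # -0.09375  (= -3/32 exactly)
state_statistics(c(124, 15, 1), 140)$fis   #  0.06061284... (= 271/4471)
```

An independent forward simulator (`simulate_population()`) cross-checks
the exact chain, a deterministic recursion
(`iterate_infinite_population()`) gives the infinite-population limit,
`run_experiment()` sweeps `(N, c, mu)` grids to CSV + JSON manifest, and
`inst/cli/partialfis` exposes every operation as a shell subcommand.

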