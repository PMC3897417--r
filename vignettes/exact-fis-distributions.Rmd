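---
title: "Exact F_IS distributions under partial asexuality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact F_IS distributions under partial asexuality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partialFIS)
```

## The model

partialFIS models one biallelic locus (alleles $a$ and $A$) in a diploid
population of fixed size $N$ with discrete, non-overlapping generations.
Each offspring is produced **clonally** with probability $c$ (the rate of
asexuality) — it copies the full diploid genotype of one uniformly chosen
parent — or **sexually** with probability $1-c$, by random union of two
gametes, each a uniformly chosen allele of a uniformly chosen parent
(gametes are drawn with replacement, so selfing occurs at the background
rate $1/N$). Every transmitted allele mutates independently to the other
allele with probability $\mu$ (reciprocal mutation). There is no
selection and no migration.

The population's genetic configuration is summarised by its **genotypic
state** $(n_{aa}, n_{aA}, n_{AA})$, the counts of the three genotypes,
with $n_{aa}+n_{aA}+n_{AA}=N$. There are $S=(N+1)(N+2)/2$ states. Given
the parental state with genotype frequencies $f = (n_{aa}, n_{aA},
n_{AA})/N$, the expected offspring genotype frequencies are the mixture

$$ f' \;=\; c\,T_{\mathrm{asex}}(f) \;+\; (1-c)\,T_{\mathrm{sex}}(f), $$

where $T_{\mathrm{asex}}$ applies per-allele mutation to a copied
genotype (with $v = 1-\mu$):

$$ f'_{aa} = f_{aa}v^2 + f_{aA}\mu v + f_{AA}\mu^2,\qquad
   f'_{aA} = 2\mu v\,(f_{aa}+f_{AA}) + f_{aA}(v^2+\mu^2), $$

($f'_{AA}$ symmetric), and $T_{\mathrm{sex}}$ returns Hardy–Weinberg
proportions of the mutated allele frequency
$p' = p(1-\mu) + (1-p)\mu$, $p = f_{aa} + f_{aA}/2$.

Because the $N$ offspring are produced independently, the transition
probability between states is **multinomial**: the probability of moving
from state $E_k$ to $E_l = (n'_{aa}, n'_{aA}, n'_{AA})$ is the
multinomial probability of drawing those counts in $N$ trials with
category probabilities $f'(E_k)$. For $\mu \in (0, 0.5)$ every entry of
the $S \times S$ transition matrix $P$ is strictly positive, so the
chain is irreducible and aperiodic, hence ergodic: by Perron–Frobenius
it has a unique stationary distribution $\pi$ with $\pi P = \pi$,
reached from any initial state.

### Summaries of the stationary distribution

For each state we compute the probability of allelic identity within
individuals, $Q_w = (n_{aa}+n_{AA})/N$, and between alleles of the
population pool, $Q_b = p^2 + q^2$ with $p = (2n_{aa}+n_{aA})/(2N)$,
and the inbreeding coefficient

$$ F_{IS} \;=\; \frac{Q_w - Q_b}{1 - Q_b}, $$

undefined at the two allele-fixation states $(N,0,0)$ and $(0,0,N)$
where $Q_b = 1$. Negative $F_{IS}$ is heterozygote excess; the
all-heterozygote state $(0,N,0)$ has $F_{IS} = -1$.

$Q_b$ here uses the *with-replacement* identity over all $2N$ alleles
($p^2+q^2$), not the strictly between-individuals estimator. The two
differ at order $1/N$; the package's convention is pinned by exact
rational arithmetic on reference configurations — for example
$(116, 24, 0)$ at $N=140$ gives $F_{IS} = -3/32 = -0.09375$ exactly,
and $(124, 15, 1)$ gives $271/4471 = 0.06061284\ldots$ — which only the
with-replacement form reproduces.

From $\pi$ the package reports:

* **Sign and fixation probabilities.** The fixation probability is the
  unconditional mass of the two fixation states. The probabilities of
  negative and of nonnegative $F_{IS}$ are *conditional on no fixation*
  (renormalised): at $\mu = 10^{-8}$ nearly all unconditional mass sits
  on the fixation states, and the conditional split is the meaningful
  quantity for polymorphic loci.
* **Discrete distributions** of $F_{IS}$ (fixation states excluded,
  renormalised), $Q_w$ and $Q_b$ (all states). Stationary mass is
  aggregated over states sharing the same *exact rational* value of the
  statistic (reduced numerator/denominator pairs), so values that collide
  mathematically but differ in the last floating-point bit aggregate
  correctly.
* **Four moments** of the conditioned $F_{IS}$ distribution: mean,
  variance, classical skewness $m_3/m_2^{3/2}$ and classical excess
  kurtosis $m_4/m_2^2 - 3$.
* **State rankings** (1 = most probable) and comparisons of rankings
  across parameter sets (counts of states with identical vs changed
  rank).
* **Sign-transition fluxes**: the average one-generation probability of
  staying in or leaving the negative-$F_{IS}$ class. Each state gets
  uniform source weight $1/S$ (the stationary distribution is *not*
  involved), the two sign classes partition all states with the
  fixation states placed in the nonnegative class, and
  $\mathrm{flux}[X][Y]$ sums the transition mass from class $X$ into
  class $Y$ divided by $S$. The four cells therefore sum to 1, and each
  source row's total equals that class's share of the state space — a
  structural constant independent of $c$ and $\mu$ (at $N = 60$ it is
  $673/1891 = 0.355896$), which is a useful validity check on any
  implementation of this estimator.

### Conventions where the design was open

* **Fixation states and the sign partition.** $F_{IS}$ is undefined at
  fixation. For the *sign-flux* partition the fixation states are
  assigned to the nonnegative class so the two classes cover all states
  and the table's cells sum to 1. For $F_{IS}$ *distributions and
  moments* the fixation states are excluded and the distribution
  renormalised; $(0,N,0)$ is retained ($F_{IS}=-1$ is defined there).
* **Rank ties.** Stationary probabilities are generically distinct, but
  mirror-image states (swap $a \leftrightarrow A$) have *mathematically
  equal* mass under symmetric mutation; floating point resolves each
  pair's order by rounding. Ordinal ranks break exact ties by canonical
  state order, and `rank_states()` reports the number of exactly tied
  states as a diagnostic. Consequently the count of rank-identical
  states between two parameter sets is reproducible only up to a few
  states across implementations — an intrinsic feature of ranking
  near-tied values, not a solver defect.
* **Canonical state order** is $n_{aa}$ descending, then $n_{aA}$
  descending. It is an implementation constant; every output table
  carries explicit `(n_aa, n_aA, n_AA)` labels.

## Numerical methods

**Matrix build.** Multinomial probabilities are computed in log space
with `lgamma` coefficients and exponentiated in compiled code (1e8
`exp` calls take well under a second compiled; the same loop in
interpreted R is two orders of magnitude slower). Rows are renormalised
to sum exactly to 1. Before renormalisation the row-sum deviation is
asserted to be below $64\,(\ln\Gamma(N+1)+1)\,\epsilon$ — the rounding
floor of log-space arithmetic, about $7\times10^{-12}$ at $N=140$;
measured deviations are $\sim 10^{-13}$. A genuine model error would
exceed this by orders of magnitude.

**Stationary solve.** Power iteration needs on the order of $1/\mu$
steps (the spectral gap closes as $\mu \to 0$), which is hopeless at
$\mu = 10^{-8}$. Instead one equation of the singular system
$(P^{\mathsf T} - I)\pi = 0$ is replaced by the normalisation
$\sum_i \pi_i = 1$ and the system solved by dense LU. Entries in
$[-10^{-12}, 0)$ are clipped to zero and the vector renormalised; the
residual $\lVert \pi P - \pi \rVert_\infty$ is checked against
$10^{-12}$ (measured residuals are $\sim 10^{-16}$). Conditional
summaries at tiny $\mu$ are ratios of very small stationary masses and
are computed from the raw solve without thresholding.

**Sizes and budgets.** The dense matrix holds $S^2$ doubles: 28 MB at
$N = 60$ ($S = 1891$), 0.8 GB at $N = 140$ ($S = 10011$). A build takes
seconds and an LU solve tens of seconds at $N = 140$ on one core, with
peak memory about 2.4 GB during the solve. The dense build is capped at
16000 states by default (`max_states`); beyond that the quadratic memory
growth calls for an out-of-core formulation that this package does not
implement ($N = 400$ would already need 113 GB).

**Deterministic recursion.** `iterate_infinite_population()` iterates
the expected-frequency map without sampling — the infinite-population
limit. For $\mu > 0$ its unique fixed point is $(1/4, 1/2, 1/4)$ with
$F_{IS} = 0$ for every $c$, including full asexuality: without drift,
mutation alone restores Hardy–Weinberg proportions. Heterozygote
fixation ($F_{IS} \to -1$) under full asexuality is therefore a
finite-population, drift-driven phenomenon, visible in the exact chain
at small $N\mu$.

## The Monte-Carlo oracle

`simulate_population()` is an independent forward simulator of the same
generative process, used to cross-check the exact chain. It samples
each offspring's *lineage* explicitly (clonal parent copy, or two
gametes from random parents, then per-allele mutation) and never touches
the mixture/multinomial algebra used by `transition_matrix()` — so
agreement between simulated occupancy and the exact $\pi$ validates the
factorisation of the transition law, not just its coding. Runs are
reproducible from an integer seed, recorded in the result.

What the simulator emulates is exactly the model above; what it does
*not* emulate is any feature of real data — genotyping error, sampling
of individuals, linked loci, selection, population structure, varying
$N$ or $c$ over time. Tests passing against it therefore validate the
mathematics of the implementation, not the model's fit to any
particular organism.

The test suite compares occupancy at $N = 5$, $c = 0.5$, $\mu = 0.05$
(a fast-mixing chain) over $10^6$ generations, recording every 25th
generation so that retained samples are nearly independent and binomial
standard errors apply; per-state agreement is required within 3 SE.
One-generation transition frequencies from a fixed source state are
compared to the exact multinomial row within 4 SE and by a chi-square
goodness-of-fit test.

## Problem sizes used in the shipped tests

Module tests run at $N \le 25$ where exhaustive oracles are feasible
(complete enumeration of all $3^N$ offspring assignments at $N \le 3$;
brute-force state enumeration at $N \le 50$). End-to-end checks
reproduce reference values at $N = 60$ (1891 states) across several
$(c, \mu)$ combinations and at $N = 140$ (10011 states) for the
heaviest cases: stationary solves at $\mu = 10^{-6}$, $c \in
\{0, 0.5\}$ for rankings, at $c = 0.9$, $\mu = 10^{-3}$ for sign
probabilities, and a matrix build at $c = 1$, $\mu = 10^{-3}$ for the
sign flux. These sizes were chosen as the smallest that exercise every
regime of the model (drift-dominated $N\mu \ll 1$ and mutation-dominated
$N\mu \sim 0.1$) while keeping a full test run in minutes.

## Known limitations

* Biallelic loci only; the state-space construction does not extend as
  written to more alleles (the state count grows combinatorially with
  the number of genotypes).
* Dense linear algebra bounds $N$ at roughly 150–250 on a workstation;
  no sparse or out-of-core path is provided.
* The identical-rank count between two stationary distributions is
  sensitive at the unit level to floating-point resolution of
  mathematically tied mirror states (see above); treat small
  differences across platforms as expected.
* `mu = 0` disables stationary analysis (the chain is absorbing at the
  fixation states and not ergodic); transient dynamics remain available.
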