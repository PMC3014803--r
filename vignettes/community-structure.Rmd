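---
title: "Models and methods behind commstruct"
author: "commstruct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind commstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commstruct)
```

## The problem

Passive ground-level surveys (pitfall traps and their relatives) yield a
table of taxa and counts: how many individuals of each species, family and
order were caught. Three questions dominate the analysis of such tables in
community ecology:

1. **Which species-abundance distribution (SAD) describes the community?**
   The shape of the ranked abundances — a few hyper-dominant species versus
   a smooth, even spread — is read as a fingerprint of the processes
   structuring the assemblage.
2. **How diverse is the community, and do two samples differ in
   diversity?** Shannon–Wiener diversity with an analytic variance allows a
   t-type test between two samples.
3. **Is the community dominated by a trophic role?** Classifying taxa as
   herbivores, predators or scavengers and testing guild tallies for
   homogeneity.

A recurring complication in arid-land pitfall data motivates much of the
design: colonial taxa, above all ants, fall into traps en masse. A single
recruiting species can hold 80% and more of all individuals, swamping every
abundance-based summary. The package therefore treats *taxon exclusion* as
a first-class, provenance-tracked operation, so analyses can be reported
with and without the dominant group.

## The four abundance models

All fitting happens on an `abundance_vector`: the strictly positive counts
$n_1 \ge n_2 \ge \dots \ge n_S$ at one taxonomic level, with $N = \sum_i
n_i$. Ties are broken by input order, so rank profiles are deterministic.

The candidate models, in increasing order of evenness:

* **Dominance pre-emption (geometric series).** Each species takes a
  fraction $k \in (0,1)$ of the niche space left by its predecessors,
  giving expected rank proportions
  $p_i = k(1-k)^{i-1} / \bigl(1-(1-k)^S\bigr)$.
* **Fisher log-series.** A species' count follows the zero-truncated
  series $P(n) = -x^n / (n \log(1-x))$, $n \ge 1$, $x \in (0,1)$. Fisher's
  $\alpha = -S/\log(1-x)$ is reported as a derived diversity parameter.
* **Poisson-lognormal.** Mean abundances are lognormal$(\mu, \sigma)$ and
  observed counts Poisson around them; species with $n = 0$ are truncated
  away. This is the count-level realization of the lognormal SAD —
  appropriate for discrete trap counts, where fitting a continuous
  lognormal to log-counts would ignore the sampling layer.
* **MacArthur's broken stick.** Simultaneous random partition of the
  resource: $p_i = \frac{1}{S}\sum_{j=i}^{S} 1/j$, with no free
  parameters.

### Likelihood constructions

The log-series and Poisson-lognormal are genuine count distributions, so
their log-likelihood is the sum of log pmf values over species. The
pre-emption and broken-stick models predict *proportions per rank*, not a
count distribution; to give them a likelihood (required for AIC) the
package uses the multinomial on ranked counts, including the multinomial
coefficient:
$$\log L = \log \binom{N}{n_1,\dots,n_S} + \sum_i n_i \log p_i .$$

This bridge is a modelling choice with a consequence worth stating
plainly: the two likelihood families live on different granularities of
the sample space (independent species counts versus one allocation of $N$
individuals), so AIC comparisons *across* the families are less robust
than comparisons *within* them, and become sensitive when $N/S$ is small.
The validation suite quantifies this at the sizes the package targets
(see below); users comparing models across the two families at small
sample sizes should lean on the $\Delta$AIC equivalence flag rather than
the bare ranking.

Free parameters counted in $\mathrm{AIC} = 2k - 2\log L_{\max}$: 1
(pre-emption $k$), 1 (log-series $x$; $\alpha$ is derived), 2
(lognormal $\mu, \sigma$), 0 (broken stick). $S$ and $N$ are conditioned
on throughout, as is conventional. Models within `delta_threshold`
(default 2) of the minimum AIC are flagged *equivalent* — AIC differences
below about 2 do not separate models meaningfully.

## Estimation

**Maximum likelihood.** The log-series score equation reduces to mean
matching, $N/S = -x/\bigl((1-x)\log(1-x)\bigr)$, solved by bracketed
root-finding to near machine precision. The pre-emption $k$ is found by
bounded scalar optimization of the multinomial log-likelihood. The
Poisson-lognormal is maximized by Nelder–Mead on $(\mu, \log\sigma)$ from
five deterministic starts (method of moments on log counts, plus fixed
perturbations of $\pm 1$ in $\mu$ and a factor 2 in $\sigma$), followed by
a BFGS polish; the likelihood can be multimodal for small $S$, and the
multi-start makes the grid-dominance checks in the test suite pass without
hand-tuning.

**Quadrature.** The Poisson-lognormal mass needs
$\int \mathrm{Pois}(n; e^z)\, \mathcal N(z; \mu, \sigma^2)\, dz$. The
package uses 64-node Gauss–Hermite quadrature with log-sum-exp
accumulation, *re-centred for every count at the mode of the log
integrand* with its Laplace width. The re-centring matters: the integrand
narrows like $n^{-1/2}$, so a rule fixed at $(\mu, \sigma)$ loses accuracy
precisely for the abundant species and visibly biases $\hat\sigma$
downward. The adapted rule agrees with adaptive numerical integration to
better than $10^{-8}$ over the tested range and is deterministic.

**MCMC.** The same likelihoods can be sampled by random-walk Metropolis on
an unconstrained scale (logit for $x$ and $k$, log for $\sigma$), with
weakly informative priors: Uniform(0,1) for $x$ and $k$, Normal(0, 10) for
$\mu$, Half-Normal(5) for $\sigma$. Defaults are a single chain of 10,000
draws with 1,000 burn-in and a mandatory integer seed; the proposal scale
is tuned only during burn-in (toward 44% acceptance in one dimension, 30%
in two) and then frozen, so a run is bit-reproducible from its seed.
Convergence is summarized by a split-half potential-scale-reduction factor
(flagged above 1.1). The AIC of an MCMC fit uses the maximum per-draw
log-likelihood refined by local optimization from the best draw; with
these priors that converges to the ML value (the validation suite checks
agreement to 0.1 nat, and observes gaps below $10^{-6}$), so Bayesian and
ML model selection coincide.

## Diversity

Shannon–Wiener diversity is computed in natural log from observed
proportions, $H = -\sum p_i \log p_i$, with no small-sample bias
correction, together with evenness $J = H/\log S$ (undefined at $S = 1$)
and the large-sample variance
$$\widehat{\mathrm{var}}\,H = \frac{\sum p_i (\log p_i)^2 - \bigl(\sum p_i
\log p_i\bigr)^2}{N} + \frac{S-1}{2N^2}.$$
Two samples are compared by Hutcheson's modification of the t-test,
$t = (H_a - H_b)/\sqrt{\mathrm{var}H_a + \mathrm{var}H_b}$ with Welch-type
degrees of freedom and a two-sided p-value. The variance and the df are
large-sample approximations; the suite checks by simulation that the test
holds its nominal 5% type-I error (within 3–7%) on multinomial resamples
of a fixed community at $N = 2000$.

## Trophic guilds

Guild membership (herbivore / predator / scavenger) is assigned at the
record level; `"unknown"` is allowed for undetermined material and is
excluded from tallies with its count logged. Family richness per guild
counts families with at least one member of that guild, so a mixed family
may appear in several guilds. The omnibus test compares the three tallies
to an equal split (df = 2), followed by the three pairwise equal-split
tests (df = 1) judged against the Bonferroni level $\alpha' = \alpha/3$.
The equal-expectation null is an explicit assumption — there is no a
priori reason to expect one guild to dominate — and the building block
`chisq_gof()` accepts arbitrary expected counts for users who prefer a
different null. No continuity correction is applied, as expected counts in
the intended use are large.

## The synthetic community generator

Because raw per-trap counts from field studies of this kind are rarely
deposited, every stage of the package is validated against
`simulate_community()`, which emulates the statistical structure such data
exhibit: about 150–160 species in a few dozen families and about 18
orders; a total catch in the tens of thousands; optionally one colonial
"recruiter" species holding a fixed fraction (typically ~83%) of all
individuals; log-series-shaped decay among the remaining species; and
guild labels drawn from configured probabilities (predator-heavy by
default in the reference fixture).

Three generator choices deserve explanation:

* **Exact conditioning for the log-series.** The joint law of $S$ iid
  zero-truncated log-series counts *given their total $N$* is proportional
  to $\prod_i 1/n_i$ on positive compositions of $N$ — the parameter $x$
  cancels once the total is fixed. The generator samples this conditional
  law exactly, by pairwise Gibbs exchanges with
  $P(a \mid a + b = t) \propto 1/\bigl(a(t-a)\bigr)$, started from a
  rescaled iid draw. The obvious alternative — drawing iid counts and
  allocating $N$ individuals by a multinomial on the drawn proportions —
  superimposes an extra Poisson-like sampling layer that measurably
  distorts the marginal count distribution (enough to flip AIC selection
  toward the more flexible Poisson-lognormal in roughly a quarter of
  replicates). Conditioning keeps both the invariant
  $\sum \mathrm{count} = N$ exactly and the model's distribution. A
  byproduct: with $S$ and $N$ fixed exactly, the log-series ML estimate is
  a function of $N/S$ alone, so recovery of $x$ is essentially exact by
  construction.
* **Multinomial allocation for the rank-profile models** is not a
  compromise: a multinomial draw of size $N$ on the profile is precisely
  the sampling model their likelihood bridge assumes.
* **Poisson draws then multinomial allocation for the lognormal** add a
  second Poisson layer, which is immaterial there because the model
  already contains a Poisson stage on means that dominate the variance.

Species are assigned uniformly at random to families and families to
orders (with every family and order guaranteed at least one member);
uniformity is the least-assumption default since no family-size
distribution is imposed. The generator does **not** emulate spatial trap
structure, season or year effects, detection/trapping bias, or realistic
taxonomic imbalance between families — so passing tests demonstrate
correctness of the estimators and workflow on communities with the target
abundance structure, not robustness to those field phenomena.

Default study sizes used throughout validation, chosen to match the scale
of a multi-year arid-land pitfall survey: $S = 150$, $N = 25{,}000$ for
fitting and selection checks (100 replicates per model), $S = 160$,
$N = 28{,}111$ with an 83% recruiter for the end-to-end fixture, 1,000
replicates for the Hutcheson calibration, and a pre-emption fraction
$k = 0.3$ with lognormal $\sigma = 1.2$ (with $\mu$ set so the mean count
matches $N/S$) as generating parameters.

## Degenerate inputs and numerical conventions

* All counts equal to 1: the log-series $x$ sits at its lower boundary;
  the fit is returned with a warning.
* All counts equal: the Poisson-lognormal $\hat\sigma$ is pinned at a
  small lower bound ($10^{-4}$) with a warning and $\mu$ optimized alone.
* A single group: $H = 0$ exactly, $\mathrm{var}H = 0$ exactly, evenness
  undefined (`NA`), broken-stick log-likelihood 0 and AIC 0.
* Two single-species samples cannot be compared by Hutcheson's test
  (zero pooled variance) and raise an error.
* Pre-emption profiles are computed in log space so extreme $(S, k)$
  survive floating-point underflow; ranks whose proportion underflows to
  zero simply contribute $-\infty$ log-likelihood when occupied.
* Rank ties are never reordered (stable sorts throughout), and AIC ties
  in selection keep input order.

## Known limitations

* AIC comparisons across the two likelihood families (count pmf versus
  multinomial-on-ranks) are a convention, not a theorem; at small $N/S$
  the multinomial models gain an edge unrelated to ecological fit. Within
  families, comparisons behave as expected at the validated sizes.
* A community with a genuine point mass — one species holding a large
  fixed share of $N$ on top of a log-series tail — is *better* fitted by
  the heavy-tailed Poisson-lognormal than by the log-series, and the
  selection report will say so. The recommended workflow for such data is
  the one the pipeline automates: analyze with and without the dominant
  taxon and report both strata.
* Hutcheson's variance is a delta-method approximation; with very small
  $N$ or extreme dominance the nominal error rate can drift.
* The MCMC sampler is a single adaptive random-walk chain, adequate for
  the 1–2 parameter posteriors here; it is not a general-purpose sampler.
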