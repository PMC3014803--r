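# commstruct

Community-structure statistics for taxon-by-count survey data — the kind
of table a pitfall-trap campaign produces: one row per species or
morphospecies with its family, order, an optional trophic-guild label, and
the number of individuals caught.

The package is aimed at community ecologists (and anyone analysing
abundance tables with the same machinery, e.g. microbiome profiles) who
want the classical battery of community-structure analyses behind one
reproducible interface:

* **Species-abundance-distribution (SAD) fitting and selection.** Four
  models, in increasing order of evenness: dominance pre-emption
  (geometric series, parameter *k*), the Fisher log-series
  (P(n) = −xⁿ/(n log(1−x)), parameter *x*, derived Fisher's α), the
  zero-truncated Poisson-lognormal (μ, σ), and MacArthur's broken stick
  (parameter-free). Estimation by maximum likelihood and by MCMC
  (random-walk Metropolis with weak priors), model choice by AIC with a
  ΔAIC < 2 equivalence rule.
* **Diversity.** Shannon–Wiener H (natural log), its large-sample
  variance, evenness J = H/log S, and Hutcheson's t-test for comparing H
  between two samples (Welch-type df, two-sided p).
* **Trophic guilds.** Abundance and family richness tallied by
  herbivore/predator/scavenger, an equal-split omnibus chi-square (df = 2)
  and pairwise tests (df = 1) at the Bonferroni level α′ = α/3.
* **Synthetic communities.** A seeded generator that emulates the
  structure of a large arid-land pitfall survey — including a colonial
  "recruiter" species holding a fixed share of the catch — so the whole
  workflow is testable without field data.
* **A pipeline** (`run_pipeline()`) that runs all of the above per
  taxonomic level, with and without configured taxon exclusions (the
  with/without-ants comparison), and renders a plain-text report. A thin
  command-line wrapper ships in `inst/scripts/commstruct`.

See `vignette("community-structure")` for the models, the likelihood
constructions (including how the rank-profile models are given a
multinomial likelihood so all four are AIC-comparable), and the design
choices.

## Worked example

A small synthetic demonstration table ships with the package
(`inst/extdata/pitfall_demo_synthetic.csv`; 16 taxa, hand-written, ants
dominant):

```r
library(commstruct)
path <- system.file("extdata", "pitfall_demo_synthetic.csv",
                    package = "commstruct")
tab <- read_community_table(path)
av  <- aggregate_abundance(tab, "species")

fits <- lapply(c("logseries", "preemption", "brokenstick", "lognormal"),
               function(m) fit_sad(av, m))
select_sad_models(fits)
#> SAD model selection (delta-AIC threshold 2): best = lognormal
#>         model n_params    logLik      AIC  delta_AIC equivalent
#> 1   lognormal        2  -100.445  204.891    0.00000       TRUE
#> 2   logseries        1  -104.794  211.587    6.69612      FALSE
#> 3  preemption        1  -968.908 1939.816 1734.92492      FALSE
#> 4 brokenstick        0 -3329.907 6659.814 6454.92288      FALSE
```

The heavy-tailed lognormal wins here because two ant species hold 81% of
all individuals — exactly the situation in which the recommended workflow
is to repeat the analysis without the colonial family and report both:

```r
noants <- exclude_taxa(tab, "family", "Formicidae")
shannon(av)
#> H = 1.3003 nats (var 0.000305), S = 16, N = 6295, J = 0.4690
shannon(aggregate_abundance(noants, "species"))
#> H = 2.2011 nats (var 0.000533), S = 14, N = 1195, J = 0.8341
hutcheson_test(av, aggregate_abundance(noants, "species"))
#>  Hutcheson's t-test for Shannon diversity
#> t = -31.126, df = 2780.7, p-value < 2.2e-16
```

Removing the ants nearly doubles Shannon diversity and lifts evenness from
0.47 to 0.83; Hutcheson's test calls the difference decisive. The guild
battery on the same table:

```r
guild_tests(tally_guilds(tab), alpha = 0.05)
#> Guild chi-square tests (alpha = 0.05, Bonferroni alpha' = 0.0167)
#> abundance: omnibus X^2 = 8380, df = 2, p = 0
#> ...
#> family_richness: omnibus X^2 = 0.5, df = 2, p = 0.7788
#> (12 individuals with guild 'unknown' excluded)
```

Guild abundances differ strongly while family richness does not — the
typical signature when a few guilds recruit heavily to traps.

The same analysis, end to end, from one call:

```r
bundle <- run_pipeline(path, levels = c("species", "family"),
                       exclusions = "family=Formicidae", seed = 1)
render_report(bundle)
```

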