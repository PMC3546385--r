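# rutsim

Constrained random-mating pedigree simulations for polygynous
populations with overlapping generations.

## The problem

In harem-breeding mammals with philopatric, matrilineal females —
red deer are the motivating system — two mating patterns concentrate
paternity within female kin groups: **mate fidelity** (the same
female–male pair breeding in more than one rut without a pair bond)
and **intralineage polygyny** (females of one matriline mating with
the same male). Both raise pairwise relatedness in the population and,
when related males also rut near one another, inbreeding.

Testing whether these behaviours exceed chance requires a null model
that respects who *could* have mated: a female is only available in
the years she conceived, and only to males that held a harem in the
study area — possibly only to those rutting during her oestrus window
and near her. rutsim provides that comparison end to end, for
researchers analysing individual-based pedigree + census data and for
anyone studying the statistical behaviour of such tests.

## What it computes

* **Pedigree core** — kinship by the tabular method in compiled code
  (K(i,i) = (1 + K(f,m))/2; K(i,j) = (K(f,j) + K(m,j))/2), additive
  relatedness r = 2K, Wright's inbreeding f = K(father, mother),
  full-sibship sizes, matriline assignment.
* **Census handling** — conception dates backdated 235 days from
  birth, 11-day oestrus windows, annual candidate females and males,
  scheme-specific eligible-male sets.
* **Six null schemes** — `RANDOM`, `TEMPORAL`, `SPATIAL_500`,
  `SPATIAL_100`, and the 100-m scheme with sampling weighted by
  age-predicted (`AGE_CORRECTED`) or identity-predicted
  (`BS_CORRECTED`) annual breeding success; 1000-replicate ensembles,
  mothers fixed, sires re-drawn with replacement.
* **Ten pedigree statistics** — re-mating percentages of pairs,
  females and males (with mating-opportunity denominators), mean
  full-sibship size, mate-diversity and intralineage ratios, mean
  pairwise relatedness, and three inbreeding summaries — computed
  identically on observed and simulated pedigrees.
* **Inference** — one-tailed Z tests against each simulation envelope
  with family-wise Bonferroni thresholds (z = (obs − mean)/SD).
* **Male spatial structure** — lifetime mean rut locations, a
  relatedness-on-distance slope with additive per-male effects removed,
  and an exact-level location-permutation test.
* **Synthetic studies** — a generator with tunable mate fidelity φ,
  harem monopolisation κ, male natal-site philopatry and site
  fidelity, producing individuals/census/calvings/pedigree tables plus
  a per-conception truth log.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(rutsim)

cfg <- generator_config(n_years = 14L, n_founder_females = 30L,
                        n_founder_males = 14L, grid_cells = c(24L, 15L))
study <- generate_study(cfg, seed = 42)
study
#> Synthetic mating study: 215 individuals, 143 calvings, 5744 census records
#>   years: 1971 - 1984  sire model: behavioural  seed: 42

obs <- stat_block(study$individuals, study$calvings, study$census)
dplyr::select(obs, pct_pairs_remating, mean_full_sibship,
              intralineage_ratio, mean_relatedness)
#> # A tibble: 1 × 4
#>   pct_pairs_remating mean_full_sibship intralineage_ratio mean_relatedness
#>                <dbl>             <dbl>              <dbl>            <dbl>
#> 1               47.1              1.43              0.912           0.0232

ens <- lapply(c("RANDOM", "SPATIAL_100"), \(s)
  run_ensemble(study$individuals, study$calvings, study$census, s,
               n_replicates = 1000, seed = 1))
names(ens) <- c("RANDOM", "SPATIAL_100")
cmp <- compare_schemes(obs, ens)
dplyr::filter(cmp, statistic == "pct_pairs_remating") |>
  dplyr::select(scheme, observed, sim_mean, sim_sd, z, p_one_tailed)
#> # A tibble: 2 × 6
#>   scheme      observed sim_mean sim_sd     z p_one_tailed
#>   <chr>          <dbl>    <dbl>  <dbl> <dbl>        <dbl>
#> 1 RANDOM          47.1     6.51   2.36 17.2      1.96e-66
#> 2 SPATIAL_100     47.1    37.0    3.31  3.05     1.14e- 3
```

47.1% of pairs with a multi-year mating opportunity re-mated — the
generator was run with fidelity φ = 0.3 and strong spatial structure.
Under fully random mating only ~6.5% would re-mate (z = 17.2); even a
null constrained to males rutting within 100 m of the dam during her
window expects ~37%, still exceeded (z = 3.05). The gap that survives
the strictest null is the signature of true mate fidelity.

```r
K <- kinship_matrix(study$individuals)
loc <- male_rut_locations(study$census, study$individuals)
fit <- fit_relatedness_distance(male_pairwise_table(K, loc),
                                n_permutations = 999, seed = 2)
fit
#> Relatedness-distance permutation test
#>   slope: -1.1e-05 relatedness per metre (58 males, 1653 pairs)
#>   permutation p: 0.003 (999 permutations)
```

Related males rut nearer one another than expected (negative slope,
permutation p = 0.003) — the generator's male natal-site philopatry,
recovered by the pipeline.

A thin command-line wrapper is installed as `exec/rutsim`
(`generate`, `stats`, `simulate`, `compare`, `spatial` subcommands)
for shell pipelines over the CSV interchange formats.

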