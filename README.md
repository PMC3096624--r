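# gmycdelim

Single-locus species delimitation on ultrametric gene trees with the
general mixed Yule-coalescent (GMYC) model, plus the surrounding
DNA-taxonomy workflow: haplotype collapsing, alignment variation
statistics, topotype-based naming of the delimited entities, and
congruence checks against a second locus. Simulators generate trees and
alignments under the model itself, so the whole pipeline can be
validated at desk scale without any external data.

The intended user is a molecular taxonomist with a clock-constrained
gene tree (e.g. a BEAST maximum clade credibility tree of collapsed
mtDNA haplotypes) who wants putative species with likelihood support,
names anchored to type material, and an independent-locus sanity check.

## The model

An ultrametric tree of `n` sequences has `n - 1` branching events at
heights `t_1 > t_2 > ... > t_{n-1}` (heights measured from the tips,
tips at 0). The GMYC model places a threshold `T` on the tree: nodes
older than `T` are between-species (Yule) diversification events, nodes
younger than `T` are within-species coalescent events. Each inter-event
interval of duration `x_i` contributes

    log b_i - b_i * x_i,
    b_i = lambda1 * n_div,i ^ p1  +  lambda2 * sum_j ( n_ij (n_ij - 1) ) ^ p2

where `n_div,i` is the number of between-species lineages (frozen at
the number of delimited entities below the threshold), `n_ij` the
number of lineages of cluster `j`, `lambda1`/`lambda2` the speciation
and coalescent rates, and `p1`/`p2` rate-scaling exponents. The null
model is a single coalescent for the whole tree
(`b_i = lambda * (n_i (n_i - 1))^p`), which the mixed model nests
exactly. The threshold is profiled over all candidate positions
(midpoints between consecutive branching times plus the two extremes);
`2 (logL_mixed - logL_null)` is referred to a chi-square with 3 df.
Each lineage crossing the winning threshold roots one putative species:
a *cluster* (two or more tips) or a *singleton*. A multiple-threshold
variant hill-climbs from the single-threshold solution, moving each
cluster boundary one node rootward or tipward until no move improves
the likelihood.

## Worked example

Simulate 5 species with 6 samples each under a 300-fold rate separation
and fit the single-threshold model:

```r
library(gmycdelim)
sim <- simulate_mixed_tree(k = 5, lambda1 = 1, n_j = 6, lambda2 = 300,
                           seed = 11)
fit <- fit_single_threshold(sim$tree)
fit
#> GMYC fit (single-threshold)
#>   entities: 4 (4 clusters + 0 singletons)
#>   threshold T: 0.632925 (height from tips)
#>   logL mixed: 214.5868   logL null: 193.5906
#>   LR vs null: 41.993 (df = 3, p = 4.027e-09)
```

The mixed model beats the single-coalescent null decisively
(LR = 42.0 on 3 df): the tree really does contain a speciation-to-
coalescence transition. Four entities are delimited; under this seed
two true species are lumped into one cluster, which the naming stage
makes visible — an entity holding the complete topotype sets of two
nominal species receives a compound name:

```r
md <- read_metadata(write_simulation_tables(sim$truth, tempdir())[["metadata"]])
named <- name_species(fit$assignment, md)
data.frame(entity = names(named$entities), name = unname(named$name),
           size = lengths(named$entities))
#>   entity    name size
#> 1      1     sp1    6
#> 2      2 sp4+sp5   12
#> 3      3     sp3    6
#> 4      4     sp2    6
```

`fit$profile` holds the per-candidate likelihood profile (for a
lineage-through-time plot with the confidence band `fit$conf_set`), and
`fit_multiple_threshold(sim$tree, start = fit)` refines the
delimitation with per-lineage thresholds. `run_pipeline(run_config(...))`
(or the `gmyc_cli()` subcommands `simulate`, `fit`, `fit-multi`,
`collapse`, `stats`, `name`, `congruence`, `pipeline`) wires every
stage together and writes TSVs with provenance headers.

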