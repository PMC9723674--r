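# ecoassembly

Null-model inference of microbial community assembly processes.

Microbial ecologists routinely ask *why* two soil communities differ: was
the difference produced by deterministic environmental filtering
(**selection**), by movement of organisms between sites (**dispersal**),
or by stochastic demographic change (**drift**)? `ecoassembly` answers
this per pair of samples from an OTU table and a phylogeny, using the
two-step null-model framework standard in microbiome ecology, and then
asks *what drives* the selection it finds by partitioning the variation
of the phylogenetic-turnover matrix between soil chemistry and
vegetation composition. It is written for microbial ecologists analysing
amplicon data sets (16S, ITS) across environmental or land-use
gradients.

## The statistics at the core

**βMNTD / βNTI.** Abundance-weighted beta mean nearest taxon distance
between samples A and B,

    βMNTD = ½ [ Σ_{i∈A} f_i^A · min_{j∈B} D_ij  +  Σ_{j∈B} f_j^B · min_{i∈A} D_ij ],

with `f` relative abundances and `D` patristic distances, is standardized
against a taxa-shuffle null (tip labels permuted across the whole tree,
999 replicates) to give the beta nearest taxon index

    βNTI = (βMNTD_obs − mean_null) / sd_null.

`βNTI < −2` → homogeneous selection; `βNTI > 2` → variable selection;
`|βNTI| ≤ 2` → neutral processes.

**RC_Bray.** For phylogenetically null pairs, Raup–Crick on Bray–Curtis:
each null replicate independently reassembles both samples from the
regional pool (richness drawn by occupancy, counts allocated by
dataset-wide relative abundance) and the observed dissimilarity is ranked
within the null, rescaled to [−1, 1]. `RC > 0.95` → dispersal limitation
(+ drift); `RC < −0.95` → homogenizing dispersal; otherwise drift alone.

**Group comparisons.** Process proportions by history class
(reference vs. disturbed) with two-proportion Z-tests, and Kruskal–Wallis
on βNTI distributions.

**Drivers of selection.** Principal coordinates of the βNTI matrix are
regressed on predictor sets by distance-based RDA; two-set variation
partitioning reports adjusted-R² fractions unique to soil, unique to
vegetation, shared, and residual, with permutation tests (the shared
fraction cannot be tested).

**Assumption check.** A Mantel correlogram tests whether closely related
OTUs have similar abundance-weighted niche values — the phylogenetic
conservatism that justifies reading βNTI as selection.

A synthetic-data generator (`simulate_dataset()`) emulates a
paired-watershed design (8 watersheds × 6 plots in 4 reference/disturbed
pairs) with known per-watershed assembly regimes, so the whole pipeline
can be validated against ground truth. See the methods vignette
(`vignettes/community-assembly-null-models.Rmd`) for the models,
parameter choices, and limitations.

## Worked example

Generate a synthetic paired-watershed data set, compute both turnover
statistics at the default 999 null replicates, classify every sample
pair, and compare history classes:

```r
library(ecoassembly)

ds <- simulate_dataset(seed = 42)             # 48 samples x 200 OTUs
b  <- bnti(ds$comm, ds$tree, n_reps = 999, seed = 1)
r  <- rc_bray(ds$comm,       n_reps = 999, seed = 2)

calls <- classify_processes(b$bnti, r$rc)
props <- group_proportions(calls, ds$metadata)
subset(props, count > 0)
#>        group                    process count n_pairs proportion
#> 1  disturbed      homogeneous_selection    20     276      0.072
#> 2  disturbed         variable_selection   110     276      0.399
#> 3  disturbed     homogenizing_dispersal    19     276      0.069
#> 4  disturbed dispersal_limitation_drift    30     276      0.109
#> 5  disturbed                      drift    97     276      0.351
#> 6  reference      homogeneous_selection     7     276      0.025
#> 7  reference         variable_selection    15     276      0.054
#> 8  reference     homogenizing_dispersal    12     276      0.043
#> 9  reference dispersal_limitation_drift   151     276      0.547
#> 10 reference                      drift    91     276      0.330

comp <- compare_proportions(props)
subset(comp, process == "selection_overall")
#>             process prop1  prop2    z        p
#> 6 selection_overall 0.471 0.0797 10.3 7.77e-25
```

Selection dominates the disturbed soils (47% of pairs vs. 8% in the
reference soils; pooled-selection Z-test p ≈ 8e-25) while
dispersal limitation dominates the reference soils (55% of pairs) —
exactly the contrast the generator's default regime map encodes
(disturbed watersheds assemble under selection, reference watersheds
under dispersal limitation or drift).

Partitioning the βNTI variation between the simulated soil-chemistry and
vegetation predictor sets:

```r
m <- b$bnti; diag(m) <- 0; m[!is.finite(m)] <- 0
vp <- two_set_varpart(bnti_to_response(m), ds$soil, ds$vegetation,
                      n_perm = 999, seed = 3)
vp
#> Two-set variation partitioning of betaNTI (adjusted R2)
#>          partition adj_r2     p significant_variables
#>               Soil  0.097 0.012
#>         Vegetation  0.090 0.020          L_tulipifera
#>  Soil + Vegetation  0.110 0.033          L_tulipifera
#>  Soil | Vegetation  0.020 0.243
#>  Vegetation | Soil  0.013 0.340          L_tulipifera
#>  Soil ∩ Vegetation  0.076    NA
#>          Residuals  0.890    NA
#> (the shared fraction cannot be tested)
```

Both predictor sets explain significant βNTI variation marginally
(p ≈ 0.01–0.02), but almost all of it is shared (0.076 of 0.110): in
this simulation both sets are read-outs of the same disturbance
contrast, so neither retains a significant unique fraction once the
other is partialled out.

`run_pipeline()` chains all of the above (simulate/load → signal check →
βNTI → RC_Bray → classify → varpart) from one seeded configuration and
writes every stage as TSV plus a run manifest; `inst/scripts/ecoassembly`
exposes the same stages as shell subcommands.

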