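# camnet

Community assembly null models and compositional association networks
for microbiome count data.

Wild herbivores that feed on chemically defended plants (for example
moose browsing balsam fir, rich in plant secondary compounds) carry gut
microbial communities shaped by diet, physiology and geography. A
recurring analysis pattern in this field asks two questions of a
sample × taxon count table, a phylogeny and per-animal covariates:

1. **Which ecological processes assemble the communities?** For each
   sample pair, βMNTD (between-community mean nearest taxon distance) is
   compared with a tip-shuffled null to give
   βNTI = (βMNTD<sub>obs</sub> − μ<sub>null</sub>)/σ<sub>null</sub>, and
   Bray–Curtis dissimilarity with a richness- and abundance-constrained
   null to give RC<sub>bray</sub> ∈ [−1, 1]. The Stegen decision rule
   then labels the pair: βNTI > 2 variable selection, βNTI < −2
   homogeneous selection; otherwise RC > 0.95 dispersal limitation,
   RC < −0.95 homogenizing dispersal, |RC| ≤ 0.95 drift/undominated.
   Per-stratum fractions of these labels summarize how assembly shifts
   with age, region, diet or physiological status.
2. **How are taxa associated?** SparCC infers basis (absolute-abundance)
   correlations from compositional counts via log-ratio variances;
   permutation tables give edge significance, and graph topology
   (degree, betweenness, eigenvector centrality, fast-greedy modularity,
   hubs) describes the resulting networks per stratum.

Around this core the package provides genus agglomeration and the
standard prevalence/abundance filters, Faith's PD, generalized UniFrac
(exponent α interpolating unweighted and weighted UniFrac), PERMANOVA
with marginal (type II-like) sums of squares, host-physiology statistics
(Pearson tests with IQR outlier removal, Shannon diet diversity, high/low
splits including the UN:C > 3.5 catabolism rule), a file-based
`run_pipeline()` orchestrator, and a synthetic-data generator that
produces phylogenies, Brownian niche traits, count tables assembled under
each of the five processes, compositional counts with planted basis
correlations, and host metadata with a target correlation structure —
ground truth for every downstream stage.

## Worked example

Simulate an island-structured metacommunity, partition its assembly
processes, and summarize:

```r
library(camnet)

cfg   <- assembly_scenario("dispersal_limitation", seed = 1)
d     <- simulate_assembly_dataset(cfg)          # tree + traits + counts
th    <- assembly_thresholds(n_null = 199, seed = 1)
pairs <- assembly_analysis(d$table, d$tree, th)  # per-pair bMNTD/bNTI/RC
glance(pairs)
#> # A tibble: 1 × 4
#>   n_pairs n_classified modal_process     drift_fraction
#>     <int>        <int> <chr>                      <dbl>
#> 1     190          188 drift_undominated          0.622

summarize_assembly(pairs)
#> # A tibble: 5 × 5
#>   group process                fraction n_pairs n_unclassifiable
#>   <chr> <chr>                     <dbl>   <int>            <int>
#> 1 all   variable_selection       0.0372     188                2
#> 2 all   homogeneous_selection    0          188                2
#> 3 all   dispersal_limitation     0.277      188                2
#> 4 all   homogenizing_dispersal   0.0638     188                2
#> 5 all   drift_undominated        0.622      188                2
```

Dispersal limitation rises to 28% of classified pairs — far above its
level under pure drift (a few percent) — while drift/undominated stays
modal, the signature this scenario is built to produce. Two pairs were
flagged unclassifiable (degenerate βMNTD nulls) and excluded from the
denominator. `autoplot(summarize_assembly(pairs))` draws the stacked
process bars.

Host statistics work the same way on metadata:

```r
md <- simulate_metadata(66, seed = 1)
pearson_test(md$fir, md$ga_c, remove_outliers = TRUE)
#> # A tibble: 1 × 5
#>       r t_stat    df   p_value n_used
#>   <dbl>  <dbl> <int>     <dbl>  <int>
#> 1 0.491   4.29    58 0.0000687     60
```

Six of 66 animals fell outside the Tukey fences and were removed before
the test; the remaining 60 show a positive fir–detoxification
correlation, as planted by the generator.

The file-based pipeline (`run_pipeline()`, or
`inst/scripts/camnet.R` from a shell) reads table/tree/taxonomy/metadata
TSVs, applies the filter cascade, computes Faith's PD, generalized
UniFrac and PERMANOVA globally, and per stratifying factor writes
assembly summaries, SparCC edge lists and node topology under an output
directory with a JSON manifest; reruns with the same seed are
byte-identical.

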