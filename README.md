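# haplodiv

Temporal haplotype diversity analysis for ancient and modern mitochondrial
cohorts.

## The problem

Zooarchaeological genetics routinely produces datasets with a few dozen
ancient mitochondrial sequences next to hundreds of modern ones — e.g. a
300-bp hypervariable-I control-region alignment with 41 ancient and 808
modern South American camelids. Asking whether the ancient population was
*more diverse* (whether maternal lineages have been lost since) cannot be
answered by comparing raw statistics: the larger modern cohort mechanically
observes more haplotypes and more segregating sites. haplodiv answers the
question conditional on sample size.

## What it computes

* **Haplotype calling** under explicit missing-data policies
  (`complete_deletion` masks every column with a gap/`N`; `strict` keeps them
  as literal states), with per-stratum counts.
* **Diversity statistics**: Nei's unbiased haplotype diversity
  `Hd = n/(n-1) * (1 - Σ p_i²)` (equal to the probability that two randomly
  drawn samples differ), segregating sites `S`, and nucleotide diversity `π`
  as the mean per-pair per-site difference with pairwise deletion of gap/`N`
  sites.
* **The bootstrap-rarefaction test** (`temporal_diversity_test()`): resample
  the modern cohort with replacement at the ancient size `m` (default 10,000
  replicates), compute `Hd` and `S` per replicate, and report the midrank
  percentile of the observed ancient values in that null. Percentiles near
  100 are the signature of lost maternal lineages. Partitions (all samples;
  large vs *Lama*; small vs *Vicugna*) are configurable.
* **Haplotype networks**: a minimum spanning network (at `ε = 0` exactly the
  union of all minimum spanning trees of the Hamming distance matrix) and a
  two-layer temporal network with exact shared/private haplotype accounting;
  GraphML and TSV export.
* **Osteometrics**: deterministic two-means size-group discrimination on the
  log product of paired bone measurements (astragalus Bd × GLm, phalanx
  BFp × Dp) and exact/Monte-Carlo permutation tests of group separation.
* **A synthetic-data generator** (haplotype pool with configurable lineage
  loss, terminal C→T/G→A deamination artifacts and end-biased missingness)
  so the whole pipeline is testable without sequence downloads.

## Worked example

Simulate a pool of 40 haplotypes on a 300-bp locus, draw the study-sized
cohorts (41 ancient / 808 modern) with 70% of lineages lost from the modern
stratum, and run the comparison:

```r
library(haplodiv)
pool <- simulate_pool(K = 40, L = 300, mu = 1.5, seed = 11)
aset <- sample_cohorts(pool, n_ancient = 41, n_modern = 808, loss = 0.7,
                       seed = 12)
tc <- temporal_diversity_test(aset, n_reps = 2000, seed = 13)
summary(tc)
#>     partition  m n_reps Hd_observed Hd_percentile S_observed S_percentile
#> all       all 41   2000   0.9170732           100         19          100
```

The ancient cohort's haplotype diversity (0.917) and segregating sites (19)
both sit at the 100th percentile of 2,000 size-matched modern resamples:
no random draw of 41 modern sequences is as diverse as the ancient sample —
the simulated lineage loss is detected. The per-stratum summaries show why
the raw comparison would have misled: the modern cohort reports *more*
segregating sites (28 vs 19) purely through its 20-fold larger sample size.

```r
diversity_summary(subset(aset, stratum = "ancient"))
#> diversity_summary (policy=complete_deletion)
#>   n = 41   h = 17   Hd = 0.9171   S = 19   pi = 0.02422
diversity_summary(subset(aset, stratum = "modern"))
#> diversity_summary (policy=complete_deletion)
#>   n = 808   h = 12   Hd = 0.8363   S = 28   pi = 0.01930

build_temporal(call_haplotypes(aset))
#> temporal_network: 20 haplotypes (17 ancient-layer, 8 modern-layer)
#>   shared = 5, private ancient = 12, private modern = 3
```

Twelve of 20 haplotypes are private to the ancient layer — the haplotype-level
view of the same loss. The osteometric side:

```r
md <- simulate_morphometrics(n_big = 20, n_small = 20, seed = 14)
gr <- test_group_difference(md, classify_size_groups(md), seed = 15)
gr
#> morpho_grouping (astragalus): big = 20, small = 20
#>   monte_carlo permutation tests (10000 relabelings):
#>     x        p = 0.0001
#>     y        p = 0.0001
#>     product  p = 0.0001
```

A three-command pipeline (`pipeline_simulate()`, `pipeline_analyze()`,
`pipeline_report()`) orchestrates the stages from JSON configs with one
global seed; `inst/cli/haplodiv.R` is a thin shell wrapper over it. See the
vignette (`vignettes/temporal-diversity.Rmd`) for the model, the numerical
choices and the calibration/power experiments.

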