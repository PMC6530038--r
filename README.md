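# lahyper

Module-level hypergraphs of dynamic gene correlation via Liquid Association.

## The problem

Many gene-pair correlations are *dynamic*: the correlation between two genes
switches between positive, negative and absent depending on an underlying
cellular condition that is usually not recorded in the data. When a third
gene tracks that condition, the three genes form a ternary interaction. For
expression rows normalised by the normal score (rank-based inverse normal)
transform, the Liquid Association (LA) statistic of a triplet (X, Y, Z)
reduces to the expected triple product,

    λ = E(XYZ),  estimated by  λ̂ = (1/m) Σᵢ XᵢYᵢZᵢ,

which is symmetric in the three genes and measures how the (X, Y)
correlation moves with the level of the "scouting" gene Z. The estimate is
valid as a dynamic-correlation measure when all three pairwise correlations
are near zero, so the scan only admits triplets whose pairs fall strictly
inside the interval (μ − cσ, μ + cσ) of the empirical pairwise-correlation
distribution.

Because a transcriptome holds on the order of 10¹² triplets, `lahyper`
aggregates: it scans eligible triplets gene by gene, selects the significant
ones with a permutation-based local false discovery rate

    fdr(λ) = f̂₀(λ) / f̂(λ),

(the ratio of the estimated null score density to the observed score
density, thresholded at a user target), groups genes into modules, and lifts
the selected gene triplets to module labels. The result is a weighted
3-uniform hypergraph: vertices are modules, a hyperedge joins three modules
(repeats allowed, so self-loops exist), its weight is the fold change of the
observed gene-triplet count over the count expected if triplets were placed
at random. Modules come either from a user gene-set collection (GMT,
"supervised") or from clustering genes on their triplet co-involvement
profiles (the pair count matrix A, its row correlation C, distance 1 − C,
average-linkage clustering with an adaptive minimum-size tree cut,
"unsupervised").

## Worked example

Plant two dynamic-correlation triplets (conditional correlation
0.8·sign(z)) among 50 genes and 150 samples, run the unsupervised
workflow, and compare against the ground truth:

```r
library(lahyper)

specs <- list(planted_triplet_spec(1, 2, 3, 0.8, "sign"),
              planted_triplet_spec(4, 5, 6, 0.8, "sign"))
ds  <- generate_planted_dataset(50, 150, specs, seed = 42)
cfg <- la_config(ds$matrix, mode = "unsupervised", c = 3, fdr_target = 0.1,
                 min_fold_change = 0, min_cluster_size = 4, seed = 42,
                 out_dir = "demo_out")
res <- run_pipeline(cfg)
#> preprocess: 50 genes x 150 samples
#> screen: mu=0.0013 sigma=0.0836 interval=(-0.2495, 0.2521), 99.7% of pairs eligible
#> selection: 58224 raw per-scout records, 2 canonical triplets at fdr 0.1
#> grouping (unsupervised): 2 modules, 6 genes assigned, 0 dropped
#> hypergraph: 2 lifted triples (0 gene triplets discarded)

res$selection$triplets
#>   i j k       lam scout
#> 1 1 2 3 0.5053616     1
#> 2 4 5 6 0.6141470     4

planted_recovery_report(res$selection$triplets, ds$truth)
#> $recall        1
#> $empirical_fdr 0
```

Both planted triplets are recovered (their scores, ≈ 0.51 and 0.61, sit
near the population value 0.8·√(2/π) ≈ 0.64 less rank-transform
attenuation) and nothing else is selected. The output directory holds
`triplets.tsv`, `modules.tsv`, `hyperedges.tsv`, `graph.graphml` (the
clique expansion for generic viewers), `manifest.json` and `run.log`.

A command-line wrapper over the same pipeline lives at
`inst/cli/lahyper.R`:

```sh
Rscript inst/cli/lahyper.R --expr matrix.tsv --mode unsupervised \
    --c 0.5 --fdr 0.01 --seed 1 --out results/
```

For screen-width guidance, `correlation_sampling_sd(m)` gives the null
sampling sd of a pairwise correlation (0.046 at m = 474, 0.114 at m = 77)
and `suggest_screen_constant()` the `c` that matches the null 95% CI.

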