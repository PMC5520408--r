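# homoplasr

Phylogenetic clustering of parallel and divergent amino acid substitutions —
a test for changing single-position fitness landscapes (SPFLs).

## The problem

Amino acid preferences at a protein site change over evolutionary time,
through epistasis or environmental change. When they do, a variant that is
fit in one clade is likely to be unfit in a distantly related clade, so
*parallel* substitutions (the same ancestral amino acid B giving rise to the
same derived amino acid A, B→A and B→A, on phylogenetically independent
branches) should sit closer together on the tree than *divergent*
substitutions from the same ancestral state (B→A and B→X, X ≠ A).
`homoplasr` measures exactly that, for deep protein alignments on rooted
trees with branch lengths.

Convergent substitutions (same derived, different ancestral states) are
deliberately excluded — pooling them with parallel ones produces spurious
clustering through mutational and genetic-code biases alone.

## The statistic

For every homoplasy-informative site (≥1 parallel and ≥1 divergent pair from
the same ancestral amino acid B):

1. ancestral states are reconstructed by marginal maximum likelihood
   (pruning algorithm, empirical exchangeability matrix + equilibrium
   frequencies, discrete-gamma rate heterogeneity, empirical-Bayes over rate
   categories) and substitutions mapped onto edges where the MAP state
   changes;
2. all unordered pairs of substitutions with the same B on independent
   edges (neither ancestral to the other) are classified parallel/divergent,
   each with its **mid-edge distance** — the sum of path lengths from the two
   edge centers to the pair's last common ancestor, in substitutions/site;
3. per (site, B), `min(N_paral, N_diverg)` pairs of each kind are drawn
   (matched subsampling), neutralizing biases from pooling sites and
   ancestral states with different properties;
4. the pooled pairs give the **P/D ratio** per log2-distance bin (the
   O-ring-style curve), the **mean distance ratio**
   `mean(d_parallel)/mean(d_divergent)`, and the **crossing distance** where
   P/D first reaches 1; all with 95% CIs from bootstrapping sites
   (re-running the subsampling inside each replicate).

Under a time-homogeneous null, P/D ≈ 1 everywhere and the mean distance
ratio ≈ 1; under SPFL change, P/D starts above 1 and declines with distance,
and the ratio drops below 1.

The package also contains an event-level (Gillespie) simulator with full
truth logging: a null mode, a clade-specific-matrix mode, and a
`spfl_switch` positive control in which each site's set of k permitted amino
acids drifts along branches (one member swapped at rate λ per unit branch
length), plus the paper-style filters (gap fraction, genetic-code
accessibility of (B, A) pairs under NCBI translation tables, high-confidence
pairs by bootstrap support and posterior-1 states).

## Worked example

Simulate a positive control (drifting fitness landscapes) and ask the
pipeline whether it sees the clustering:

```r
library(homoplasr)

tree  <- random_calibration_tree(n_leaves = 100, total_length = 15, seed = 7)
model <- default_rate_model(alpha = 0.5, K = 4)
sim   <- simulate_evolution(sim_config(tree, model, n_sites = 150,
                                       mode = "spfl_switch", lambda = 5,
                                       k_permitted = 5, seed = 7))
report <- run_pipeline(tree, sim$aln, alpha = 0.5, gamma_categories = 4,
                       bootstrap_reps = 200, seed = 7)
report
#> P/D homoplasy-clustering report
#>   sites: 150 total, 150 analyzed, 140 homoplasy-informative
#>   substitutions: 2362; pairs: 8856
#>   mean distance ratio: 0.949 [0.902, 0.970]
#>   crossing distance: undefined (curve starts below 1)
report$curve[, c("bin_lo", "bin_hi", "pd", "ci_lo", "ci_hi")]
#>    bin_lo bin_hi        pd      ci_lo     ci_hi
#> 1: 0.0625  0.125 0.2000000 0.04535985 1.1281250
#> 2: 0.1250  0.250 1.1627907 0.89349882 1.9164286
#> 3: 0.2500  0.500 1.2928177 1.10951429 1.5823729
#> 4: 0.5000  1.000 0.9930915 0.89119665 1.0370890
#> 5: 1.0000  2.000 0.7278912 0.57624797 0.8758478
```

Reading the output: parallel pairs are on average 5% closer than matched
divergent pairs (ratio 0.949, CI excluding 1), and the P/D curve is elevated
at intermediate distances (1.29, CI > 1 in the 0.25–0.5 bin) and falls below
1 at large distances (0.73) — the clustering signature of landscape change.
The depressed smallest bin is a known artifact of MAP reconstruction
(parallel changes on adjacent short branches merge into their parent edge);
see the methods vignette. On null-simulated data the same pipeline returns a
ratio CI covering 1 and a flat curve.

## Command line

```sh
Rscript inst/cli/homoplasr.R simulate    --tree tree.nwk --out simdir --mode null --sites 300 --seed 1
Rscript inst/cli/homoplasr.R reconstruct --tree tree.nwk --alignment aln.fasta --out states.tsv
Rscript inst/cli/homoplasr.R analyze     --config run.cfg
```

`run.cfg` is flat `key = value` (`tree`, `alignment`, optional `states`,
`gap_threshold`, `accessibility`, `code_table`, `high_confidence`,
`bootstrap_reps`, `seed`, `out_dir`, ...). `analyze` writes `pairs.tsv`,
`curve.tsv`, `scalars.tsv` and a `run_log.txt` echoing every filter-stage
count; exit code 2 flags a clean empty result (no informative sites).

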