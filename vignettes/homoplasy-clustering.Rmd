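---
title: "Measuring fitness-landscape change from the clustering of homoplasies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fitness-landscape change from the clustering of homoplasies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

A single-position fitness landscape (SPFL) is the vector of fitnesses of the
20 amino acids at one protein site. If SPFLs drift over time, the rate of a
specific substitution B→A varies across the tree: clades where A is
currently fit accumulate repeated B→A events, while clades where A is unfit
do not. The observable consequence is that *parallel* substitution pairs
(B→A twice, on branches neither of which is ancestral to the other) are
phylogenetically closer to each other than *divergent* pairs (B→A with B→X,
X ≠ A) from the same ancestral state.

`homoplasr` turns this into a calibrated statistic:

* **Distance between two substitutions** is the mid-edge distance: half of
  each carrying edge plus the path lengths from the edges' parent nodes to
  the pair's last common ancestor, in substitutions/site. The substitution
  is localized only to an edge, so its expected position is the edge center;
  using centers keeps the metric symmetric and additive.
* **Independence**: a pair is only counted when neither edge lies on the
  root path of the other — two changes on one lineage are a single
  evolutionary trajectory, not repeated evolution.
* **Matched subsampling**: per site and ancestral amino acid B, we keep
  `min(N_paral, N_diverg)` pairs of each kind, drawn uniformly without
  replacement. This is the critical control: sites (and ancestral states
  within sites) differ in conservation, clade occupancy and amino acid
  promiscuity, and pooling them unmatched can manufacture apparent
  clustering with no SPFL change at all. After matching, parallel and
  divergent counts are equal within every (site, B) stratum, so only the
  *distance distributions* differ.
* **Statistics**: the per-log2-bin parallel/divergent count ratio (P/D
  curve, an O-ring-type statistic), the mean distance ratio
  `mean(d_par)/mean(d_div)`, and the distance where the P/D point-estimate
  curve first reaches 1 (log-linear interpolation between bin midpoints).
  Uncertainty comes from bootstrapping *sites* — the exchangeable unit —
  with the entire subsampling procedure redone inside each replicate.

Ancestral states are reconstructed by marginal maximum likelihood under a
reversible empirical model: `Q[i,j] = S[i,j]·π[j]`, scaled to one expected
substitution per site per unit branch length, with discrete-gamma rate
variation between sites (equal-probability categories, category means,
renormalized to mean 1). Per site, rate categories are integrated out with
their posterior weights (empirical Bayes); the per-site rate estimate `r_s`
is the posterior-mean category rate. One substitution per (edge, site) is
representable — a MAP-to-MAP state change — exactly as in codeml-style
reconstructions; multiple hits within an edge are invisible by construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | gamma shape; 0.5 is typical for mitochondrial proteins (strong site-to-site rate variation) |
| `gamma_categories` (K) | 4 | discrete-gamma resolution; the conventional codeml/RAxML default |
| exchangeabilities | mtREV24 | empirical mitochondrial matrix; user-replaceable via a PAML-style file |
| frequencies | alignment counts ("+F") | floored at 1e-4 and renormalized |
| `gap_threshold` | 0.01 | analyze columns with <1% gaps (strict) |
| `min_divergent` | 5 | a distance bin with fewer divergent pairs is flagged unstable |
| bins | integer log2 edges | covering the observed distance range; zero distances fall in the smallest bin |
| `bootstrap_reps` | 1000 | site bootstrap replicates; 95% percentile CIs |
| `support_min`, `posterior_min` | 100, 1.0 | high-confidence pair filter: ≥1 node between the edge centers with full support, and all four node states reconstructed with posterior 1 |
| `lambda`, `k_permitted` | —, 5 | positive-control landscape dynamics (below) |

Distances may optionally be multiplied by `r_s` (`normalize_rates = TRUE`)
to work in site-specific expected substitutions.

## What the simulator emulates — and what it does not

`simulate_evolution()` is an event-level (Gillespie) simulator: root states
are drawn from π, each site draws one gamma category for the whole tree (no
covarion), and states evolve edge by edge under `Q·r_s`, logging every true
event with its position. Event-level simulation is deliberate: the truth log
contains the multiple hits that MAP reconstruction cannot see, so
reconstruction biases can be measured rather than assumed.

* **null**: one matrix everywhere — the calibration world. Expected events
  per site equal tree length × site rate (the model is scaled to 1).
* **clade_matrices**: a different (e.g. jittered) matrix per clade, to show
  that clade-specific mutational biases alone do not bend the P/D curve.
* **spfl_switch**: the positive control. Each site carries a set of
  `k_permitted` allowed amino acids. At Poisson(λ·branch length) points one
  permitted member is swapped for one prohibited member, so the landscape
  *drifts* with correlation length ≈ k/λ along the tree. Substitutions into
  non-permitted states have rate zero; the total rate simply shrinks (no
  renormalization — we model constraint, not invented selection
  coefficients). If the current state is the member swapped out, the site
  jumps immediately to a uniformly chosen permitted state; these forced
  events are logged with a flag so analyses can include or exclude them.

A design note on the switch move. An earlier variant resampled the *entire*
permitted set at each switch point. That destroys the very signal the
control must produce: with small k most switches strand the current state,
so nearly all events become forced jumps whose targets come from freshly,
independently drawn sets — their target choices carry no spatial
correlation, and the P/D curve stays flat even when computed from the truth
log (we measured exactly this). The single-member swap preserves the
two-state permitted/prohibited character of landscape change while letting
the landscape decay gradually, which is what a per-variant switching process
implies. With λ = 5 and k = 5 the landscape turns over on roughly the same
time scale as amino acid substitution itself — the regime the analysis is
designed to detect.

λ is per unit branch length, *not* scaled by the site's gamma rate: the
landscape changes as a function of time, not of the site's own substitution
pace, so any P/D signal is attributable to heteropecilly (changed relative
rates) rather than heterotachy (changed overall rate).

Seeds: one master seed; each (site, edge) consumes its own substream derived
by stable integer hashing, so enlarging the alignment never perturbs the
realization of earlier sites.

What the simulator does **not** emulate: indels and alignment error (no gap
process — the gap filter is exercised with synthetic masks), codon-level
structure (amino acid alphabet only, so the accessibility filter tests
against real genetic codes but the simulant has no codon usage), tree
estimation error (the true tree is reused for reconstruction, as when a
fixed published phylogeny is used), and selection coefficients (permitted /
prohibited is binary). A green calibration therefore establishes the
statistic's behavior under the stated generative model — not robustness to
alignment or topology error.

## Numerical choices

* Transition probabilities by symmetric eigendecomposition of the
  reversible Q (exact, reused across edges/categories); tiny negative
  entries clipped and rows renormalized.
* Pruning with per-site column rescaling (log-scalers), so 200+ leaf trees
  are safe from underflow.
* MAP ties broken alphabetically by one-letter code — deterministic.
* A leaf with missing data ('-', 'X', '?') has uniform leaf posteriors; its
  MAP is reported as NA and its pendant edge contributes no substitutions at
  that site, rather than letting the tie-break fabricate an 'A'.
* Degenerate inputs: zero-length edges are allowed (edge center = node;
  mid-edge distance degenerates to patristic distance); a basal
  multifurcation is accepted as a rooted multifurcation with a warning;
  fractional support labels are rescaled to [0, 100] with a warning.
* The bootstrap CI is the 2.5/97.5 percentile interval; the crossing
  distance inside a replicate uses that replicate's curve, so its CI
  reflects binning noise too.
* A bin with zero divergent pairs has an undefined (NA) ratio and is never
  "stable"; crossing interpolation uses stable bins only.

## Design decisions that were genuinely open

* **"from any B codon"** in the accessibility filter is read as *every*
  codon of B having a single-nucleotide neighbor coding A (strict mode);
  the permissive *some*-codon mode is available for sensitivity analysis.
  The filter exists to remove codon-usage artifacts, which only works if
  accessibility does not depend on which codon a lineage uses. Default
  genetic code: vertebrate mitochondrial (table 2); tables 1 and 5 (and any
  other NCBI table) selectable.
* **K = 4** gamma categories by default; the reconstruction contract takes
  alpha and K as inputs rather than estimating them.
* **`r_s`** is the posterior-mean category rate (the standard marginal
  estimate).
* **Curve reporting**: the point-estimate curve comes from one subsample
  draw (seeded); the bootstrap median curve is reported alongside, and the
  two agree closely in practice.

## Known limitations

The dominant one is a *reconstruction* artifact at sibling-scale distances:
when a parallel pair sits on two short sibling edges, marginal MAP
reconstruction prefers to place a single substitution on the parent edge —
divergent pairs cannot merge this way — so the smallest distance bins are
selectively depleted of parallel pairs. On trees whose typical edge length
is a few hundredths of a substitution per site (the calibration world: 200
leaves, total length 20), the bins below ~0.1 are dominated by sibling
pairs and show P/D well below 1 even under the null. The package's own
evidence for this diagnosis: the identical statistics computed from the
simulator's truth log are flat at 1 in every stable bin, while the
pipeline's smallest bins are depressed in both null and positive-control
runs. Consequences: (a) the per-bin null-coverage check fails in the
smallest stable bins at desk scale, while the global mean-distance-ratio
calibration is clean; (b) in the positive control the declining P/D signal
is read from the curve's interior (the rise to its maximum and the decline
beyond it), not from the artifact-depressed first bin. On deep trees with
hundreds of substitutions per site of total length — the regime the method
is meant for — the sibling-pair fraction of small-distance bins is far
smaller, and published codeml-based analyses report only weak reconstruction
bias in simulations.

Other limitations: the mean distance ratio at desk scale (~0.95 under
λ = 5, k = 5) is much closer to 1 than the ~0.8 reported on real deep
metazoan data; most pair mass sits at distances beyond the landscape
correlation length, diluting the mean — the binned curve is the more
sensitive instrument. Dense LCA tables are quadratic in node count (fine to
a few thousand leaves). The simulator's stationary state under spfl_switch
is only approximately π-restricted, since the landscape and state co-evolve.
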