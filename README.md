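# fibrildmd

Event-driven coarse-grained simulation and polymorph scoring of amyloid
peptide assembly.

Amyloid-beta oligomers adopt many competing fibrillar architectures —
U-shaped hairpins, S-shaped serpentines, beta-helical off-pathway
aggregates — and which of them forms depends on how many chains
aggregate together.  Studying that question in silico needs three
things: a dynamics engine fast enough to watch spontaneous assembly, a
peptide model coarse enough to make that affordable, and an automatic
way to tell the resulting structures apart.  `fibrildmd` provides all
three for R users:

* **Discontinuous molecular dynamics (DMD).**  All interactions are
  hard cores, square wells and hard bond walls, so dynamics reduces to
  an exactly solved sequence of collision events — no integrator, no
  time step, exact energy conservation between thermostat kicks.  The
  event loop is compiled (Rcpp) with an indexed event heap, neighbour
  lists, an Andersen-style ghost-collision thermostat, and explicit
  chirality walls that keep every residue in its L-isomer form.
* **A four-sphere-per-residue peptide model.**  Three united backbone
  beads (NH, CA, CO) plus one side-chain sphere per non-glycine
  residue; amino-acid-specific square wells (a 20 x 20 matrix in units
  of the hydrogen-bond energy `eps_HB`); directional backbone hydrogen
  bonding with single occupancy and auxiliary geometry gates; an
  enhanced D23-K28 salt bridge and a parallel-preference bias, both
  switchable.  Every number lives in versioned YAML configuration
  tables.
* **A structure-analysis layer.**  The similarity statistic correlates
  chain-averaged intra-peptide CA distance profiles (long-range pairs,
  `j - i >= 5`) between a structure and a reference:

  `r = cov(d_struct, d_ref) / (sd(d_struct) sd(d_ref))`

  Classification against a library of idealized conformer templates (U,
  S1-S3, D1-D2, beta-helix) assigns the best match above `r = 0.8`,
  detects hybrid aggregates, scores in-register stacking from the
  inter-chain hydrogen-bond registry, measures secondary-structure
  content, clusters chains into oligomers, and bins trajectory tails
  into population heat maps over (r, energy).

Everything is tidyverse-native: structures are bead tibbles, results
are tibbles or small S3 objects with `tidy()`/`glance()` methods and
`autoplot()` visualisations.

## A worked example

Simulate three chains of the amyloid-core fragment KLVFFAE in the 1 mM
box, cold enough to aggregate, and watch inter-chain hydrogen bonds
appear:

```r
library(fibrildmd)

tab <- default_forcefield()
box_length(3, 1e-3)
#> [1] 171

st <- make_random_config(3, 1e-3, seed = 1, sequence = "KLVFFAE",
                         first_residue = 16L, temperature = 0.08)
run <- dmd_advance(st, tab, n_collisions = 2e6, temperature = 0.08,
                   kick_rate = 0.003, seed = 9, observe_every = 2e5)
tail(run$observables[, c("collisions", "pe", "n_hb_inter",
                         "largest_cluster")], 3)
#> # A tibble: 3 x 4
#>   collisions     pe n_hb_inter largest_cluster
#>        <dbl>  <dbl>      <dbl>           <dbl>
#> 1    1600000  -9.70          0               1
#> 2    1800000 -10.7           0               1
#> 3    2000000 -10.5           0               1
```

The chains have collapsed into compact coils (interaction energy down
to about -10 eps_HB) and are still diffusing toward each other across
the dilute box; the longer cold runs in the acceptance script carry
the story through encounter, sticking, inter-chain hydrogen-bond
growth and trimer formation.  Score and classify a structure:

```r
u <- make_fibril("U", 8, jitter = 0.3, seed = 7)
lab <- classify_structure(u, reference_library())
glance(lab)
#> # A tibble: 1 x 5
#>   class in_register best_r energy largest_cluster
#>   <chr> <lgl>        <dbl>  <dbl>           <dbl>
#> 1 U     TRUE          1.00     NA               8
```

The eight-chain U-shape stack survives 0.3 Å of coordinate noise with a
profile similarity of 1.00 to its reference and an in-register
hydrogen-bond ladder.  A command-line wrapper
(`inst/cli/fibrildmd.R`) exposes `simulate`, `fixtures`, `score`,
`classify`, `heatmap` and `boxcalc` subcommands over the same functions.

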