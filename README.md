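# lakeassembly

Community assembly and compositional stability analysis for microbial
(protistan, fungal) communities sampled over time along environmental
gradients — the setting of monthly lake water-column campaigns with
particle-associated (PA) and free-living (FL) size fractions at several
depths. The package is aimed at microbial ecologists who have an ASV/OTU count
table, a phylogenetic tree and sample metadata, and want the standard
quantitative answers to "how do these communities assemble, and how stable are
they?":

* **Sloan neutral community model (NCM)** — fits the immigration rate *m* from
  the occupancy–abundance relationship. At stationarity a taxon with
  metacommunity relative abundance *p* has local abundance
  *x* ~ Beta(*Nmp*, *Nm*(1−*p*)); its detection frequency across samples as a
  function of *p* identifies *Nm*. Fitting is bounded least squares on
  log(*Nm*) with taxon-bootstrap confidence intervals and an
  above/neutral/below partition of taxa around the fitted curve. By default
  the detection curve accounts exactly for finite read depth
  (1 − B(*a*, *b*+*N*)/B(*a*, *b*), the beta-binomial zero class), which
  removes the rare-taxon bias of the classic sharp threshold at *d* = 1/*N*
  (still available as `detection = "threshold"`).
* **Stegen-style null models** — abundance-weighted βMNTD with a
  taxon-shuffle null gives βNTI; abundance-based Raup–Crick (RCbray) reassembles
  null communities at observed richness and read totals. Each sample pair is
  classified: βNTI > 2 variable selection, βNTI < −2 homogeneous selection,
  otherwise RC > 0.95 dispersal limitation, RC < −0.95 homogenizing dispersal,
  |RC| ≤ 0.95 undominated. The βMNTD null loop is in C++ (999 permutations
  over 50 samples × 150 taxa run in seconds).
* **Compositional stability** — per (lake, fraction), depth-aggregated
  communities are compared between consecutive months:
  *s*ₜ = 1 − BrayCurtis(*t*−1, *t*) ∈ [0, 1], averaged into a stability
  index (Jaccard- and rank-correlation variants included).
* **PLS path modelling** — mode-A partial least squares path models link
  latent environmental drivers (salinity, nutrients, physicochemical,
  particles) and richness to stability, with GoF = √(mean communality × mean
  R²), bootstrap sign-crossing p-values (significance at p < 0.1) and
  direct/indirect/total effect decomposition.
* **Seeded synthetic-data generators** — neutral (beta-multinomial),
  selection-structured (Brownian niches on a Yule tree) and multi-lake monthly
  time series with PA/FL fractions, depths and sonde-style metadata, so every
  stage is validated against data with known structure.

## Worked example

Simulate 100 neutral communities (5000 reads each, 200 taxa, true
*m* = 0.05), fit the NCM, and partition sample pairs into assembly processes:

```r
library(lakeassembly)

comm <- simulate_neutral(n_samples = 100, N = 5000, m = 0.05,
                         n_taxa = 200, seed = 42)
fit <- fit_ncm(comm, n_bootstrap = 1000, seed = 1)
fit
#> Sloan neutral community model fit (199 taxa, 100 samples)
#>   Nm = 258.4  (N = 5000.0, m = 0.05168 [0.04906, 0.05412])
#>   R^2 = 0.9782 [0.9696, 0.9854], detection limit d = 2.00e-04

table(partition_taxa(fit)$partition)
#>   below neutral   above
#>       8     155      36

tree <- simulate_tree(200, seed = 7)
bn <- bnti_pairwise(comm[1:20, ], tree, n_null = 999, seed = 2)
rc <- rc_bray(comm[1:20, ], n_null = 999, seed = 3)
round(table(classify_process(bn$bnti, rc$rc)) / choose(20, 2), 3)
#>     variable_selection  homogeneous_selection   dispersal_limitation
#>                  0.037                  0.000                  0.479
#> homogenizing_dispersal            undominated
#>                  0.000                  0.484
```

The fit recovers the generating immigration rate (0.0517 vs 0.05, inside the
bootstrap interval) with R² = 0.98, and most taxa sit inside the neutral band.
The process table reads correctly too: there is no selection signal (βNTI
flags under 4% of pairs, phylogeny is unrelated to abundance here), and the
low immigration rate *is* dispersal limitation — communities drift apart more
than the fixed-richness Raup–Crick null expects, so roughly half the pairs are
classified that way and the rest are undominated.

The full pipeline — simulation, NCM, null models, stability, per-lake path
models, run manifest — is driven by one config file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "lakeassembly"),
             out_dir = "demo_run")
```

or from a shell:

```sh
Rscript inst/cli/lakeassembly.R run --config inst/extdata/demo_config.yaml --output demo_run
```

Per-stage TSV/JSON outputs land under `demo_run/`, and `manifest.json` records
the config snapshot, per-stage seeds, row counts and file checksums. Two runs
from the same config are byte-identical.

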