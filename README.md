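# sban

Social-behavioral association networks (SBANs) for community ecology:
infer, summarize and compare species interaction networks from
activity-based abundance observations.

## The problem

Wintering waterbird communities partition habitat and time: species select
habitat patches for foraging or roosting, and short-term behaviors
(competition, aggression, courtship) mediate who shares which patch when.
Direct interaction observation at community scale is intractable, so the
SBAN approach infers associations from co-occurrence: each species
contributes one network node per behavior class (2 activities + 3
behaviors), and two nodes are linked when their per-event abundance counts
correlate across daily selection events within a habitat.

For one (management regime, habitat) stratum with abundance matrix
$X$ (events $\times$ nodes), edge weights are

$$w_{uv} = \left[r_{uv}\right]_{+} \cdot \mathbf{1}\{r_{uv} \ge \tau\},\qquad
r_{uv} = \mathrm{cor}(X_{\cdot u}, X_{\cdot v}),$$

with Pearson correlation $r$, negatives zeroed (or made absolute), and
build threshold $\tau = 0.05$. Networks over the fixed universe of
$T = |\text{catalog}| \times 5$ nodes (70 for the default 14-species
catalog) are summarized by active species ($n$), active nodes ($V$), edges
($N$), density $d = 100\,N/\binom{T}{2}$, and the SIPS/BIPS edge
classifications (intra/inter-species and intra/inter-behavior tallies).
Keystone species are ranked by hub centrality (principal eigenvector of the
weighted adjacency) or PageRank on the network simplified at a strict 0.4
cutoff. Stratum attributes are compared by a two-way fixed-effects ANOVA
(regime $\times$ habitat, the 8 attributes as cell replicates) with
Fisher's LSD post hoc.

A negative-binomial community simulator with plantable block-correlation
structure (`make_default_config()`, `simulate_events()`,
`plant_block_correlation()`) stands in for the raw video-derived data,
which are deposited externally.

## Worked example

```r
library(sban)

catalog <- species_catalog()                       # 14 species, 5 guilds
config  <- make_default_config(catalog, n_days = 60, seed = 42)
events  <- simulate_events(config)                 # 14,429 observation rows
res     <- run_sban(events, catalog, out_dir = "sban_out")

head(res$summaries[, 1:7])
#>   regime habitat n_species active_nodes n_edges density_pct sips_intra
#> 1     R1      BG        14           68     456        18.9        125
#> 2     R2      BG        14           50     197         8.2         57
#> 3     R1      DW        14           68     515        21.3        122
#> 4     R2      DW        14           62     239         9.9         89
#> 5     R1      GL        14           70    1039        43.0        139
#> 6     R2      GL        14           69     653        27.0        128

res$anova
#> Two-way ANOVA (Type III, balanced)
#>           source          ss df          ms           f    p
#>  corrected_model  1440280.43  9  160031.159  1.38061117 .214
#>        intercept  6548027.92  1 6548027.922 56.49075210 .000
#>            sites   214555.61  1  214555.612  1.85100126 .178
#>          habitat  1209892.60  4  302473.149  2.60947813 .043
#>  sites_x_habitat    15832.22  4    3958.055  0.03414669 .998
#>            error  8113929.05 70  115913.272
#>            total 16102237.40 80
#>  corrected_total  9554209.48 79
#> R squared = 0.151 (Adjusted R squared = 0.042)

head(res$keystones, 3)
#>     species_id     score rank regime habitat
#> 1      C_nigra 1.0000000    1     R1      BG
#> 2 P_leucorodia 0.9693447    2     R1      BG
#> 3  A_cygnoides 0.9463024    3     R1      BG
```

Reading the output: every managed (R1) stratum forms a denser network than
its unmanaged (R2) counterpart (e.g. grassland: 1,039 vs. 653 edges, density
43.0% vs. 27.0% of the 2,415 possible node pairs) -- the simulator encodes
the managed-sites-richer contrast, and the pipeline recovers it. The ANOVA
pools the 8 attributes per stratum as replicates: here habitat differences
are significant (p = .043) while the regime main effect is not (p = .178).
`res$keystones` ranks species by their best node's hub score per stratum
(1.0 = the network's strongest hub). Per-stratum GraphML and edge-list
files, the summary table, keystone rankings and ANOVA/LSD CSVs land in
`sban_out/`.

The published attribute table this package's statistics are validated
against ships as a fixture: `reference_summaries()`; running
`anova_two_way(build_response_table(reference_summaries()))` reproduces the
published between-subjects table (habitat SS 619,593, F = 6.141, R² = .278).

## Command line

```sh
SBAN_CLI=$(Rscript -e 'cat(system.file("cli", "sban", package = "sban"))')
Rscript "$SBAN_CLI" simulate --n-days 60 --seed 42 --out events.csv
Rscript "$SBAN_CLI" all --events events.csv --out sban_out/
Rscript "$SBAN_CLI" compare --summaries sban_out/summary.csv --out cmp/
```

Options may also be given as a YAML config (`--config cfg.yaml`); explicit
flags win. Logs go to stderr, artifacts to files.

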