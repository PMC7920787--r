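---
title: "Methods: social-behavioral association networks from abundance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social-behavioral association networks from abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sban)
```

## The model

A *social-behavioral association network* (SBAN) describes how co-occurring
species coordinate resource use in a shared habitat. Its observational unit
is the *selection event*: one day's stable aggregation of wintering
waterbirds at a site, during which every species' individuals are counted
per habitat class and per behavior class. The behavior classes are two
activities (foraging, roosting) and three short-term behaviors (competition,
aggression, courtship). Each species contributes one node per behavior
class, so a 14-species catalog spans a fixed universe of $T = 70$ nodes and
the node universe is identical in every stratum.

For one stratum -- a (management regime, habitat) pair -- the retained
events form an event $\times$ node abundance matrix $X$. Edges are defined
from the sample Pearson correlation of its columns,
$r_{uv} = \mathrm{cor}(X_{\cdot u}, X_{\cdot v})$, with three policies
applied in order:

1. **Sign policy.** Negative correlations carry no association weight.
   The default (`zero_negative`) sets them to 0; `absolute` keeps their
   magnitude. Both are exposed because the study description invokes both;
   they differ only where negative correlations occur at all, and the
   default is the one the published networks used.
2. **Build threshold** (default 0.05, *ties kept*): entries below the
   threshold are zeroed. This is a readability filter, not a significance
   test.
3. **Keystone cutoff** (default 0.4, *ties dropped*): for hub
   identification only, edges must be *strictly* stronger than the cutoff.
   The asymmetric tie handling follows the verbatim wording of the two
   rules ("below the threshold were set to 0" vs. "higher than 0.4 ...
   included").

Zero-variance columns (species absent from a stratum) get correlation 0 by
policy rather than `NA`, which keeps absent species as isolated nodes and
makes attributes comparable across strata.

### Network attributes

For each network we report: species with at least one active node ($n$),
active nodes ($V$, degree $\ge 1$), edges ($N$), and edge density
$d = 100\,N/\binom{T}{2}$ **over the fixed 70-node universe** -- not over
active nodes. This denominator choice is the only one that reproduces the
published density arithmetic (6 of 10 printed rows match exactly, e.g.
$100 \cdot 780/2415 = 32.3$; the other 4 are recorded as presumed
typesetting errata and never targeted). Densities are rounded half away
from zero to one decimal, matching the printed table.

Edges are classified two ways: SIPS (species interaction preference scores)
split $N$ into intra- vs. inter-species edges; BIPS (behavioral interaction
preference scores) split $N$ into intra- vs. inter-behavior edges. Because
the universe holds exactly one node per (species, class) pair, an edge can
never be intra-species *and* intra-behavior, which yields the invariants
$\mathrm{SIPS_{intra}} + \mathrm{SIPS_{inter}} = N$,
$\mathrm{BIPS_{intra}} + \mathrm{BIPS_{inter}} = N$,
$\mathrm{SIPS_{intra}} \le \mathrm{BIPS_{inter}}$ and
$\mathrm{BIPS_{intra}} \le \mathrm{SIPS_{inter}}$ -- all property-tested.

### Keystone (hub) species

The source description names "hub centrality" and "PageRank" without
formulas. Both are implemented:

* `hub_scores()`: HITS hub scores on the weighted adjacency; for an
  undirected graph these coincide with the principal (Perron) eigenvector.
  Scores are computed per connected component by power iteration with a
  small positive diagonal shift (bipartite components otherwise oscillate
  between two period-2 iterates), each component's eigenvector is scaled by
  its dominant eigenvalue so better-connected components dominate, and the
  result is normalized to maximum 1. Isolates score 0.
* `pagerank_scores()`: damping 0.85 (the standard default; none is stated
  in the source), weighted transition probabilities, dangling nodes
  teleporting uniformly, power iteration to L1 tolerance $10^{-9}$ with a
  hard cap of 1,000 iterations (exceeding it is an error, not a silent
  result).

Species-level aggregation is unstated in the source; the default is the
**maximum** over a species' five node scores (a species is a keystone if
*any* of its nodes is a hub), with `sum` as an option. Ties break by the
other aggregate, then species id, so rankings are deterministic. Several
species are reported as joint keystones when their scores are within a
relative tolerance (default 0.05) of the leader -- the published table
lists 2--3 hub species for some habitats, and the tolerance it implies is
unknowable, so ours is configurable and documented rather than fitted.

### Regime x habitat comparison

The eight numeric attributes of each of the 10 stratum summaries are melted
into an 80-row response table and fit with a two-way fixed-effects ANOVA,
`value ~ regime * habitat`. Under this balanced layout Type III and
sequential sums of squares coincide, and the degrees of freedom (9, 1, 1,
4, 4, 70, 80, 79) reproduce the published between-subjects table exactly.
Pooling attributes with heterogeneous scales (counts of hundreds of edges
next to one-decimal densities) as "replicates" is statistically
questionable -- edge counts dominate the error variance -- but it is
precisely what the reference analysis did, so it is reproduced and the
caveat is documented here rather than silently corrected. Post hoc
comparisons use Fisher's LSD on marginal means,
$SE = \sqrt{MS_E (1/m_i + 1/m_j)}$ on the error degrees of freedom,
by default only after a significant omnibus F (a `force` flag overrides).
p-values below .0005 are rendered as ".000" by the CSV emitter, matching
the published display convention.

## The synthetic-data generator

The raw video-derived observations are deposited externally, so the package
ships a generator that emulates their statistical shape rather than their
values. The stated world:

* **Design**: 4 sites (2 per regime), 150 days (one wintering season,
  mid-October to mid-March), one selection event per site per day.
* **Occupancy and abundance**: per event, each species enters each habitat
  independently with probability `p_include`; habitat baselines (MF 0.55,
  SW 0.45, GL 0.30, BG 0.15, DW 0.15 in R1) follow the observed richness
  gradient, and R2 values are 0.6 of R1, encoding the managed-sites-richer
  contrast. Abundance means follow the same gradient (MF 30 down to BG 5
  individuals in R1, halved in R2).
* **Noise**: counts are negative-binomial (shape 5) -- overdispersion is
  standard for bird counts; no distribution is stated in the source.
* **Activities and behaviors**: the activity split is 0.7
  foraging / 0.3 roosting; behavior rates are 0.10 (competition),
  0.05 (aggression), 0.02 (courtship) of a species' event total, drawn
  binomially from it so a behavior count can never exceed the abundance
  that produced it.

Where the generator deviates from the most literal reading of its
description, it does so for identifiable reasons:

* **Latent factors.** Correlation between node columns is induced by
  event-level standard-normal factors acting multiplicatively on the
  log scale, mean-corrected by $e^{-\lambda^2/2}$. A *single* shared factor
  cannot make two planted blocks internally correlated yet mutually
  uncorrelated, so the loadings table supports several independent factors:
  the default configuration uses one (guild-mates share its loading), and
  `plant_block_correlation()` assigns one factor per group. A node listed
  in two groups loads on both factors and becomes a *bridge* correlated
  with both blocks.
* **Activity split.** Foraging and roosting counts are drawn as
  *independent* negative binomials with means $m\cdot s$ and $m(1-s)$
  rather than by binomially splitting one total, so that each activity
  column can carry its own loading. Marginal means are identical under
  both schemes.
* **Planted correlation strength.** For a target within-group correlation
  $\rho$, the loading solves
  $e^{\lambda^2} = \dfrac{1-\rho+\rho/M}{1-\rho(1+1/\theta)}$
  in closed form, where $M$ is the group's mean expected class count and
  $\theta$ the dispersion. This is exact for fully included
  (probability-1) species with equal means; partial inclusion or unequal
  means dilute the realized correlation, which is why parameter-recovery
  tests use probability-1 configurations.
* **Behavior-node loadings** scale the binomial rate (capped at 1); the cap
  slightly biases marginal means for extreme factor draws. Behavior
  columns are therefore only approximately log-normal-correlated.

What a green test does *not* establish: the generator has no phenology,
no migration timing, no spatial structure within a habitat, no day-to-day
autocorrelation, and is not fitted to the deposited data. Green pipeline
tests certify the machinery (filtering, pivoting, correlation, thresholds,
scores, ANOVA), not ecological realism, and the published hub-species
identities per habitat are explicitly out of reach without the raw data.

## Numerical choices

* Pearson correlation delegates to `stats::cor`; zero-variance columns are
  zeroed afterwards by policy.
* Density rounding is half away from zero (the reference tables'
  convention), not R's banker's rounding.
* Hub power iteration: L2-normalized iterates, convergence at
  $10^{-12}$ L1 change, diagonal shift $0.05\cdot\max_i \sum_j w_{ij}$;
  the reported eigenvalue is the Rayleigh quotient of the *unshifted*
  adjacency.
* Richness ties in the daily-event filter break by total count, then
  lexicographic event id (the source does not address ties); the filter is
  idempotent.
* A stratum with fewer than two retained events cannot be correlated;
  `correlate_nodes()` raises an error, while the `run_sban()` orchestrator
  substitutes an empty network with a warning so one sparse stratum cannot
  void a whole run.
* All-constant ANOVA responses (corrected total $\approx 0$ at machine
  precision) report zero effect sums of squares with $p = 1$ rather than
  0/0.

## Known limitations

* Correlation networks conflate co-occurrence with interaction; no
  significance testing, partial correlation, or time-lagged association is
  attempted (explicitly out of scope).
* The choice between `zero_negative` and `absolute` matters only when
  negative correlations survive thresholding; the published account is
  ambiguous about which produced its edge counts, and the default follows
  the policy its network plots used.
* The published density column could not be fully reconciled: four of ten
  rows disagree with every denominator we tested and are treated as errata.
* The error mean square of the published ANOVA table prints as 25,223.6
  while the exact quotient is 25,223.5498; reproduction is asserted to one
  unit in the last printed digit.
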