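---
title: "Temporal change in taxon co-occurrence networks from assemblage counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal change in taxon co-occurrence networks from assemblage counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleonet)
```

## The problem

Paleolimnological assemblage records — counts of subfossil cladoceran
(water-flea) remains identified in lake-sediment intervals — are usually
summarized by diversity indices. Diversity, however, can stay flat while
the *organization* of the community changes. `paleonet` treats an
assemblage data set as a co-occurrence network: taxa are nodes, and a
significant Spearman rank correlation between two taxa's Hellinger-
transformed relative abundances (across lakes, or across depth intervals)
is a link. Shifts in the topology of that network between time periods —
connectance, modularity, mean degree centrality, skewness of the degree
distribution — are then tested against a constrained random-graph null.

Two study designs are supported end to end:

* **Landscape ("top-bottom") design** (`run_topbottom()`): many lakes,
  each contributing a modern (core-top) and a pre-Industrial (core-bottom)
  sample; lakes are grouped by a human impact index (HII) into low
  (HII ≤ 0.1), moderate (0.1 < HII < 0.5) and high (HII ≥ 0.5) classes,
  and one network is built per class × period (six networks), with edges
  at *P* < 0.01.
* **Full-core (zonal) design** (`run_fullcore()`): a single dated core is
  split into contiguous stratigraphic zones by constrained clustering,
  and one depth-by-taxon network is built per zone, with edges at
  *P* < 0.05 (a smaller within-lake taxon pool, compared within one
  record).

## The network and its metrics

For `S` taxa present in a group and `L` significant links, the package
computes, on the unweighted, unsigned topology:

* **Connectance** `L / (S(S-1)/2)` — the realized fraction of possible
  undirected links.
* **Mean degree centrality** `2L/S` — mean links per taxon.
* **Modularity** `Q = (1/2L) Σ_ij (A_ij − γ k_i k_j / 2L) δ(c_i, c_j)`,
  with the partition `c` found by divisive edge-betweenness (Girvan-
  Newman) clustering: repeatedly delete the edge of highest betweenness
  (recomputing betweenness after every deletion), record the component
  structure after each deletion, and return the recorded partition with
  maximal `Q`. The resolution `γ` defaults to 1 and is exposed in
  `girvan_newman()` and `network_summary()`.
* **Skewness of the degree distribution**, by default the
  `Σ(X_i − X̄)³ / ((S−1) σ³)` form with σ the sample standard deviation.
  The biased moment-ratio form `m₃ / m₂^{3/2}` used by several common
  skewness routines is also provided (`degree_skewness(method =
  "moment")`); the two disagree for small `S`, and the package defaults
  to the (S−1)σ³ form.

Numerical conventions worth knowing:

* Spearman rho uses average ranks for ties; the two-sided p-value comes
  from the t approximation `t = ρ√((n−2)/(1−ρ²))` on `n − 2` degrees of
  freedom, with `p = 0` for `|ρ| = 1` and zero-variance taxa masked. At
  least 5 samples are required, the minimum for which a correlation-based
  network is meaningful.
* Edge p-values are used raw, without a correction across the taxa-pair
  family — the convention of the analysis this package operationalizes.
  Negative correlations are kept as links (their sign is stored on the
  edge but ignored by the topology metrics).
* A group's node set is every taxon present (nonzero in at least one
  sample) in that group, including taxa that end with no significant
  link. This presence-based rule is selectable via the `present_taxa`
  argument of `build_network()`.
* Determinism: ties in edge-betweenness removal are broken by
  lexicographic edge order; the max-Q cut prefers fewer communities on
  ties; CONISS merge-cost ties prefer the stratigraphically earlier pair.
  These choices make runs reproducible across platforms; none of them
  changes any non-degenerate result.
* Degenerate inputs are flagged, not fatal, wherever a downstream summary
  can still be assembled: an edgeless graph has undefined (NA)
  modularity, a regular graph has zero skewness with a degeneracy flag.

## Zonation

`zonate_core()` truncates the record at a configured earliest age
(default 1750 CE), Hellinger-transforms relative abundances, computes the
Bray–Curtis (percentage difference) dissimilarity matrix, and clusters
with CONISS — agglomerative clustering in which only stratigraphically
adjacent clusters may merge and the merge cost is the increase in
within-cluster dispersion, `Σ_{i<j∈C} d²_ij / |C|`, computed directly
from the dissimilarities. The number of significant zones is chosen by a
broken-stick comparison: the dispersion explained by the k-th split is
compared with `T/(n−1) Σ_{j=k}^{n−1} 1/j`, and zones are added while the
leading splits beat that expectation. Zones smaller than `min_intervals`
(default 5, the smallest record that still supports a correlation
network) are disallowed; the cut is coarsened until every zone complies.

The dissimilarity is computed on Hellinger-transformed abundances by
default, following the stated processing order of the source analysis;
`transform = "relative"` switches to raw relative abundances, since the
order is ambiguous in prose descriptions of this workflow.

## The null model and inference

A single observed network per group cannot carry a significance test, so
each group is compared through a constrained Erdős–Rényi ensemble:
`n_reps` (default 30, mirroring the average per-class sample size of the
landscape design) random graphs `G(S, p)` with `S` the group's node count
and `p` its observed connectance. Each replicate is summarized by the
same four metrics; a one-way ANOVA across groups, a Tukey HSD post-hoc
contrast, and a Benjamini–Hochberg FDR adjustment *within* the family of
one impact class or one lake (four metric tests plus the rarefied-Shannon
Mann–Whitney test) complete the inference. The omnibus ANOVA p-value per
metric is the family member entering the BH adjustment; Tukey pairwise
p-values are reported alongside.

Because the null preserves only `(S, p)` — not the degree sequence —
metric contrasts partly reflect the `(S, p)` differences themselves; this
is a property of the design being reproduced, not an artifact. Rarefied
Shannon diversity uses a single seeded without-replacement draw per
sample to a common depth (default: the minimum retained sample total);
samples below the depth are dropped with a warning.

## The synthetic-data generator

`generate_assemblage()` and `generate_zoned_core()` exist so that every
stage is testable with a known truth. A latent Gaussian vector per sample
is drawn from a block correlation matrix (taxa in modules, within-module
correlation `rho_w`, one sign-flipped taxon in a configurable fraction of
modules for negative associations), pushed through an exponential link
onto a geometric dominance profile, and converted to counts by a
multinomial draw at a counting effort uniform on 100–600 individuals per
sample. Because every downstream statistic is rank-based, only the latent
rank structure needs to be controlled; the monotone link is otherwise
arbitrary.

Defaults were fixed once, as the conditions the generator is meant to
emulate:

* 45 taxa × 100 sites (landscape mode), 20 taxa × 20 intervals
  (`core_config()`, full-core mode) — the scale of a regional subfossil
  pool and of a dated core record;
* counting effort 100–600 individuals, the range of real counting effort
  for such records;
* `rho_w = 0.7` for "strong" planted association;
* nine modules (guilds of ~5 taxa): small guilds keep each module's
  aggregate share of the composition modest, which keeps closure-induced
  spurious correlation mild (see Limitations);
* dominance ratio 0.92, a ~45-fold abundance range: steep enough to mimic
  dominance by a few taxa, shallow enough that the rarest taxon is still
  countable at the configured effort — a planted association between
  taxa that are never observed is unrecoverable in principle;
* latent scale 1 across lakes, 0.6 between intervals of one core:
  compositional contrast between lakes exceeds interval-to-interval
  fluctuation within one lake. Core intervals are generated independently
  by default (`ar = 0`); an AR(1) persistence option exists, but
  persistent drift *is* assemblage change, and smooth drift legitimately
  weakens the one-zone null.

What the generator does **not** emulate: taphonomic loss, counting error
models, species invasions, secular trends within zones, and spatial or
temporal autocorrelation among sites. Passing recovery tests on this
generator therefore shows that the pipeline detects the planted kind of
structure at realistic sample sizes — not that real records satisfy the
generator's assumptions.

## Problem sizes used in validation

The shipped checks run the worked-example metrics exactly; ensemble
calibration with 1000 edge-count replicates; type-I control of the
FDR-adjusted family over 200 seeded two-group runs at identical `(S, p)`;
the published high-impact connectance contrast (S = 38, c = 0.085 vs
S = 27, c = 0.077, 30 replicates) over 200 seeds; planted-pair recovery
over 10 landscape data sets; change-point recovery over 50 cores; and the
end-to-end landscape run over 10 seeds. These sizes give Monte-Carlo
standard errors comfortably below the margins being tested while keeping
the default validation run short.

## Known limitations

* **Compositional closure.** Relative abundances sum to one, so when a
  correlated block of taxa rises, everything else must fall: closure
  induces genuine negative rank correlations between unrelated taxa. With
  few large modules this produces significant negative between-module
  links (at the default small-guild conditions the effect is mild, an
  excess edge rate of roughly 1% at α = 0.01). Because the topology
  metrics are unsigned, such links also connect planted modules, which is
  why module-membership recovery is assessed on the positive-link
  subnetwork in the package's tests. Compositionality-aware association
  measures are out of scope here by design.
* **The null is `G(S, p)`.** No degree-sequence or abundance-permutation
  null is provided.
* **Ages are consumed as given** — no age-depth modelling — and the HII
  enters only as a scalar score; its GIS derivation is out of scope.
* The Spearman p-values rely on the t approximation, which is slightly
  conservative at very small n; an exact permutation p-value is feasible
  for n ≤ 10 but the approximation is the convention of the workflow
  reproduced here.

## A worked example

```{r example, eval = FALSE}
library(paleonet)

# a synthetic landscape with a planted decorrelation in the high class
tb <- generate_topbottom(rho_w = list("high:top" = 0.1),
                         cfg = synth_config(seed = 101))
report <- run_topbottom(tb$counts, run_config("topbottom", seed = 1))

format_metrics(report$metrics)   # the six-network metric table
report$tests                     # ANOVA / Tukey / FDR per class and metric
report$diversity_tests           # rarefied-Shannon Mann-Whitney per class

# a synthetic core with a change point after interval 10
core <- generate_zoned_core(core_config(seed = 7), change_point = 10,
                            shift = rep(c(2, 0), 10))
zr <- run_fullcore(core$counts, run_config("fullcore", seed = 1))
attr(zr$zones, "zone_summary")
format_metrics(zr$metrics)
```
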