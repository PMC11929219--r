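---
title: "Optimizing health station locations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing health station locations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stationopt)
```

## The problem

Given the home locations of a patient population, where should `k` health
stations stand so that reaching care is as cheap as possible in aggregate?
`stationopt` casts this facility-location question as clustering: stations
are centroids, patients are data points, and the objective is the
visit-weighted sum over patients of the cost of reaching the nearest
station. Everything operates on planar projected coordinates in metres
(e.g. ETRS-TM35FIN for Finnish data); the package never reprojects, and
all layers of one problem must share one CRS, because Euclidean geometry
on the coordinates is assumed throughout.

## The three objectives

For patient set $P$ and station set $HS$, with per-patient visit weight
$w_p$:

$$\text{Euclidean:}\quad \sum_{p \in P} w_p\, d_{L2}\!\big(p,\ \arg\min_{h \in HS} d_{L2}(h,p)\big)$$
$$\text{Squared Euclidean:}\quad \sum_{p \in P} w_p\, d_{L2}\!\big(p,\ \arg\min_{h \in HS} d_{L2}(h,p)^2\big)^2$$
$$\text{Travel cost:}\quad \sum_{p \in P} w_p\, c\!\big(p,\ \arg\min_{h \in HS} c(h,p)\big)$$

Each objective performs its own argmin — the station serving a patient is
the cheapest one *under that objective*, not necessarily the geometrically
nearest. Squared Euclidean is the classical k-means criterion; it
penalizes long distances quadratically and therefore spends stations on
remote sparse areas. Plain Euclidean is the natural geographic choice.
Travel cost is the objective of substantive interest: it prices each visit
in euros through a mode-choice model and exploits the road and transit
structure.

Weights default to 1 (per-visit optimization). Setting `weight` to annual
visit counts makes every total an annual euro/metre figure; the synthetic
generator does this by default.

## The travel-cost model

Mode choice is rule-based, first match wins in `mode_precedence`
(default `walk > taxi > bus > car`):

| rule | condition | per-visit cost (defaults) |
|---|---|---|
| walk | Euclidean distance to station < 1000 m | 0 € |
| taxi | age ≥ 80 years | 2 × (5.90 € + 1.50 €/km × km) |
| bus | Euclidean distance to nearest stop < 200 m | 2 × 5.10 € |
| car | otherwise | 2 × 0.25 €/km × km |

Kilometres are *estimated road kilometres* (overhead graph, below); the
walk and bus-stop threshold tests use Euclidean distances, since the
thresholds describe immediate neighbourhood geometry rather than routed
trips. The bus fare is a flat rate — no fare zones — and the patient's
time cost (wage loss) is deliberately out of scope, keeping the model a
pure out-of-pocket travel cost.

Three choices here were genuinely open and are package decisions:

* **Walk precedes taxi.** The walk rule is anchored to residence distance
  only, so an 80-year-old living 300 m from the station walks at 0 € here.
  The order is configurable for the opposite reading.
* **`trips_per_visit = 2`.** Tariffs are per trip; a visit is a round
  trip. Set to 1 for one-way accounting.
* **Car and taxi tariffs** (0.25 €/km; 5.90 € + 1.50 €/km) are
  Finnish-tariff-like defaults and explicit configuration, never
  hard-coded in the formulas.

## Road network and the overhead graph

The road network is an undirected embedded graph with per-edge length
(metres) and average speed (km/h). It is the ground-truth travel oracle:
`shortest_path()` runs Dijkstra over edge lengths, and travel time is
accumulated along the *length-optimal* path (distance is primary; time
derives from it), not along a separately time-optimal route. Off-network
points — patients, stations, anchors — snap to the nearest node, with no
access-leg penalty; the same convention applies to both sides of every
query, so the bias largely cancels in comparisons. One-way streets, turn
restrictions and rush-hour dynamics are out of scope.

Exact shortest paths are far too slow inside the optimizer (the stations
move every trial, so no patient-to-station matrix can be pre-computed).
The overhead graph replaces them with a constant-time estimator:

1. Cluster patient locations into `K` groups (squared Euclidean, random
   swap) and snap each centroid to its nearest road node. These are the
   anchors — dense where demand is dense.
2. For every anchor pair, store the **overhead ratio** (road distance ÷
   Euclidean distance) and the effective speed (distance ÷ time along the
   same path, i.e. a harmonic mean of segment speeds).
3. A query for points $(p, q)$ finds their nearest anchors $i, j$ by
   linear scan and returns $d_{L2}(p,q) \times \mathrm{ratio}[i,j]$ and
   the time from $\mathrm{speed}[i,j]$.

On an unobstructed grid the ratio is bounded by the Manhattan diagonal
$\sqrt 2$; around lakes it grows well beyond that, which is precisely why
a single global detour constant (the classical 1.4) is not enough.

Numerical details: anchor pairs closer than `eps = 1` m get ratio 1
(guards the $0/0$ blow-up for coincident anchors); pairs in different road
components are flagged unreachable (`NA`) and queries over them raise an
error rather than returning infinities; the anchor coordinates are the
*snapped node* coordinates, which makes every ratio provably ≥ 1 because
edges can never be shorter than their chords. `K = 256` is the default —
large enough that the median relative error against exact Dijkstra on the
default synthetic region is below 1% — and remains user-configurable; the
anchor-selection clustering uses 500 swap trials, since anchor placement
needs spatial coverage rather than an optimal clustering.

## The random-swap optimizer

Plain k-means (Lloyd iterations) cannot move a centroid across an empty
region, so on data with many well-separated population hubs it routinely
strands two centroids in one hub and leaves another hub unserved —
repeating it only partly compensates. Random swap wraps k-means in a
global trial-and-error move:

1. Initialize with `k` patient locations drawn without replacement
   (seeded).
2. Polish with two k-means iterations (assignment, then visit-weighted
   arithmetic-mean centroid update).
3. Repeat `T = 5000` times: replace one uniformly chosen station with one
   uniformly chosen patient location, polish with two k-means iterations,
   accept the candidate only if the objective is *strictly* lower.

Design points, each a deliberate resolution of an open choice:

* **Swap targets are patient locations**, guaranteeing a relocated
  station lands where demand exists (standard random-swap practice).
* **Strict acceptance** (ties rejected) keeps the accepted-cost history
  strictly decreasing — a clean invariant the tests assert.
* **Arithmetic-mean centroids for all objectives, including travel
  cost.** The mean is not the cost-optimal site under the travel-cost
  metric, but it is fast and robust; spatial-median (p-median) updates and
  local search around centroids are out of scope.
* **Empty-cluster repair:** a station whose cluster empties immediately
  jumps to the patient farthest from its assigned station under the
  active metric; without repair `k` silently shrinks.
* **Building snap is post-processing**, applied once after the search
  (with the final cost recomputed): it keeps stations off lakes and other
  places with no infrastructure, at a small, reported cost increase.

The whole loop is compiled (Rcpp); all randomness flows through R's RNG,
so a fixed seed reproduces results bit for bit.

`centroid_index()` quantifies clustering success at the cluster level: map
every found station to its nearest ground-truth hub and count the hubs
that attract none. CI = 0 means every hub is represented. The mapping is
one-directional (found → truth) with orphan counting, matching the
"too many here / too few there" reading of k-means failure maps.

## What the synthetic generator emulates

Real patient registries cannot be redistributed, so the generator produces
layers with the statistical structure the method's claims depend on, under
a fixed seed. Defaults (chosen once as the package's study conditions):

* **9333 patients** in a 120 × 120 km region around **15 hubs** of very
  unequal size — one dominant city hub holds 40% of patients, the rest
  decay geometrically — mirroring a regional capital versus villages.
  Hub spread 2.5 km, minimum separation 15 km: clusters are well separated
  relative to their width, exactly the regime where k-means fails and the
  swap search matters.
* **Ages** truncated-normal (mean 67, sd 12, minimum 18) with the 80+
  mass topped up to at least 15%, so the taxi rule binds for a realistic
  share of an elderly chronic-care cohort.
* **Visit weights** `1 + Poisson(3.7)`, mean 4.7 visits/person/year.
* **Road network**: a 2 km grid with ~12% of nodes removed as square
  lakes (components re-linked by straight causeways), major-road rows and
  columns through every hub at 80 km/h (others 50 km/h), bus stops every
  600 m along major roads, and 30 candidate buildings per hub.

What it does *not* emulate: real street geometry and one-way systems,
fare zones, capacity or specialization of stations, and any correlation
between age and location. Passing tests therefore demonstrate the
algorithmic claims — estimator accuracy, optimizer robustness, model
arithmetic — on data with the right statistical shape, not the euro
figures of any real region.

## Verification approach and problem sizes

The test suite checks every operation against an independent oracle where
one exists: brute-force scans for assignment, snapping and nearest-stop
distances; full enumeration of 2-partitions for a small k-means optimum;
`igraph` batch Dijkstra matrices for every overhead-matrix entry; a
closed-form limit in which the travel-cost objective with ratio ≡ 1, no
walkers, no taxis and no bus access collapses exactly to
`2 × 0.25 €/km × Euclidean total / 1000`.

Acceptance-level runs use the default region (9333 patients): median
estimator error over 1000 random patient pairs at K = 256 (threshold 5%,
observed well under 1%, decreasing in K); a 20-run robustness experiment
(k = 15, T = 5000) requiring CI = 0 in at least 95% of runs while
single-run k-means leaves a positive mean CI; and one full timed pipeline
(simulate → build graph → optimize k = 23, T = 5000 → evaluate), which
completes in roughly a minute on one CPU, with bit-identical repetition
checked at T = 200. `scripts/acceptance.R` re-runs the headline
computation from scratch and writes the resulting numbers as JSON.

## Known limitations

* Arithmetic-mean centroids are suboptimal for the travel-cost objective;
  the reported optimum is a good, not provably optimal, configuration.
* The overhead estimator inherits anchor granularity: queries far from
  any anchor (outside demand areas) can carry larger errors than the
  demand-weighted medians suggest.
* Station capacity, service mix and care quality are not modelled; every
  station is assumed equivalent and unconstrained.
* The travel-cost parameters are region-specific by nature and must be
  re-tuned for other settings; distance and time reports are generic.
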