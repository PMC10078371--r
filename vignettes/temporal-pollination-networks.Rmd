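---
title: "Temporal plant-pollinator networks and pollination service: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal plant-pollinator networks and pollination service: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
library(dplyr)
```

# The problem

Monitoring programs in strongly seasonal systems — the motivating case is
a high-Arctic mesic heath where a single avens-like plant attracts the
overwhelming majority of insect flower visits — produce dated records of
which insect visited which plant, pollen loads washed from captured
insects, and single-visit deposition (SVD) trials on virgin flowers.
`pollinet` turns these three table types into (i) weekly, annual, and
multi-year bipartite networks, (ii) their structural statistics, (iii)
resampling-based significance verdicts for those statistics, and (iv)
estimates of the pollination service delivered to a focal plant. A seeded
synthetic-community generator reproduces the statistical shape of such
data so the whole chain can be exercised and calibrated without field
data.

# Data model and week assignment

Three record schemas are read by `read_records()`: visitation
(`plant, insect, date, count`), pollen loads
(`individual, insect, date, plant_genus, grains`) and SVD trials
(`genus, family, grains, is_control`), plus a taxonomy-harmonization map.
Rows violating an invariant — visit counts below 1, negative grain
counts, control rows carrying a taxon name, records without a definite
date — are rejected and listed in a parse report rather than repaired:
undated observations cannot be placed in a week, and the whole analysis
is anchored on weeks.

Weeks are 7-day bins counted from a fixed season origin, June 1 of each
year by default (`assign_week()`, `add_season_weeks()`). The origin is a
month-day anchor shared by all years so that "week 3" denotes the same
calendar window in every season and cross-year comparisons of the same
week are meaningful. The choice of June 1 reflects the onset of the
snow-free season in the motivating system; any other anchor can be
passed. A week straddling a month boundary needs no special handling
under this convention — bins are purely day-count based.

Harmonization (`harmonize()`) maps every raw name through the taxonomy
table, errors on unmapped names rather than passing them through, drops
listed non-insect visitors (crab spiders and mites recorded by the
visitation protocol), and merges records that become identical after
renaming by summing visit counts, conserving the total.

# Network construction

`build_network()` aggregates visit counts into a plants x insects weight
matrix for a focal period; species with no interactions in the period are
excluded entirely, so "possible links" never count plant-insect pairs
whose phenologies do not overlap (forbidden links). `merge_pollen_links()`
adds pollen-transport information conservatively: a pollen load proves at
least one earlier visit, so each distinct (insect, plant genus) pair with
grains in the period adds exactly **one** visit instance, regardless of
how many individuals carried it or how many grains — and the link is
dated by the capture week, assuming short pollen residence on the insect.
Secondary pollen transport is ignored. Annual combined networks apply the
+1 rule per week and then sum the weekly networks, consistent with the
weekly dating of pollen links. `build_metaweb()` scores each link by the
number of weekly networks containing it, giving the multi-year persistence
view.

Pollen grains are identified to plant genus while visitation records may
be species-level; a pollen genus is attached to the unique visitation
plant of that genus when one exists and to a genus-level node otherwise.
The synthetic community sidesteps the ambiguity by using genus-level
plant names throughout.

# Structural metrics

All metrics operate on the pruned network (every species has at least one
link).

**Connectance.** Binary connectance is $L/(P \times A)$. Its weighted
counterpart follows the effective-partner (entropy) linkage-density
definition: with $H_j$ the Shannon entropy (natural log) of species
$j$'s interaction weights, $e^{H_j}$ is its effective partner count, and

$$LD = \tfrac12\Big[\sum_j \tfrac{m_{\cdot j}}{m}e^{H_j} +
\sum_i \tfrac{m_{i\cdot}}{m}e^{H_i}\Big], \qquad
C_w = \frac{LD}{P+A}.$$

A single link gives $C_w = 0.5$, as does any complete equal-weight
network — convenient closed-form anchors used in the tests. The entropy
is base-invariant because the exponential back-transform matches the
logarithm base.

**NODF.** The pairwise strict-inequality form: within each side, a
species pair with unequal fills contributes
$100\,|\text{shared partners}|/\text{fill(poorer)}$, ties contribute 0,
and NODF is the mean over all row pairs and column pairs. Because the
decreasing-fill condition is evaluated per pair, no global sorting is
needed and the statistic is invariant to species order; it agrees exactly
with vegan's fill-sorted implementation for the binary case. The weighted
variant replaces overlap with strict weight dominance and conditions on
strictly smaller marginal totals; ties again contribute 0. This strict
marginal-total rule differs from vegan's fill-ordered weighted variant,
so the weighted implementation is validated against a brute-force pair
enumeration oracle instead.

**Modularity.** Barber's bipartite modularity
$Q = \frac1m\sum_{ij}(w_{ij} - s_i t_j/m)\,\delta(g_i,g_j)$ is maximized
by a seeded multi-restart greedy heuristic: best-gain single-node moves
(including moves to a fresh module) alternated with pairwise module
merges until neither improves $Q$, restarted from the all-singletons
partition and from random labelings (20 restarts by default). On all
test networks small enough for exhaustive partition search (up to 9
species, up to the 21 147 partitions of 9 elements) the heuristic attains
the exhaustive optimum, and by construction it can never exceed it. Exact
numerical agreement with any particular published modularity value is not
claimed — stochastic module detection is only a lower bound, and the
original analyses' algorithm is unspecified.

Pollen-transport networks carry link presence, not visit frequency, so
their interaction strengths are not comparable to visit counts; they are
scored with binary metrics only (`metric_set()` coerces and warns).
Undefined metrics (NODF with both sides singleton, for example) are
reported as `NA`, never as 0.

# Null models

The resampling null asks whether an observed network looks like a random
same-size draw from a larger interaction pool (the 5-year metaweb for
annual networks; the year's annual network for weekly ones). A replicate
keeps the observed numbers of plants and insects, draws the species
uniformly without replacement (the minimal assumption — the source
analyses do not state a sampling law), inherits the induced link set, and
redraws each present link's strength from continuous
$\mathrm{Uniform}[\min, \max]$ over the source's positive weights
(resampling observed values is available as an option). Species isolated
in a replicate are kept as drawn and pruned only for metric computation,
exactly as observed networks are pruned; replicates with no links at all
are discarded, logged, and redrawn, with an abort after 10R consecutive
empty draws.

Verdicts use empirical order-statistic quantiles without interpolation
and strict inequalities: `low` below the 0.025 quantile, `high` above the
0.975 quantile of R = 1000 replicates. Under the null mechanism itself
the observed value is exchangeable with the replicates, so the two-tailed
rejection rate is $\approx 25/1001 + 26/1001 \approx 5.1\%$; the
calibration test checks the realized rate against the 99% binomial band
around 5% ([3.2%, 6.8%] at 1000 trials). The calibration uses weighted
connectance: replicate weights are continuous, so the metric is tie-free.
Binary metrics on small networks take few distinct values, and ties under
strict inequalities deflate the rejection rate — a discreteness property
of the verdict rule, not a miscalibration of the mechanism.

# Pollination service

`svd_table()` summarizes deposition trials at genus level (over
genus-resolved rows) and family level (over **all** rows of the family,
including genus-resolved ones, so the family mean is the best available
estimate for family-only visitors). Control-flower deposition is
summarized alongside but never subtracted from the means — contamination
on unvisited stigmas is reported as context, not treated as a baseline.

`estimate_service()` multiplies weekly visits to the focal plant by the
taxon's SVD mean, preferring the genus estimate and falling back to the
family estimate; taxa with neither are excluded with a warning (no
global-mean fallback). Annual and community totals are exact sums of
weekly rows, and the estimator is linear in visits by construction.

`activity_periods()` defines a taxon's flight period as the mean, over
the years in which it was observed at all, of the number of distinct
weeks with an observation. `service_vs_activity()` fits annual deposition
against activity period, a centered numeric year term, and their
interaction, then simplifies stepwise: the interaction is dropped when
its p-value exceeds 0.05 and the model refit, then the year term on the
same rule (the retention threshold operationalizes "nonsignificant").
Both multiple and adjusted $R^2$ are reported everywhere, because only an
adjusted value can be negative and single-number reports are otherwise
ambiguous.

Weekly pollen transport (`estimate_transport()`) averages loads over all
captured individuals of a taxon (zeros included) and scales back by the
number of individuals; how mean loads should scale to weekly "transport"
is genuinely underdetermined (per individual vs per visit), so the
per-individual choice is flagged in the output's `scaling` attribute.

# The synthetic community

The generator (`simulate_community()`) is the package's test bed and
defines the study conditions under which everything is validated:

* **Season and phenology.** 5 years of 13-week seasons; activity-window
  centers $\sim \mathcal N(\text{midseason}, 2\text{ wk})$ and widths
  log-normal (median 5 weeks). This is the simplest mechanism producing
  the unimodal midseason richness peak seen in weekly field networks; it
  is not fitted to any particular site.
* **Dominance.** The focal plant flowers all season and receives a fixed
  expected share (default 0.97) of every insect's visits; the remainder
  splits over the week's active plants by log-normal attractiveness.
  Realized shares land in [0.95, 0.99] at default sizes.
* **Skewed pollinator community.** Insect abundance is log-normal and
  positively correlated (0.6) with window width, so a few abundant,
  long-flying taxa dominate visitation — the structure that makes
  activity period predictive of total deposition.
* **Counts.** Weekly visits are Poisson; body loads negative-binomial
  (size 0.6, strongly overdispersed) scaled by the square root of the
  visit share so that rarely-visited plants still appear in pollen loads;
  SVD trials negative-binomial (size 2) around true genus means drawn
  from Uniform(10, 300); control flowers follow a zero-inflated
  negative-binomial tuned to a low-contamination summary (median ~2,
  mean ~19, SD ~45) as a soft calibration, not a test gate. Pollen loads
  are emitted for the final year only, mirroring a single pollen-washing
  campaign.
* **Ground truth** (windows, SVD means, expected focal visits and
  deposition) is returned beside the tables so parameter recovery can be
  scored.

What the generator does **not** emulate: observation-effort variation and
weather-dependent sampling gaps, secondary pollen transport,
heterospecific pollen, taxonomic mis-identification, and the
rare-species undersampling bias of real network data. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to those field realities.

Scenario presets (`scenario()`) freeze documented configurations:
`no_year_effect` zeroes interannual rate variation;
`strong_activity_effect` uses a small, fully SVD-covered community
(8 taxa x 5 years = 40 taxon-years) with abundance strongly tied to
window width and a narrow SVD-mean range (80-120 grains), so deposition
differences are activity-driven; `midseason_specialists` narrows the
diets of midseason-centered insects (1 + 3 x distance-from-midseason
non-dominant hosts), reproducing the pattern of lowest weekly connectance
coinciding with peak richness. The `strong_activity_effect` preset was
fixed after a design-stage power analysis across calibration seeds
showing all taxa present in all years and activity slopes detected at
p < 1e-6; the preset has not been changed since.

# Numerical choices and degenerate inputs

* Quantiles are raw order statistics (type 1), verdicts strict — matching
  the wording "lower than the 0.025 quantile or exceeding the 0.975
  quantile" exactly.
* Modularity uses gain tolerance 1e-12 to stop; the returned Q always
  recomputes from its own partition to within 1e-12.
* Empty periods signal a classed condition (`pollinet_empty_period`);
  weekly series constructors catch it and log the skipped week.
* A flat regression response returns slope 0 and $R^2 = 0$ exactly,
  avoiding the numerically meaningless ratios `lm()` summaries produce on
  zero-variance responses.
* All randomness flows from explicit seeds; the pipeline derives fixed
  per-stage substreams from one master seed, so reruns are byte-identical
  and single stages are independently reproducible.

# Problem sizes used in validation

The test-suite exercises: exhaustive two-plant enumerations (insect
counts 1-6); 1000 random 6x6 matrices against the NODF oracle; 50
networks of up to 9 species against exhaustive modularity search; 1000
calibration trials of 1000 replicates each for the null test (on an
8-plant x 14-insect single-season metaweb, 5x8 observed draws); 10 000
containment draws; 5 baseline replicates of the full community
(20 plants, 65 insects, 5 years) for parameter recovery; and 20 seeded
runs of the midseason-specialist scenario. These sizes were chosen so
each property is measured with comfortable statistical margin while the
suite stays quick to run.

# Known limitations

* The modularity optimizer is a heuristic; on large networks different
  seeds can return different near-optimal partitions.
* Pollen-genus matching attaches a link to a genus-level node whenever
  several congeneric plants occur in the visitation web — a conservative
  but lossy resolution.
* The null model conditions on species counts only; degree-preserving
  (swap) nulls are out of scope by design.
* Service estimates inherit every bias of the SVD trials (virgin flowers,
  single visits) and assume visits recorded in weekly networks are
  exchangeable with SVD-trial visits.
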