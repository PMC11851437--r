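# fibir — a fish-based index of biotic integrity for dammed rivers

Cascades of hydropower dams turn free-flowing rivers into chains of
reservoirs. Fish assemblages respond in a characteristic way: rheophilic
(flow-loving), drift-spawning and migratory species drop out, while lentic
and eurytopic generalists take over. `fibir` implements a complete
multimetric bioassessment workflow — a Fish-based Index of Biotic Integrity
(F-IBI) — designed for exactly this situation, where *every* site is
disturbed and reference conditions must come from historical species lists
rather than from pristine sites. It is written for quantitative ecologists
and river managers who have site-by-species presence/absence tables for a
historical and a current period, a species-by-trait table, and a description
of the dammed river network.

## The method

**Reference conditions from historical composition.** Sites are clustered on
their historical (pre-development) species composition: clustering tendency
is checked with the Hopkins statistic

> H = Σᵢ r′ᵢ / (Σᵢ rᵢ + Σᵢ r′ᵢ),

where rᵢ are nearest-neighbour distances of sampled data rows and r′ᵢ of
uniform reference probes (H ≈ 0.5 means no structure); similarity is the
Jaccard index S(a,b) = |A∩B| / |A∪B|; groups come from average-linkage
hierarchical clustering with the group count chosen by the gap statistic.
The historical species lists of each group are pooled (set union), and the
reference value `R_group` of each metric is the trait percentage of the
pooled list.

**Metric screening.** Candidate metrics are percentages of species carrying
each of 25 binary ecological traits. Three stages reduce them to a sensitive
set: (1) *redundancy* — for trait pairs with |Spearman r| ≥ 0.6, the member
more correlated with the endemic-species anchor is dropped; (2)
*discrimination power* — a box-plot overlap score (IQ 0–3) between
historical and current site values, keeping only IQ = 3; (3) *sensitivity* —
a metric is kept only if its current-minus-historical delta has the same
strict sign at every site.

**Scoring and grading.** Each retained metric scores
`SE1 = C / R_group` (metrics that decrease under disturbance) or
`SE2 = (Max − C) / (Max − R_group)` (metrics that increase), clipped to
[0, 1]. Site totals are sums over metrics; the expected total equals the
number of sensitive metrics. Totals above the 95th percentile of the
expected total grade *Excellent*; [0, P95] splits into four equal bands
(*Good*, *Fair*, *Poor*, *Very Poor*). Habitat classes (free-flowing
reaches vs reservoir transition zones) are compared with t-tests after
Kolmogorov–Smirnov normality and variance checks.

**Connectivity and drivers.** The time-weighted river connectivity index
averages, over the dam-commissioning history,
`RCI_i(k) = 100 Σⱼ w_i w_j p_ij(k)` with length weights `w_i = 2 r_i l_i / L`
and path passability `p_ij = Π p_m` (0 for complete barriers, 0.25 with a
fishway). A seeded random-forest regression attributes F-IBI variation to 11
human-pressure and environmental covariates (log10(x+1)-transformed), with
%IncMSE / IncNodePurity importances, leave-one-out validation, and
polynomial response-curve fits for the top four drivers.

**Synthetic scenarios.** Because such field data are rarely shareable, the
package ships a generator (`scenario_config()`, `simulate_scenario()`) that
plants all of this structure — cluster groups, directional and mixed-trend
trait responses, a dammed network, covariates — so every stage has a
recovery-based test.

## Worked example

```r
library(fibir)

cfg <- scenario_config(seed = 1)     # 12 sites, 139 species, 8 groups
scn <- simulate_scenario(cfg)

# 1. reference conditions
z <- standardize_occurrence(scn$historical)
hopkins_statistic(z, seed = 1)
#> Hopkins statistic H = 0.6307 (n = 4 probes)
sol  <- cluster_sites(jaccard_similarity(scn$historical), k = 8)
refs <- pool_references(scn$historical, sol, scn$traits)
refs$pool_sizes$n_species
#> 117 115 125 117 118 113 109 107

# 2. screening and scoring
mh  <- metric_values(scn$historical, scn$traits)
mc  <- metric_values(scn$current, scn$traits)
rep <- run_screening(mh, mc, scn$traits,
                     candidates = c("NFM","PF","HYF","CUF","LAF","SIF",
                                    "FLF","SPF","EF","EUF","DRF"))
sc  <- score_sites(mc, refs, rep)
sc$totals
#>    site  group total expected_total grade
#>  1 S01       1 3.89               8 Fair
#>  2 S02       1 3.08               8 Poor
#>  ...
#> 12 S12       8 0.496              8 Very Poor

compare_habitats(sc, scn$metadata)    # NRAD vs TR, t on totals: p = 0.19

# 3. drivers
cov <- prepare_covariates(scn$metadata)
dat <- dplyr::inner_join(sc$totals[c("site", "total")], cov, by = "site")
mod <- fit_driver_model(dat, "total", seed = 1)
mod
#> <fibir_driver> response 'total': 43.5% variance explained (OOB), LOO R2 = 0.44
#> top drivers: PRE, ALT, WA, TEM
fit_response_curves(dat, "total", top_drivers(mod))
autoplot(mod); autoplot(sc)
```

The Hopkins value above 0.5 says the historical composition is clusterable;
the screening retains the eight planted sensitive metrics with their planted
directions; totals fall with the planted downstream disturbance gradient
(Fair upstream to Very Poor downstream); and the forest attributes score
variation to covariates that track that gradient.

The connectivity module works on its own tables:

```r
segs <- tibble::tibble(id = c("up", "down"), length_km = 10, rank = 1)
barr <- tibble::tibble(from = "up", to = "down", passability = 0, year = 3)
trci(river_network(segs, barr), years = 1:4)$trci$trci
#> 37.5 37.5        # (100·(.25+.25) twice, then 25 twice) / 4
```

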