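---
title: "Methods: building and validating a fish-based index of biotic integrity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a fish-based index of biotic integrity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibir)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, how the synthetic-data
generator was designed, and where the open design decisions were settled.

## 1. The assessment model

The package assesses river health with a multimetric index built from
trait-percentage metrics: for a site with species set $S$ and binary trait
$m$, the metric is $100\,|\{s \in S: x_{sm}=1\}| / |S|$. All computation is
on species incidence, never abundance; the metrics are therefore
compositional (they describe *who* is present, and every metric is relative
to site richness).

The central difficulty in heavily developed rivers is that no undisturbed
site exists to serve as a spatial reference. The reference condition is
instead reconstructed from *historical* species lists: sites are clustered
on historical composition, each cluster group's member lists are pooled by
set union, and the pooled list supplies the expected (reference) value
$R_{group}$ of every metric. Pooling by union — rather than averaging site
values — assumes that sites in a group sampled one shared fauna
incompletely, which is the reason for requiring high within-group
similarity in the first place.

### Clustering tendency

Before clustering, the Hopkins statistic checks that the standardised
historical matrix is clusterable at all. We implement the standard
construction: $n$ probe rows are sampled from the data and their
nearest-other-row Euclidean distances $r_i$ compared with the
nearest-data-row distances $r'_i$ of $n$ uniform pseudo-points drawn in the
data bounding box, giving $H = \sum r'_i / (\sum r_i + \sum r'_i)$. A
procedure that drew *both* probe sets from the data would force $H \to 0.5$
by construction and could never signal clusterability, so it cannot be what
the interpretation rule ($H$ near 0.5 = no structure, towards 1 =
clusterable) intends; the uniform-reference construction is the only
self-consistent reading, and the test suite calibrates it on a uniform null
(mean $H$ over 200 seeds must sit in $[0.45, 0.55]$) and on separated
Gaussian blobs ($H > 0.75$).

Standardisation uses the population-variance convention (divisor $n$), so a
balanced 0/1 column maps exactly to $\pm 1$; constant columns are dropped
with a message since they carry no clustering information.

### Similarity, linkage, and the number of groups

Site similarity is the Jaccard index on species sets; clustering is
agglomerative on $1 - S$. The linkage is not dictated by the method, so we
default to average linkage (UPGMA), the conventional pairing with Jaccard
similarity in community ecology, and expose the argument. Two input spaces
are available — the Jaccard matrix (used for assignments, since the
similarity matrix is what the method defines) and the z-scored matrix with
Euclidean distance (used for the Hopkins statistic and the gap statistic,
whose uniform reference boxes presume a Euclidean geometry).

The number of groups comes from the gap statistic
(`cluster::clusGap`, B = 100 uniform reference data sets drawn over each
feature's observed range) with the first-local-max-within-one-SE rule:
the smallest $k$ with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) -
\mathrm{SE}(k+1)$. At twelve sites this rule is deliberately conservative:
on weakly separated compositional groups it often returns a small $k$
(sometimes 1), and only clearly separated structure earns a large $k$. The
tests therefore validate it on planted well-separated blobs, and users with
prior knowledge of the grouping (as in any real assessment, where the
dendrogram is inspected) can pass their own $k$ to `cluster_sites()`.

## 2. Metric screening

Twenty-five candidate traits enter three sequential filters.

1. **Redundancy.** Spearman correlations are computed between species-level
   binary trait vectors (not between site-level percentages: collinearity
   among traits is a property of the fauna, and twelve site values would
   estimate it poorly). For every pair with $|r| \ge 0.6$, the member with
   the larger $|r|$ to the endemic-fish anchor is dropped; the anchor
   itself is never dropped. When both members tie (e.g. both have zero
   anchor correlation), removal follows a user-supplied priority list,
   shipped with a default because the qualitative tie-break a practitioner
   would use ("which member responds more directly to dam construction")
   cannot be formalised from first principles.
2. **Discrimination power.** Historical site values (reference) and current
   site values (impaired) are compared by box-plot overlap: IQ 3 when the
   interquartile ranges are disjoint, 2 when they overlap but neither
   median lies in the other IQR, 1 when exactly one does, 0 when both do.
   Quartiles use linear interpolation (type 7), the most common convention;
   the choice only matters at sample sizes this small, which is why it is
   fixed and documented rather than configurable. Only IQ = 3 metrics
   proceed (`iq_min` is exposed for reuse in gentler settings).
3. **Sensitivity.** A metric is sensitive only if current minus historical
   has the same strict sign at every site. Zero deltas break the trend:
   "uniformly lower or higher" is read strictly, because a tie provides no
   evidence of direction and the downstream scoring needs an unambiguous
   direction per metric.

Every candidate receives exactly one fate
(`removed_redundancy` / `removed_discrimination` / `removed_sensitivity` /
`retained`), and fates are invariant to the order in which candidates are
listed.

## 3. Scoring and grading

Retained metrics score $SE_1 = C/R_{group}$ (decreasers) or
$SE_2 = (Max - C)/(Max - R_{group})$ (increasers), clipped to $[0,1]$.
Clipping is required for coherence: the expected total is defined as one
point per metric, and grade bands partition $[0,\ \mathrm{expected}]$, which
only makes sense if no metric can contribute more than 1.

$Max$ is not defined by the ratio method itself, so it is a documented
convention: by default the largest value the metric attains across all
current sites and all group references, which guarantees $SE_2 \in [0,1]$ on
the data at hand. Alternatives (`theoretical` = 100, `reference` = the
reference maximum) are one argument away. In the degenerate case where no
current value exceeds any reference value, the increaser is at or better
than reference everywhere and scores 1 (with a warning), since the ratio is
undefined but the ecological meaning is not.

Grading reads "the 95th percentile of the expected total" as the scalar
$0.95 \times \mathrm{expected}$ — a fixed number has no distribution, so the
percentile can only act as a proportional anchor. Totals above $P_{95}$
grade Excellent; $[0, P_{95}]$ splits into four equal lower-inclusive bands
(Very Poor, Poor, Fair, Good from the bottom; the Good band is closed at
$P_{95}$). For eight metrics this puts the Excellent threshold at 7.6 and
the band width at 1.9. The bands are exhaustive and non-overlapping on
$[0, \infty)$, which the tests check on a dense grid.

Habitat comparison uses an equal-variance two-sample t-test after a
Kolmogorov–Smirnov normality check (against a normal with the sample
moments) and an F variance-ratio check; when the variance check fails at
$\alpha = 0.05$ the Welch test is substituted. With six sites per class
these tests have little power — they are reported as descriptive statistics,
not as gatekeepers.

## 4. Connectivity

The time-weighted river connectivity index follows the
rank-and-length-weighted pairwise form
$RCI_i(k) = 100\sum_j w_i w_j p_{ij}(k)$, $w_i = 2 r_i l_i / L$, with the
path passability $p_{ij} = \prod_m p_m$ over barriers commissioned by year
$k$, and $TRCI_i$ the average of $RCI_i(k)$ over the evaluation window.
Three conventions are worth stating:

* the $j$-sum includes the self term $p_{ii} = 1$ (the empty product), so a
  single free segment scores exactly 100;
* under full passability $RCI_i = 100\,w_i$, i.e. the per-segment indices
  sum to 100 — the index apportions connectivity across segments rather
  than giving each segment 100, which is the only reading consistent with
  the defining sum and its worked cases (two equal segments split by a
  complete barrier each score 25, by a 0.25-passability fishway 31.25);
* barriers act from their commissioning year *inclusive*, and years before
  the first dam contribute the free-flowing index — otherwise a time
  average over the development history would be meaningless.

Monotonicity (adding a barrier or lowering any $p_m$ never raises any
$TRCI_i$) is enforced by randomised sweep tests. The ordinal covariate CTP
fed to the driver analysis is the dense rank of $TRCI_i$ (1 = least
connected, ties share a rank); the continuous index is exported alongside,
since the discretisation is a convention, not information.

## 5. Driver analysis

A regression random forest (1000 trees, `mtry` = one third of the
covariates, mandatory seed) regresses F-IBI totals — and, per metric, the
metric scores — on 11 covariates, `log10(x+1)`-transformed except the
ordinals HT and CTP. Both importance measures are reported; the "top four"
drivers are those ranking in the top four on *both* measures, with
permutation importance breaking disagreements. Explained variance is
reported twice, deliberately: the out-of-bag pseudo-$R^2$
$100(1 - MSE_{oob}/\widehat{Var}(y))$ and the leave-one-out $R^2$ from
refitting with each site held out, because a single "variance explained"
figure is ambiguous between the two and at $n = 12$ they can differ
materially (either can be negative when the covariates carry no signal —
reported as-is, not truncated).

Response curves for the top drivers are nested polynomial fits (degrees
1–3; twelve points cannot support more): the degree grows only while the
added term is significant at $p < 0.05$ by the nested-model F-test, with an
exact-fit guard that stops before the F-test divides by a zero residual.
Linear fits with non-significant slopes are flagged rather than suppressed.

## 6. The synthetic-data generator

The generator exists so that every stage has a *recovery* test: it plants
known structure and the pipeline must find it. Defaults are fixed at the
scale of the motivating study system — 12 sites on a dammed mainstem, 139
regional species, 25 traits, 8 cluster groups — with disturbance intensity
rising from 0.45 upstream to 0.95 downstream.

**Traits.** Species are drawn around a latent flow-dependence axis
$u \sim N(0,1)$: the four mutually exclusive families (mouth position,
water column, body form, egg type) are multinomial with $u$-tilted cell
probabilities, the free traits Bernoulli with $u$-loaded logits. Real trait
tables are strongly guild-structured — rheophilic, migratory and
drift-spawning habits co-occur in specialists, lentic habits in generalists
— and the redundancy screen presupposes exactly such correlation.
Independent trait draws were tried first and rejected: random overlap
between declining and thriving guilds attenuates every planted signal and
produces no collinear pairs for the redundancy stage to act on. Intercepts
and cell weights are calibrated numerically against the latent axis so
realised marginal prevalences match the configured targets (a non-zero
loading otherwise pulls prevalence towards 50%).

**Occupancy.** Cluster groups share species pools (each regional species
enters a pool with probability 0.85; pool species occur at member sites
with probability 0.95), which yields within-group Jaccard similarity above
the 0.6 floor the reference-pooling logic presumes. Species carrying the
rare spawning-guild traits (SIF, FLF, SPF) are treated as ubiquitous
tolerant generalists — present everywhere, persisting almost surely — which
mirrors the real systems these indices target (the widespread benthic- and
special-spawning generalists are precisely the species that survive
impoundment) and keeps percentage metrics built on three or four species
from flipping sign on single-species sampling noise.

**Disturbance.** Each historically present species persists with
probability $\mathrm{logit}^{-1}(\mathrm{logit}(0.98) + d_s\,(e_i - 3))$,
where $e_i$ sums the species' trait effects and $d_s$ is site disturbance.
Effects are *centred per site* (community-mean zero) so that $d_s$ alone
controls total mortality and the trait effects control which guilds die;
without centring, every neutral metric inherits a spurious uniform trend
from closed-composition drift, which is a property of percentage metrics
worth remembering when interpreting real screenings too. Default effect
sizes (e.g. planktivores and rheophils −5, lentic and terminal-mouth guilds
+3 to +3.5, rare spawning guilds +6) were chosen once to reproduce the
qualitative situation the method is built for — shifts large enough to give
disjoint historical/current IQRs and strictly uniform site trends for the
eight directional metrics — and the three mixed-trend traits (EF, EUF, DRF)
alternate effect sign across sites in three out-of-phase patterns, so the
sensitivity screen must discard them. GDP and land-use covariates are
coupled to disturbance (negatively and positively, respectively); the
remaining covariates follow the longitudinal structure of a large
subtropical river and are otherwise noise.

**What passing tests do and do not show.** The generator produces
presence/absence communities with guild-structured traits, shared group
pools, and monotone logistic persistence. It does not simulate abundance,
detection error, dispersal, temporal autocorrelation, taxonomic drift
between historical and current lists, or exotic invasion dynamics (a
minimal exotic-addition switch exists, off by default, because none of the
scored equations involve it). Recovery of planted structure therefore
demonstrates that the pipeline's inference is correct *given its own
assumptions*; it cannot certify performance on field data whose deviations
from those assumptions (especially uneven sampling effort between eras) are
the dominant error source in practice.

## 7. Problem sizes and determinism

Simulation-based tests and the acceptance script run at the study's natural
scale (12 sites × 139 species) with 50-seed Monte-Carlo loops for the
recovery properties, 200 seeds for the Hopkins null calibration, and B =
50–100 gap-statistic references — sizes at which every loop completes in
seconds while leaving the binomial noise visible. All stochastic functions
take explicit seeds; a scenario's single seed fixes the pool, the occupancy,
the network and the covariates, and forest fits refit with `seed + fold`
for leave-one-out.

## 8. Known limitations

* Reference values inherit any incompleteness of the historical lists;
  pooling by union mitigates under-sampling within a group but cannot
  manufacture unrecorded species.
* The strict-sign sensitivity screen is conservative by design: one
  anomalous site removes a metric. With many sites a binomial sign test
  would be the natural relaxation; at twelve sites strictness is the point.
* Grading anchors on the expected total, not on an empirical score
  distribution, so grades are comparable across applications but say
  nothing about the distribution of scores in any one basin.
* The connectivity index treats passability as year-round and direction-
  symmetric; seasonal fishway performance and downstream-passage mortality
  are out of scope.
* At twelve sites the random forest's explained variance is volatile across
  seeds and can be negative; the leave-one-out figure is the more honest
  of the two reported numbers, and neither should be read to two decimals.
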