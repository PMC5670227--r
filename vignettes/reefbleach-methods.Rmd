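---
title: "Heat stress, bleaching surveys and community statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat stress, bleaching surveys and community statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`reefbleach` implements the computational core of a regional coral-bleaching
assessment: cumulative marine heat-stress metrics from temperature-logger
series, photoquadrat and roving-survey bleaching scoring, the permutational
community statistics used to compare sites and times, and a synthetic-data
generator that stands in for field data. This vignette is the package's own
account of the models, the tunable parameters, the numerical choices, and
the limits of what a green test establishes.

## 1. Thermal stress: anomalies, DHD and DHW

Sub-daily logger records (nominally every 15 minutes) are averaged to
local-clock calendar days. A day is usable only when it holds at least
`min_coverage` (default 0.75) of the nominal record count; under-covered
days carry no mean. Day boundaries are taken from the printed local date
with no time-zone arithmetic, because loggers record local time and nothing
in the workflow requires anything finer.

The daily anomaly is `daily mean − MMM`, where the MMM (maximum monthly
mean) is the long-term mean SST of the site's warmest month, supplied as
configuration (this package never derives climatologies). Degree Heating
Days accumulate anomaly contributions over a trailing window of
`window_days` (default 84 days = 12 weeks) ending at the focal day:

- `all_positive` (default): every positive anomaly contributes in full.
  Under prolonged low-amplitude heatwaves — months of anomalies below
  1 °C — this is the more realistic accounting of cumulative stress.
- `noaa_ge1`: only anomalies ≥ 1 °C contribute, and they contribute their
  full value (HotSpot convention), not `anomaly − 1`. The defining
  description of this variant is one sentence — "accumulating only positive
  anomalies ≥ 1 °C" — so the full-value reading is a documented choice.

Degree Heating Weeks are `DHD / 7`. The bleaching threshold is `MMM + 1 °C`;
"exceeding the MMM" is strict `>` (equality would contribute 0 anyway).

Numerical and degenerate-input choices:

- Missing calendar days and incomplete days contribute 0 to DHD and are
  listed in a gap report. DHD is therefore a lower bound under data loss.
- Days with fewer than `window_days` predecessors are flagged
  `partial_window` rather than padded or dropped: real deployments commonly
  start less than 12 weeks before the first survey.
- Window convention: counting the focal day's reading as 1 day old, a
  reading exactly `window_days` old contributes fully and one
  `window_days + 1` old contributes nothing — i.e. dates in
  `(t − window_days, t]`.
- **Reported DHW is rounded up to one decimal** (`report_dhw()`). Upward
  rounding is the package's reporting convention for a risk index — the
  printed value never understates accrued stress — and it is the convention
  consistent with published DHD/DHW pairs such as 64.9 → 9.3 and
  16.4 → 2.4 (the latter is unreachable by round-to-nearest). Internal
  values are never rounded, and `dhw × 7 = dhd` holds to 1e-12 (exact
  equality is impossible in binary floating point since 7 is not a power
  of two).

## 2. Survey scoring

A photoquadrat is abstracted as a unit square tiled by labelled rectangles
(the stand-in for a segmented survey photograph): substrate category, plus
genus, morphology and health (`UB` unbleached, `M` moderately bleached —
under half the colony, or pale —, `S` severely bleached, `D` dead) for
hard-coral regions.

Point sampling is stratified random: for `n` points, a `g × g` grid with
`g = ⌊√n⌋` receives one uniform point per sub-cell and the remaining
`n − g²` points fall uniformly over the whole canvas. The guarantee that
every sub-cell holds at least one point is the property that makes
stratified counts lower-variance than simple random placement; with
`n = 100` the grid is exactly 10 × 10 and there is no remainder. The exact
sub-cell geometry of the original desktop scoring software is unpublished,
so this square grid is the package's own documented construction satisfying
the same guarantee. A useful consequence verified in the tests: region
boundaries aligned with the grid are estimated with zero variance.

Scoring assigns each point the label of its containing region; a point on a
shared boundary goes to the first region in file order (a deterministic
tie-break), and a point covered by no region — impossible for a tiling
map — scores `unknown` with a warning.

Percent cover supports two denominators: all points (substrate
composition) and hard-coral points only (health/genus composition of coral
cover). `unknown` points never enter coral-health denominators and can be
dropped-and-renormalised from substrate composition. Published health
summaries are ambiguous about whether "live coral cover" denominators
include dead colonies (dead corals appear in their own abundance rows), so
both bases are exposed; the default for health composition is all scored
hard-coral points including dead.

Site-level summaries treat **transects as the replicate unit**: class
percentages are averaged across the quadrats of a transect (a class absent
from a quadrat is 0 %, not missing), then mean and standard error
(`sd/√n_transects`) are taken across transects. A single transect reports
`SE = NA` rather than a fabricated 0.

Roving-diver tallies (used where cover is too sparse for transects) are
plain counts and percentages per health category, with strict validation of
health codes naming the offending record.

## 3. Community statistics

All statistics are computed from first principles in this package; the
reference multivariate package is used only as an independent oracle in the
test suite.

**Transform and dissimilarity.** Percent-abundance matrices (transects ×
genus-health classes) are square-root transformed — the state is tracked so
double transforms error — and compared with Bray-Curtis dissimilarity
`d(i,j) = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)`. Published descriptions phrase
this as "Bray-Curtis similarity"; the dissimilarity `1 − similarity` is
implemented, and the permutation tests are identical either way. A pair of
all-zero rows is defined as `d = 0` with a warning. Bray-Curtis is a
semimetric: symmetry, identity and `[0, 1]` bounds are asserted as
invariants; the triangle inequality is not.

**One-way PERMANOVA.** With `N` observations in `a` groups,
`SS_T = (1/N)Σ_{i<j} d²_ij`, `SS_W = Σ_g (1/n_g)Σ_{i<j∈g} d²_ij`,
`SS_A = SS_T − SS_W`, and
`F = (SS_A/(a−1)) / (SS_W/(N−a))`. Significance comes from unrestricted
permutation of group labels. The estimator `p = (b+1)/(n_perm+1)` includes
the observed statistic, so `p > 0` always and the test is valid (never
anti-conservative); permuted statistics tying the observed one count
towards `b`. An exact mode enumerates all `N!` permutations for small `N`.
On Euclidean distances of univariate data the statistic reproduces the
classical ANOVA F exactly — a special case the tests exploit.

**Two-way crossed PERMANOVA.** The Gower-centred matrix
`G = C(−½D²)C`, `C = I − 11′/n`, is projected onto sequential design
subspaces: A, then B adjusted for A, then the interaction adjusted for both
(Type I sums of squares; term order is the caller's choice and matters for
unbalanced data — the published tables list Time before Site, which is the
default here). Each pseudo-F uses the residual mean square. p-values come
from unrestricted permutation of the raw observations, recomputing every
term per permutation. This is the scheme of the desktop statistics package
the original analysis used, not the reduced-model residual permutation of
the primary PERMANOVA literature; the practical consequence, measured in
this package's simulations, is that the interaction test turns conservative
when main effects are large relative to residual scale (rejection ~0.02 at
α = 0.05 under main-effect shifts of 1–2 residual sd). Under moderate
effects it holds its size; the size simulation in the tests runs in that
regime, and the caveat stands here.

**Pairwise comparisons** are one-way PERMANOVAs per group pair with Holm's
sequential Bonferroni adjustment,
`p_adj(i) = max_{j≤i} min(1, (m−j+1) p_raw(j))` over ascending raw
p-values — implemented directly and cross-checked against the standard
adjustment routine.

**PCA** is an eigen-decomposition of the column variance-covariance matrix
of the (square-root transformed) abundance data — covariance, not
correlation, matching the desktop package's default since the original
choice is unstated. Sign convention: the largest-magnitude loading of each
component is positive. Eigenvalues within numerical zero are clamped to 0;
an all-identical matrix errors.

**Pearson χ²** uses `X² = Σ(O−E)²/E`, `E` from the margins, upper-tail
chi-square p. The default applies no continuity correction: the 2 × 2
table reconstructed from published colony counts (41/4 unbleached/bleached
versus 72/6) reproduces the printed statistic 0.05 only without Yates'
correction, which is available by flag. Zero margins error, naming the
margin.

## 4. The synthetic world

The generator produces the statistical structure the analysis assumes, not
ocean physics.

**Temperature.** `T(t) = mean_annual + seasonal cosine + daily tidal
sinusoid + heatwave + N(0, noise_sd)` sampled every 15 minutes. A tidal
amplitude of 3.5 °C yields the 7 °C daily range of an extreme macrotidal
intertidal pool. The heatwave is a plateau of `magnitude` °C with linear
ramps — the motivating event is a multi-month heatwave whose daily
anomalies mostly stay below `MMM + 1`, which is why the two DHD rules
diverge so sharply on it (the ≥ 1 °C rule can report zero through a
bleaching-grade event).

**Bleaching dose-response.** Health is ordered (`UB < M < S < D`), so a
cumulative-logit model maps accumulated stress to category probabilities:
`P(state ≥ k) = logistic((dhw − (θ_k + shift))/s)`. No quantitative
dose-response exists in the source material; the defaults are calibration
conveniences chosen once — `θ_M = 2`, `θ_S = 3.5`, `θ_D = 7` DHW, `s = 1` —
so that ~4.5 DHW produces a majority-severe subtidal community while the
baseline (0 DHW) community is ~88 % unbleached, echoing the observed field
contrast. Habitat tolerance is an additive threshold shift (intertidal
default +1 DHW), the simplest encoding of fluctuation-hardened thermal
tolerance; at the 4.5 DHW calibration point it separates subtidal from
intertidal severe fractions by roughly the published 75 % vs 53 % contrast.
At much higher doses the severe-only fraction is non-monotone (colonies
move on to dead), so ordering checks on "severe" alone are made at the
calibration dose and checks at saturating doses use severe + dead.

**Surveys.** Quadrat maps are built as labelled strips: abiotic categories
by the profile's substrate mix, the coral fraction split into colonies
(Poisson count, exponential widths) with genus drawn from the profile and
one health state per colony drawn from the dose-response. Assigning health
per colony, not per point, reproduces the overdispersion of real point
counts — points within a colony are perfectly correlated. Roving surveys
draw per-colony health directly, with diameters uniform on 2–150 cm.

Everything is reproducible: one master seed drives child seeds for every
quadrat, and identical scenario + seed gives byte-identical output files
(asserted in the tests).

**What the generator does not emulate:** spatial autocorrelation between
quadrats and transects, observer error, genus-specific thermal tolerance,
satellite-vs-logger discrepancies (the observed pattern of a remote reef
showing higher satellite DHW but lower bleaching cannot arise from this
monotone dose-response), tide-driven aerial exposure, or symbiont
dynamics. A green end-to-end test therefore establishes that the pipeline
recovers a known DHW contrast from data with realistic overdispersion — it
does not validate the dose-response against nature.

## 5. Pipeline and demo design

The `demo` configuration emulates a five-bioregion survey design along a
latitudinal gradient: a strongly heated remote tropical reef surveyed only
at the second time point, macrotidal intertidal/subtidal twins under a
moderate 150-day heatwave (identical water, different habitat tolerance), a
fringing reef and a high-latitude island with little or no stress, and a
temperate roving-survey site (45 and 78 colonies at the two time points).
Heatwave magnitudes were set once so the all-positive rule accrues roughly
9, 4.8/4.6, 0 and 2.8 DHW by the second survey while the ≥ 1 °C rule
accrues none — the diagnostic signature of a long, low-amplitude event.
The statistics stage runs the two-way time × site PERMANOVA over sites
surveyed twice, the one-way site comparison at the final time point with
Holm-adjusted pairwise tests, covariance PCA, and the roving χ². Default
permutations are 9999 in the stats functions (matching the published
analysis); the demo uses 999 for speed, and every output is stamped with
seed, permutation count and file hashes.

## 6. Known limitations

- Two-way designs use Type I (sequential) sums of squares only; for the
  balanced designs this package targets, the order is immaterial, but
  heavily unbalanced designs will see order-dependent term SS.
- The unrestricted permutation scheme's interaction conservatism under
  large main effects (above).
- The stratified sampler guarantees sub-cell coverage only for the
  `⌊√n⌋²` stratified points; the uniform remainder can double-cover cells.
- `report_dhw()`'s upward rounding is a convention; analyses needing
  round-to-nearest should round the unrounded `dhw` column themselves.
- Percentage SEs are computed on the transect means without finite-sample
  or compositional corrections, matching standard field-survey practice.
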