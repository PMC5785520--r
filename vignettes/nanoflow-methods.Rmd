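---
title: "Dynamic probabilistic material-flow and risk modelling with nanoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic probabilistic material-flow and risk modelling with nanoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoflow)
```

## The problem

Engineered nanomaterials (ENMs) such as nano-silica, nano-ceria and
nanosilver enter the environment from dozens of product categories, each
with its own market share, product lifespan and release behaviour. Almost
every input to an exposure assessment of these materials — global
production volume, market growth, the fraction of a product's ENM content
released during use, the split of end-of-life (EOL) mass over waste
streams — is deeply uncertain. nanoflow therefore treats every input as a
probability distribution and propagates them jointly by Monte Carlo
through a discrete, cohort-based release model spanning a century
(1950–2050 by default), down to predicted environmental concentrations
(PECs) and probabilistic ecological risk percentages for waters.

The model is a material-flow bookkeeping model, not a mechanistic fate
model: it contains no aggregation, dissolution or advection kinetics, and
no spatial resolution below the whole target region. Its outputs are
regional, annually averaged concentration distributions, useful for
screening-level tendencies — not for point-source hot spots.

## The release core

Mass enters the system in annual *cohorts*: `I(j)` is the mass of one
substance entering one application in calendar year `j` (t/a). Each
cohort is split, using sampled transfer coefficients (TCs), into

* a production-phase release (emitted in year `j` itself),
* a use-phase-destined fraction, released **uniformly** over the product
  lifespan `m`, the cohort year counting as the first release year, and
* the never-released complement, which leaves the product all at once
  `m` years after the cohort year as EOL mass.

The four series implemented in `use_release()`, `use_stock()`,
`eol_release()` and `eol_stock()` are

$$r_{use}(t) = \sum_{j=t-m+1}^{t} \frac{I(j)}{m}, \qquad
  S_{use}(t) = \sum_{j>t-m+1}^{t} I(j)\,\frac{m+j-t-1}{m},$$

$$r_{eol}(t) = I_{eol}(t-m), \qquad
  S_{eol}(t) = \sum_{j=t-m+1}^{t} I_{eol}(j).$$

The stock summation bounds are chosen so that both stocks satisfy the
exact identity *stock = cumulative input − cumulative release* in every
year; the test suite asserts this to machine precision on randomized
cohort series, which pins the one reading of the stock weights that is
internally consistent. The EOL-stock window is applied for all `t`
(a sliding `m`-year window), which reduces to the conventional two-regime
formulation for short horizons. With `m = 1` a cohort is fully released
in its own year and carries no stock.

Two exposure scenarios bracket the fate spectrum: `degradation_1yr`
assumes released material persists for at most one year in soils and
sediments (the annual flux is the standing load), while `persistent`
assumes no degradation, so the standing load is the running cumulative
sum of all previous releases (`accumulative_release()`). Waters and air
always carry a sub-annual residence time and are evaluated from the
annual flux in both scenarios.

## Inputs as distributions

`dist_spec` carries five families (point, uniform, triangular,
trapezoidal, lognormal) with a hard support: out-of-support draws are
rejected and re-drawn (with a clamp fallback for pathologically narrow
supports), so transfer coefficients and shares never leave [0, 1].

Conventions used throughout, chosen to match a min/mode/max reporting
style with finite supports:

* a ranged estimate `[low, high]` becomes uniform on that interval
  (optionally uniform in log10 for order-of-magnitude survey bins; the
  book flag `production_sampling` selects this, default linear, because
  nothing in a plain numeric range justifies log-weighting by default);
* "median x with 50% uncertainty/variability on each side" becomes
  triangular(0.5x, x, 1.5x) — `dist_spread(x)`. Applied to growth rates
  (so the post-2000 distribution is triangular(2.5, 5, 7.5) %/a and the
  pre-2000 one triangular(0.5, 1, 1.5) %/a), to single-value TCs, to
  ecotox endpoints, and multiplicatively to assessment factors
  (triangular(5, 10, 15) around 10).

Growth rates are drawn independently per calendar year and per
iteration (one macro path per substance shared by all its applications);
independence across years is the weakest assumption available absent any
stated year-to-year correlation, and the 50% band is read as a band on
the rate itself. Production estimates from different sources (survey
companies, literature) are mixed with equal weight — each draw picks one
source uniformly — and each source is rescaled from its own reference
year to the book's `reference_year` along the iteration's growth path.
Regional mass is the global draw times the ratio of regional domestic
demand to world GDP (dimensionless; both figures must share currency and
year).

Application shares are independent per-category fractions, not a forced
partition: a joint draw summing above 1 is renormalized to 1, a sum
below 1 leaves the remainder unallocated (it never enters the system).
The same proportional-rescaling closure is applied when a joint draw of
production-phase plus use-phase TCs exceeds 1, so the EOL complement is
never negative and per-cohort conservation is exact.

All parameters are sampled **once per iteration** and held constant over
the century — only growth varies by year — under substream seeds derived
from the master seed and a `(substance, application, role)` key
(`substream_seed()`), so extending a book never perturbs existing
draws.

## Compartments, treatment nodes and PECs

Released mass is routed by `compartment_flux()`: wastewater passes the
sewage-treatment node (`stp_transfer()`; sewer-connected mass splits by
the sampled removal efficiency into sludge and effluent, unconnected
mass bypasses to surface water), sludge splits between sludge-treated
soil and incineration, incineration eliminates a sampled fraction and
sends residues to landfill, and recycling returns nothing to the market
(a conservative closure treating technical sinks as terminal). A
configured fraction of the freshwater load is exported to coastal
seawater, and configured settling fractions map the water loads onto
fresh and marine sediment.

The freshwater, seawater and sediment loads intentionally describe the
*same* waterborne mass from different vantage points (the water PEC
represents the whole mass, dissolved and particulate; the sediment PEC
asks what would accumulate if the settling share persisted), so mass
balance is defined — and tested — at the level of the release streams:
per application and year, production + use + EOL fluxes plus the change
in both stocks equal the cohort input exactly.

Concentrations are plain dilution quotients (`pec_water()`,
`pec_soil()`, `pec_sediment()`, `pec_air()`): freshwater uses the
annual river throughput (m³/a) rather than a static volume — the load is
a flux, and a throughput denominator is the only choice that keeps the
freshwater PEC an annual average; seawater uses a static coastal mixing
volume; soils and sediments use area × depth × bulk density; air uses a
steady-state mixing volume × exchange rate. Default units: ng/L
(waters), ng/kg (soils, sediments), ng/m³ (air); 1 t into 10¹² L is
1 µg/L.

The shipped `synthetic_geometry()` provides order-of-magnitude
placeholders for a large industrialized country and is labelled
synthetic: real assessments must supply measured regional geometry.

## PSSD risk

For each species, every draw picks one of its endpoints uniformly and
transforms it to a chronic no-effect concentration: endpoint × U /
(AF_acute × AF_noec), where U is the 50% interval around 1 and each
applicable assessment factor is a draw of the 50% interval around 10
(acute factors apply to acute endpoints, effect-to-no-effect factors to
observed-effect endpoints; a chronic NOEC passes unchanged on the median
path). A probabilistic species sensitivity distribution (PSSD) is an
ensemble of curves (default 1,000), each built from one draw per species
sorted ascending with cumulative fractions `k/S`; ties are broken by a
deterministic 1-in-10⁹ jitter so curves are strictly increasing.

The risk percentage combines the probability of *critical PECs* (PEC
samples above the lowest concentration of any curve) with the
probability of *critical PSSDs* (curves whose most sensitive draw lies
below the highest PEC sample). The combination is their product — the
simplest reading of "combine" and the only one that yields 0% and 100%
at the no-overlap and full-overlap extremes; a `paired` alternative
(random PEC–curve pairing, joint exceedance frequency) is available in
`risk_percent()`. Risk is computed for fresh and marine water, for the
total load and the EOL-only load (kept as a separate accounting stream
through the whole pipeline rather than re-running the model); soil and
sediment compartments are refused because no terrestrial PSSD can be
built from aquatic endpoint tables.

## Reporting conventions

`summarize_samples()` reports sample extremes, the arithmetic mean, a
*most probable range* and a *mode*. The range is the 5th–95th
inter-percentile band — a convention for "range with some probability,
excluding simultaneous-extreme scenarios", configurable and not claimed
to equal any published band. The mode is the midpoint of the
highest-count bin of a Freedman–Diaconis histogram built on a log10 axis
whenever all samples are positive (outputs span orders of magnitude; a
linear-axis mode is available by flag). `report()` writes deterministic
CSVs: release to nature vs. technical sinks by origin stream, PEC
summaries per compartment × load × scenario, the aquatic risk table and
log-density exports for the default reporting years 2017, 2030 and 2050.

## The synthetic generator and what tests do (and do not) show

`generate_parameter_book()` emulates the *structure* of a transcribed
parameter inventory: two to three ranged production estimates per
substance with their own reference years; Dirichlet-derived application
shares whose central values sum into (0, 1]; lifespans of one to about
ten years; small triangular use/production TCs; EOL TC centrals summing
to exactly 1; the synthetic geometry; the default growth trend.
`generate_endpoints()` produces log-uniform endpoint tables whose
extremes are anchored to guarantee a span of at least three orders of
magnitude. Both are fully seeded. What they do **not** emulate is the
empirical content of any real inventory — correlations between shares
and lifespans, the actual silica/ceria/silver application spectra, or
measured endpoint values — so green tests on synthetic books demonstrate
the correctness and invariances of the machinery, not the realism of any
particular exposure prediction. Reproducing published summary tables
requires transcribing the corresponding parameter inventory into the
documented book layout, which the schema accepts without code change.

`toy_fixture()` is the deterministic anchor: flat 100 t/a, share 1,
lifespan 3, 30% lifetime release to surface water, full EOL to landfill.
Every downstream number has a closed form (use release ramps 10, 20,
30 t/a; EOL release 70 t/a from year 3; stocks 20→30 t and
70→140→210 t), asserted exactly in the tests.

## Numerical and design notes

* Cohort arithmetic uses cumulative-sum and short-convolution forms —
  exact, O(years) per iteration, no floating-point surprises at the
  magnitudes involved.
* Degenerate inputs: `m = 1` (no stock), empty TC maps (all mass
  retained), zero demand (zero regional mass), horizons shorter than a
  lifespan (warning; tail cohorts truncated) are all defined and tested.
* Typical problem sizes: 10⁴ iterations × 101 years × a handful of
  applications run in seconds; the test suite uses 10⁴ iterations for
  the scenario-ordering property and 10⁵ draws for distribution-level
  checks.
* Known limitations: no import/export trade beyond the demand ratio, no
  sub-annual dynamics, no in-use transformation chemistry (representable
  only as a TC to the elimination sink), no spatial heterogeneity, and
  risk only for aquatic compartments.
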