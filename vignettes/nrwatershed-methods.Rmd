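---
title: "Methods: the nrwatershed Nr-loss analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nrwatershed Nr-loss analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrwatershed)
```

`nrwatershed` implements a desk-scale analysis chain for reactive nitrogen
(Nr) losses from lowland watersheds: a per-pixel nutrient-delivery-ratio
(NDR) export model on routed terrain, Getis–Ord Gi\* cold/hot-spot mapping,
driver attribution by the geographical-detector *q*-statistic, moving-window
landscape metrics, and Markov-chain/cellular-automata (CA) land-use
scenarios with Nr re-evaluation. Everything runs on seeded synthetic
watersheds, so each stage is testable without external data. This vignette
records the model equations, the tunable parameters, the design choices made
where the design was genuinely open, and the limits of what the synthetic
tests demonstrate.

## Terrain substrate and routing

All layers share one north-up square-cell grid (`nr_grid`). Depressions are
filled by a Planchon–Darboux sweep with a small epsilon gradient
(`eps = 1e-6` m per step), which both raises pits to their spill elevation
and resolves flats, so every interior pixel ends up with a strictly lower
neighbour. Routing is **D8 single flow direction**: each pixel drains to its
steepest-descent neighbour (drops distance-weighted, diagonals by
$\sqrt 2$), ties broken by the fixed priority E, S, W, N, SE, SW, NW, NE.
Widely used NDR implementations route by multiple flow directions; D8 is a
deliberate deviation chosen so that every downstream quantity — upslope
area, flow-path distance, downslope retention — has an exact hand-traceable
oracle. Results are therefore deterministic and bit-reproducible.

Streams come from an explicit raster when available, otherwise from a
threshold of flow accumulation (TFA, default 50 pixels). A mapped network
can be burnt into the DEM (`burn_streams()`, default drop 10 m) before
filling, which pulls routed flow onto the real channels. Slope is a
central-difference rise/run fraction floored at 0.005 so that the
connectivity denominator below never divides by a vanishing slope.

## The Nr export model

Each land-use class carries an annual Nr load `load_n`
(kg N ha$^{-1}$ yr$^{-1}$), a maximum retention efficiency `eff_n`, a
critical transport length `crit_len_n` (150 m for every class), and a
subsurface proportion `prop_subs` (0 by default: with no class-specific
evidence, all load is routed as surface flow; both are configurable). Per
pixel,

$$\mathrm{Load}_{surf,i} = (1 - \mathrm{prop}_{subs,i})\,\mathrm{Load}_i,
\qquad
\mathrm{Load}_{subs,i} = \mathrm{prop}_{subs,i}\,\mathrm{Load}_i,$$

with $\mathrm{Load}_i$ the class rate converted once to kg per pixel
(cell area in ha = cell$^2/10^4$).

**Connectivity.** The index of connectivity is
$IC = \log_{10}(D_{up}/D_{dn})$ with
$D_{up} = \bar S \sqrt A$ (mean upslope slope fraction times the square
root of upslope area in m$^2$, self included) and
$D_{dn} = \sum d/S$ summed along the D8 path to the first stream pixel
(step length over local slope). $IC_0$ defaults to the midpoint of the
observed IC range, the conventional reference; it can be overridden.

**Downslope retention.** Walking upstream from the stream, with per-step
decay $s_i = \exp(-5\,d_i/\mathrm{crit\_len}(i))$, the effective downslope
retention is

$$\mathrm{eff}'_i = \begin{cases}
\mathrm{eff}_i\,(1-s_i) & \text{next pixel is a stream}\\
\mathrm{eff}'_{down} & \mathrm{eff}_i \le \mathrm{eff}'_{down}\\
\mathrm{eff}'_{down}\,s_i + \mathrm{eff}_i\,(1-s_i) & \text{otherwise,}
\end{cases}$$

and $NDR_{0,i} = 1 - \mathrm{eff}'_i$ is the maximum deliverable fraction.
$\mathrm{eff}'$ never decreases downstream and never exceeds the largest
class efficiency on the path.

**Delivery ratios.**

$$NDR_{surf,i} = NDR_{0,i}\left(1 + \exp\frac{IC_0 - IC_i}{k}\right)^{-1},
\qquad
NDR_{subs,i} = 1 - \mathrm{eff}_{subs}\left(1 - e^{-5\ell/\ell_{subs}}\right),$$

with $\ell$ the flow-path distance to the stream. The surface exponent is
oriented so that delivery *increases* with connectivity, the convention of
the model's standard user documentation; the source literature also
circulates with the opposite sign printed, so `ndr_params(ic_orientation =
"printed")` reproduces that form. Per-pixel export is
$x_{exp,i} = \mathrm{Load}_{surf,i}\,NDR_{surf,i} +
\mathrm{Load}_{subs,i}\,NDR_{subs,i}$, summed over masks for basin and
sub-basin totals.

Stream pixels deliver their own load in full ($NDR_{surf} = NDR_{subs} = 1$
at $\ell = 0$): water-class loads represent direct-to-water inputs, and
zeroing them instead would silently drop mass. This choice is exposed by
construction (a water row with `load_n = 0` recovers the alternative).

Key parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| `k` | logistic width of the connectivity response | 12.5 |
| `ic0` | connectivity midpoint | range midpoint |
| `crit_len_n` | class critical transport length | 150 m |
| `eff_subs` | max subsurface retention | 0.8 |
| `l_subs` | subsurface saturation distance | 150 m |
| slope floor | minimum slope fraction | 0.005 |
| TFA | stream threshold | 50 pixels |
| burn drop | stream burn depth | 10 m |

`k = 12.5` follows the calibrated value reported for a large lowland basin
of this type; `calibrate_k()` re-fits it against an observed basin total by
root finding (tolerance $10^{-3}$ relative), refusing targets outside the
attainable range (export can never exceed load). `eff_subs` and `l_subs`
have no literature value at this scale; 0.8 and 150 m (matching the
surface critical length) are package defaults, exposed in the configuration.

## Hotspot mapping

Pixel export is summed onto a square analysis lattice (default 1500 m,
pixel-centre rule); cells with less than half their pixels valid are
dropped, and the dropped remainder is tracked so the partition identity
(kept + dropped = basin total) always holds. The Gi\* statistic uses
self-inclusive binary queen contiguity on the lattice — the weight scheme
is not fixed by precedent, and queen-with-self is the common default for
gridded data; a fixed distance band is available. Categories use the fixed
two-sided normal thresholds 1.645/1.960/2.576 (90/95/99%), hot or cold by
sign. No multiplicity correction is applied, matching standard practice of
reporting raw confidence classes; on i.i.d. fields about 5% of cells exceed
$|z| \ge 1.96$ by construction, which the test suite checks.

## Driver attribution

The factor detector measures the share of spatial variance of the response
explained by a stratification:
$q = 1 - \sum_h N_h \sigma^2_h / (N \sigma^2)$, with *population* variances
so the counts cancel exactly ($q = 1 - SSW/SST$). Continuous drivers are
discretized by five methods — equal width, quantile, natural breaks (exact
Fisher–Jenks dynamic programming), geometric interval, and standard
deviation — over 3–8 strata, and the (method, strata) pair maximising $q$
is reported; ties prefer fewer strata, then method order. Categorical
drivers (land use, soil) stratify directly by their codes.

Significance is offered two ways. The conventional noncentral-F form uses
$F = \frac{N-L}{L-1}\frac{q}{1-q}$ with noncentrality
$\lambda = \big(\sum_h N_h \bar y_h^2 - (\sum_h \sqrt{N_h}\,\bar
y_h)^2/N\big)/\sigma^2$. Because $\lambda$ is estimated from the same data,
this test is strongly conservative near the null (its measured type-I error
is far below the nominal level; the suite's calibration check documents
this), while it still flags strong stratifications at vanishing p-values. A
seeded permutation test (default 999 label permutations) is provided as the
assumption-free alternative and is calibrated; use it whenever near-null
factors matter. The sampling unit is configurable; the pipeline default is
the hotspot analysis cell, which keeps samples approximately independent
and the Fisher–Jenks search cheap.

## Landscape metrics

Square moving windows (default side 1500 m, matching the hotspot lattice;
window size is an open choice and is configurable) shrink at raster
borders. Conventions, fixed and shared with the in-suite naive reference:
adjacency is rook with each unordered pair counted once; patches are
8-connected; SHDI $= -\sum p_k \ln p_k$; AI $= 100 \sum p_k\,
g_{kk}/\max g_{kk}$ with the largest-integer-square bound (a class whose
window area admits no adjacency counts as fully aggregated); CONTAG
$= 100\,[1 + \sum P_{ik} \ln P_{ik} / (2 \ln m)]$ with
$P_{ik} = p_i g_{ik}/\sum_k g_{ik}$ and CONTAG $= 100$ for single-class
windows; MESH $= \sum_j a_j^2 / A_{window}$ in ha. River density
approximates stream length from 8-neighbour connectivity (half a step per
connection, $\sqrt 2$ on diagonals, one cell length for isolated pixels).
Note that centred windows have odd pixel counts, so idealized two-class
values (e.g. SHDI $= \ln 2$ on a checkerboard) are attained exactly only
when the window's valid pixels split evenly.

## Scenarios

Transition accounting cross-tabulates two dated maps; demand projection
powers the row-stochastic matrix (horizon / interval steps — e.g. a 5-year
matrix taken 3 steps to a 15-year horizon) and rounds by largest remainder
so totals are conserved. Scenario presets modify transition probabilities
before projection: economic development raises conversions to cropland
(+60% from water, barren, grassland, forest) and to developed land (+100%,
also from cropland); ecological conservation doubles cropland-to-forest and
cropland-to-water, raises barren-to-forest/water by 80%, forbids forest and
water to developed outright, and reduces their other conversions by 40%;
the two constraint scenarios leave land use at the base map and act on the
biophysical table instead (fertiliser cut: cropland load × 0.70; nutrient
use efficiency: cropland retention 0.30 → 0.40). Combined scenarios
compose. After modification, row sums are restored through the diagonal
(persistence) first; if the off-diagonal mass exceeds 1 the row is rescaled
proportionally with a warning. Whether published scenario demands came from
modified Markov projection or exogenous targets is ambiguous in the source
material; this package implements modified-Markov throughout.

Suitability is a multinomial logistic regression of the later map's class
on driver values at sampled pixels (`nnet::multinom`, 2000 samples, seeded)
— a deterministic, dependency-light, probability-calibrated replacement for
the patch-based random-forest stage of large-scale land-use simulators,
which is out of scope here. Any model obeying the per-pixel
probabilities-sum-to-one contract can be substituted.

CA allocation grows deficit classes from surplus classes in descending
order of suitability × neighbourhood share × a small uniform jitter,
admitting candidates above a quantile threshold that starts at 0.9 and
decays by ×0.9 per round — the named decreasing-threshold mechanism with
package-chosen values, since no published values exist. Forbidden
transitions are never executed, donors are never drawn below their own
demand, and final counts match demand exactly; demand equal to current
areas returns the input bit-identically. Map agreement is scored by overall
accuracy and Cohen's kappa (chance-corrected; degenerate single-class
perfect agreement scores 1).

## Synthetic watersheds

The generator emulates a low-relief, cropland-dominated basin: a tilted
plane (drainage guaranteed; depression filling touches well under 1% of
pixels) plus smoothed Gaussian relief; clustered land-use patches from
per-class smooth score fields with water biased to low elevation, forest to
steep slopes, and developed land to flat lowland, with additive offsets
calibrated so realised proportions land within ±2 points of the targets
(default mix: cropland 52.45%, forest 11.66%, water 12.18%, developed
23.71%); later dates evolve by per-pixel draws from a stylized 5-year
transition matrix whose strongest flow is cropland → developed; drivers
(precipitation, population, GDP, soil, vegetation fraction) are smooth or
lognormal fields with designed correlations to the developed-class
indicator. Smoothing uses truncated Gaussian kernels (radius 3σ), not FFTs,
so output is independent of array size and bit-reproducible under a seed.

What the synthetic tests do **not** show: real basins have heavy-tailed
loads, seasonal dynamics, correlated driver errors, in-stream processing,
and land-use patch geometry far richer than thresholded Gaussian fields.
Passing tests demonstrate that the algorithms implement their definitions
exactly and respond with the right signs and magnitudes of *relative*
change — not that absolute exports match any particular basin.

## Numerical choices and problem sizes

Fill epsilon $10^{-6}$ m; D8 ties by fixed direction priority; stream
pixels excluded from IC (delivery handled at the retention step);
degenerate Gi\* (constant field) and degenerate $q$ (zero variance) are
errors, not silent zeros; empty strata are collapsed with a warning. The
test suite runs the full chain at deliberately small sizes — a 64 × 64
end-to-end preset, 24 × 24 mass-balance basins, 320 × 320 transition
recovery (10⁵ pixels), 40 × 40 CA allocation across 20 seeds — sizes chosen
so the whole suite exercises every contract in a few minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

Single-band ESRI ASCII raster I/O only (no projection handling or GeoTIFF);
D8 routing concentrates flow relative to multiple-flow-direction schemes,
biasing IC low on divergent slopes; phosphorus, in-stream decay and
seasonal dynamics are out of scope; the noncentral-F significance form is
conservative near the null (prefer the permutation test); the CA allocator
is a contract-faithful desk-scale stand-in, not a patch-morphology
simulator.
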