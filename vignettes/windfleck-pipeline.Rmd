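---
title: "From wind to windflecks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wind to windflecks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windfleckr)
```

windfleckr quantifies the chain by which wind moves a crop canopy and the
moving canopy, in turn, modulates the light climate inside it. The package
implements four analysis stages — motion quantification from video, windfleck
detection in high-frequency irradiance records, multi-rate synchronization,
and summary statistics — together with a seeded synthetic-data generator that
emulates all the field data streams, so every stage can be exercised and
tested end to end without any recordings. This vignette documents the models,
the tunable parameters, and the places where the design was genuinely open
and a choice had to be made.

## Quantity of motion (QOM)

Motion is measured by frame differencing. For consecutive video frames (RGB,
channel values in $[0,1]$, nominally 30 frames s$^{-1}$), the per-pixel
absolute difference is computed within each analysis zone for each channel,
aggregated within the zone, and the three channel aggregates are summed into
a single scalar per frame pair, the *quantity of motion*:

$$\mathrm{QOM} = \sum_{c \in \{R,G,B\}} \frac{1}{|Z|}\sum_{p \in Z}
 \left| I_{c,p}^{(n+1)} - I_{c,p}^{(n)} \right|^2 .$$

Three aggregation statistics are available. The default is the **mean of
squared absolute differences** (an uncentered second moment). The two anchor
properties any useful statistic must satisfy are: identical frames score 0,
and a uniform change from pure white to pure black scores 3 (one per
channel). A *centered* within-zone variance of the absolute differences
satisfies the first anchor but not the second — it is zero for any spatially
uniform change and bounded by 0.75 per channel — so it cannot be the intended
default even though "variance" is the word used colloquially for this
operation; it remains selectable (`statistic = "centered_variance"`), as does
the mean absolute difference (`"mean_abs"`, which shares both anchors).

Zone geometry: a user-supplied plot polygon (0-based pixel coordinates,
origin top-left; a pixel belongs to the polygon when its centre does) is
divided over its bounding box into a 16 × 9 cell grid, and cells are grouped
into analysis zones. The grouping of the 144 cells into zones is scene
metadata — it depends on where the light sensor sits and how the plot is
framed — so `zone_grid()` takes it as input and only supplies a contiguous
default for synthetic work.

Camera noise and compression artefacts also produce frame-to-frame pixel
change. Static *reference zones* (bare soil outside the plot) estimate that
noise floor; their mean QOM per frame pair is subtracted from each analysis
zone. The corrected QOM is floored at zero by default
(`floor_at_zero = TRUE`) because downstream analyses log-transform QOM and
bin it in exponential classes from $e^{-11}$: negative or zero values are
unclassable on a log scale. Flooring is a choice, not a theorem — the
uncorrected difference is available with `floor_at_zero = FALSE`.

QOM timestamps are placed at the midpoint of each frame pair; any convention
within the 1/30 s pair interval would do, but the midpoint keeps the series
unbiased with respect to either frame.

## Windfleck detection

Windflecks are brief increases in photosynthetic photon flux density (PPFD,
µmol m$^{-2}$ s$^{-1}$) measured at 100 s$^{-1}$ inside the canopy. Spectral
irradiance, if that is what was recorded, is first converted to PPFD by the
photon integral over 400–700 nm (trapezoidal rule on the native grid, range
cut at exactly 400 and 700 nm).

Detection proceeds by turning-point analysis:

1. **Turning points** are the samples where the first difference changes
   sign. A plateau (run of exactly equal values) contributes a single
   turning point. `find_turning_points()` reports it at the *first* index of
   the run. Internally, the detector keeps whole plateau runs: an event
   *starts* at the last sample of the minimum plateau preceding its rise and
   *ends* at the first sample of the minimum plateau that follows its fall,
   while a peak is reported at the first sample of its plateau. With this
   convention, a triangular pulse of base $w$ sitting on a flat baseline has
   measured duration exactly $w$ — the flat baseline on either side is not
   part of the event. Record boundaries count as pseudo-minima so events
   truncated by the start or end of a record are still delimited.
2. **Candidate events** are (minimum, maximum, next minimum) triples.
3. **Dual amplitude thresholds.** A rise that is smaller than 5 µmol
   m$^{-2}$ s$^{-1}$ *or* smaller than 5% of the event baseline is noise; a
   retained windfleck must pass both criteria. The baseline is the PPFD at
   the start turning point, and the intensity is peak minus baseline, which
   is why the relative criterion is evaluated against the start value rather
   than the smaller of start and end.
4. **Pruning.** Sub-threshold oscillations are removed iteratively: while
   any adjacent extremum-to-extremum transition fails the thresholds, the
   smallest-amplitude failing pair of extrema is deleted, merging its
   neighbours into a single transition, and amplitudes are recomputed.
   Smallest-first deletion makes the result independent of scan order and
   naturally protects enveloping peaks, because the smaller flank of a noise
   dip is always deleted before the dip's larger flank. How exactly the
   original field analyses eliminated these oscillations is not documented
   anywhere we could find; this rule is therefore a declared design choice,
   and the test suite validates it against an independently written
   brute-force implementation of the same rule rather than against any
   external ground truth.

Per event the package reports duration (end − start, s), intensity (peak −
baseline), and the *integrated PPFD increase*: the trapezoidal integral of
the trace over the event minus the integral of the chord joining the start
and end points, clipped at zero (an event with a concave interior could
otherwise integrate negative, which would be meaningless for an "increase").
Per record it reports the event count, the frequency (s$^{-1}$, and ×100 for
comparability with per-100 s tables), and the mean time between events (next
start minus previous end; undefined below two events).

Records with gaps of two or more sample intervals are split at the gaps and
processed per segment; any other deviation from uniform 100 s$^{-1}$
sampling is rejected rather than silently resampled.

Two behavioural notes that matter when interpreting output on *noisy* data:
after pruning, every surviving transition passes the thresholds, so
consecutive events share their boundary minimum and the mean time between
events collapses toward the plateau gaps actually present in the record; and
an isolated event's boundaries stretch to the surviving minima of the
adjacent quiet stretches, so durations on heavily noisy baselines read
longer than the underlying pulse. On clean or lightly noisy series (sensor
noise well below the 5 µmol threshold, as with the synthetic generator's
defaults) neither effect is material: baselines between events are flat
plateaus and event boundaries are exact.

## Synchronization

The three streams run on different clocks: PPFD at 100 s$^{-1}$, QOM at 30
s$^{-1}$, wind at 1 s$^{-1}$, with instrument start offsets of up to a few
seconds. QOM is linearly interpolated to 100 s$^{-1}$; wind is extended by
zero-order hold (each 1 s value repeated 100 times from its interval start
— no interpolation, hence the bar-like shape of plotted wind). The analysis
zone is chosen among user-supplied candidates (those nearest the light
diffuser, which is scene metadata) as the zone with the largest absolute
PPFD–QOM cross-correlation at any lag, ties broken by lowest zone id.

Cross-correlations are Pearson-normalized per lag on the overlapping
window, which makes the "largest absolute correlation" criterion scale-free;
the lag grid is symmetric and a positive lag means the second series is
delayed. The default window of ±500 samples (±5 s) comfortably covers
manual-start offsets while excluding spurious far-lag peaks; it is
configurable (`--max-lag-s`). Lags are integer samples — at 0.01 s
resolution, sub-sample refinement would be noise given fleck durations of
0.05 s and up.

The wind-record shift is the lag maximizing the *product* of the PPFD–wind
and QOM–wind cross-correlations, restricted to lags where the QOM–wind
correlation is positive (more wind producing less motion is physically
implausible, so such lags are ignored; if no lag qualifies the estimator
refuses with a typed error rather than guessing). The pipeline applies the
estimated shift to the wind record and additionally records the PPFD–QOM
argmax shift in the run report, since whether the original analyses
re-shifted QOM after zone selection is not documented.

## Trait formulas and statistics

* Natural frequency: $N = 3 / T$ where $T$ is the time for three
  oscillations of a displaced-and-released tiller (s).
* Leaf mass per area $\mathrm{LMA} = LM / LA$ (g cm$^{-2}$); height-to-mass
  ratio $\mathrm{HM} = H / TM$ (cm g$^{-1}$); leaf-to-stem mass ratio
  $\mathrm{LTM} = LM / (TM - LM)$ (g g$^{-1}$, undefined when $TM \le LM$).
* Binning: wind in 0.3 m s$^{-1}$ classes from zero; QOM in 15 exponential
  classes with edges $e^{-11}, \dots, e^{-2}$ (constant edge ratio). Classes
  are half-open $[lo, hi)$; a windfleck is assigned the class of the *mean*
  synchronized driver value over its start–end interval (robust to 0.01 s
  boundary jitter; the value at the peak instant of a step-held wind series
  would be a coin flip at step edges). Per-class frequency is events over
  time-in-class; classes with fewer than two events are reported missing.
* Cultivar indices: motion sensitivity = mean QOM / mean wind; light
  modulation efficiency = fleck frequency / mean QOM; each axis centred and
  scaled across the cultivar panel. A degenerate axis (zero SD) reports 0
  for every cultivar rather than failing.

### Variance decomposition and heritability

Broad-sense heritability of a variety mean is
$H^2 = \sigma^2_V / (\sigma^2_V + \sigma^2_r / n)$ with $n$ biological
replicates (blocks). The pure formula is exported as `heritability()`.

Estimating the components from a variety × block table is where a real
choice lives. Technical replicates are first averaged to cell means. The
residual variance $\hat\sigma^2_r$ is the pooled variance of cell means
about their variety mean. The naive plug-in — using the raw sample variance
of variety means as $\hat\sigma^2_V$ — is badly biased upward as an
estimator of the ratio, because the variance among variety means already
contains $\sigma^2_r / n$ of residual noise: with 10 varieties and 3 blocks
the plug-in overstates a true $H^2 = 0.2$ by about +0.34 on average.
`variance_decomposition()` therefore uses the canonical method-of-moments
correction $\hat\sigma^2_V = \max(\mathrm{var}(\bar x_v) -
\hat\sigma^2_r/n,\, 0)$, the standard line-mean heritability estimator in
plant breeding. REML (e.g. lme4) gives practically identical means at this
design size, so the dependency-free, deterministic moment estimator is
preferred.

Even the corrected estimator is not mean-unbiased at small designs: with 9
degrees of freedom among variety means, the inverse-moment bias of the ratio
is of order $(1-H^2)\cdot 2/(V-3)$ (about −0.06 at $H^2 = 0.5$ for 10
varieties × 3 blocks) and the truncation of negative $\hat\sigma^2_V$ at
zero lifts the mean at low $H^2$. The acceptance suite measures exactly this
recovery and reports it honestly; no estimator bounded in $[0,1]$ removes
both effects at once at this design size.

Repeatability is the proportion of total variance explained by block
effects, with $\hat\sigma^2_{block}$ obtained from the variance of block
means corrected by $\hat\sigma^2_r / V$ and floored at zero (block variance
components estimated as zero simply indicate negligible block-to-block
variation).

## The synthetic-data generator

The generator produces the study's data streams with known ground truth. It
is first-class, tested code, and its defaults are fixed study conditions,
not tuning knobs.

* **Wind** (1 s$^{-1}$): mean-reverting AR(1) with Poisson-arriving,
  exponentially decaying gusts (3 s time constant), compensated so the
  long-run mean equals `mean_speed`, clipped at zero. Field wind models are
  not part of the source analyses — only an observed range of roughly
  0.3–2.1 m s$^{-1}$ — so the defaults (mean 1 m s$^{-1}$, AR coefficient
  0.8, gust rate 0.05 s$^{-1}$, mean gust 0.6 m s$^{-1}$, innovation SD
  0.15) are chosen to cover 0–2.4 m s$^{-1}$ with realistic gust
  clustering, for coverage rather than site fidelity.
* **Motion** (30 s$^{-1}$): $\mathrm{QOM}(t) = a\,e^{b\,w(t-\mathrm{lag})}$
  — the exponential wind response observed across most cultivars — with the
  wind looked up by zero-order hold (matching the synchronization
  convention, so injected clock offsets are exactly recoverable) and
  corrupted by a mean-preserving lognormal multiplier with CV `noise_cv`
  (a Gaussian $(1+\varepsilon)$ multiplier could go negative; the lognormal
  keeps QOM strictly positive with the same first moment). Defaults
  $a = 0.0015$, $b = 1$ put mean QOM near 0.004 at 1 m s$^{-1}$ — inside
  the exponential class range — and roughly quadruple motion between calm
  and 1.5 m s$^{-1}$.
* **PPFD** (100 s$^{-1}$): an inhomogeneous event process with
  instantaneous rate `rate_gain` × QOM(t) (default 350 flecks s$^{-1}$ per
  QOM unit, giving order 1–2 flecks s$^{-1}$ at typical motion), each event
  adding a triangular pulse on a constant shaded baseline (200 µmol m$^{-2}$
  s$^{-1}$). Triangles make duration, intensity, and integrated increase
  analytically checkable. Pulse durations are lognormal with a 95% interval
  of about 0.05–0.44 s, the regime of field-measured windflecks; amplitudes
  lognormal around 120 µmol m$^{-2}$ s$^{-1}$. Pulses are centred on the
  drawn event time so the event process adds no systematic lag relative to
  motion. Sensor noise (SD 1.5 µmol) sits well below both detection
  thresholds, as it should for a calibrated spectroradiometer.
* **Frames**: a horizontally periodic sum-of-sinusoids texture fills the
  frame interior and is displaced frame-to-frame in proportion to the input
  motion signal (sub-pixel displacements are exact because the texture is
  analytic); a static textured border serves as reference zones.
* **Traits**: additive variety + block + residual normal effects, so the
  true $H^2$ is known from the parameters.

Every generator is a pure function of an explicit integer seed (no global
RNG state escapes). What the generator deliberately does **not** emulate:
spectra and their calibration, sun angle and penumbral geometry, canopy 3-D
structure, aerodynamic physics (drag, stiffness, neighbour interactions),
camera exposure artefacts, and video stabilization residue. Tests passing on
synthetic data therefore demonstrate the correctness of the *computational
chain* — detection, synchronization, estimation — not the fidelity of any
biological claim about real canopies.

## Numerical choices and degenerate inputs

* Uniform sampling is enforced to 10$^{-6}$ relative tolerance; plateaus are
  runs of *exactly* equal values (relevant for synthetic fixtures; measured
  100 s$^{-1}$ data essentially never repeats exactly).
* Cross-correlation sufficient statistics are computed with a zero-padded
  FFT and prefix sums (O($n \log n$), identical to the naive per-lag Pearson
  correlation to 10$^{-10}$); overlaps with zero variance in either segment
  give `NA` at that lag rather than a division error.
* Ties: zone selection prefers the lowest zone id; the pruning loop removes
  the earliest of equally small failing pairs; `which.max` over the
  correlation product takes the most negative of tied lags.
* Degenerate inputs fail loudly and early: empty zones, mismatched frame
  shapes, non-positive durations or oscillation times, negative variance
  components, thresholds below zero, shift estimation with nowhere-positive
  QOM–wind correlation (typed condition `wfl_no_valid_shift`).

## Problem sizes in the test and acceptance suites

The suites are sized to run comfortably on a single CPU: oracle equivalence
uses 1000 random-walk series of length 500; lag recovery uses 600 s bundles
(60 000 PPFD samples) over 4 offsets × 20 seeds with a ±250 sample window;
heritability recovery uses 2000 replicates of a 10 × 3 design per truth
value; motion monotonicity uses ten displacement levels on 64 × 64 px, 13
frame sequences. These sizes are the package's own choices for statistical
resolution, and the methods are O(n) to O(n log n) throughout, so larger
records scale linearly.

## Known limitations

* Frame differencing measures aggregate pixel change; it cannot distinguish
  movement types (stem rotation vs leaf flutter), and different movement
  types are unlikely to be captured with equal efficiency.
* The detector's duration and between-event statistics degrade on records
  whose baseline noise approaches the thresholds (see above); the dual
  5%/5 µmol threshold is the only noise defence by design.
* The variance decomposition assumes the randomized-block structure it is
  given; it is method-of-moments, not REML, and inherits small-sample ratio
  bias documented above.
* The synchronizer estimates one constant shift per record; clock drift
  within a record is out of scope.
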