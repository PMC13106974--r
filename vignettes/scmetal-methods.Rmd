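---
title: "Quantifying single-cell metal content from LA-ICP-MS traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell metal content from LA-ICP-MS traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmetal)
```

## Scope

scmetal converts time-resolved laser-ablation ICP-MS intensity traces into
analyte mass per individual cell. Its inputs are a counts-per-second (CPS)
trace for one analyte channel, an event log assigning trace windows to
labelled spots (cell, blank, or standard), and a run configuration. Its
outputs are per-cell integrated responses, masses in femtograms with QC
flags, calibration and drift diagnostics, group summaries and
Mann-Whitney comparisons. A separate path converts bulk-digest ICP-MS
concentrations (µg/L) to pg per million cells and fg per cell. Everything
upstream of the trace — instrument tuning, interference removal in the
collision/reaction cell, slide preparation — is out of scope: the trace is
taken as the instrument reports it.

## The signal model

A pulse-counting detector reads the channel once per dwell interval
$\Delta t$ (default 10 ms here). Counts in a dwell are Poisson; dividing
by $\Delta t$ gives CPS. An ablation event adds a transient pulse, a few
hundred milliseconds wide, on top of a flat background from the carrier
gas, residual solution and electronic dark counts. The total *counts*
under a pulse — not its height — are proportional to the ablated analyte
mass, which is why all quantification below integrates windows rather
than measuring peak heights.

## Background threshold from blanks

Cell-free spots on the same slide are ablated as blanks. Per blank the
mean CPS over its window is computed; the background threshold is the
unweighted average of the per-blank means. Averaging per-blank means
(rather than pooling samples) weighs each blank spot equally regardless
of window length, matching how an analyst checks blanks one by one.
Collection scheme (all blanks before/after the cells, or interleaved
every ~20 cells) does not enter the calculation; the threshold object
retains the per-blank spread so interleaved schemes can be inspected for
time trends.

Two methods are provided:

* `blank_mean` (default): threshold = mean of per-blank means. This is the
  conventional choice for well-separated cell signals.
* `blank_mean_plus_k_sigma`: adds `kSigma` × SD *of the per-blank means*.
  Note this SD is the spot-to-spot reproducibility, much smaller than the
  per-sample Poisson spread; for a noise-band threshold (e.g. to suppress
  detection in empty windows entirely) construct a `Threshold` directly
  from the pooled per-sample SD, which the object exposes as
  `blankPointSd`.

With the default blank-mean threshold roughly half of all pure-background
samples lie above the threshold, so empty windows generally contain small
super-threshold noise runs. This is intended: the same rule applied to
the 0 fg standard makes the calibration intercept absorb exactly that
background contribution (below).

## Peak boundaries and integration

Within a cell (or standard) window, the *core region* is the maximal
contiguous run of samples strictly above the threshold that contains the
global maximum; apex ties resolve to the earliest index, for determinism.
Boundaries then extend outward:

* `local_min_at_or_below` (default): the nearest sample at or below the
  threshold that is also a local minimum (≤ both neighbours; a window edge
  qualifies). This formalises "the first downward excursion at or below
  the background on either side of the peak": the boundary is placed in
  the first dip that actually reaches the background, so the pulse tail is
  retained instead of being cut at the first noise crossing.
* `first_at_or_below`: the nearest sub-threshold sample, a stricter
  alternative since the narrative description of such rules is genuinely
  ambiguous.

If a search reaches the window edge without a qualifying boundary, the
edge is used and the measurement is flagged `EDGE_TRUNCATED`. The
response is the plain sum of CPS between the boundaries (×Δt in counts
mode). Super-threshold runs inside the window are absorbed; any left
outside flag the measurement `MERGED_SUSPECT` (overlapping events are
flagged, never deconvolved). Cells with no super-threshold sample are
reported with response 0 and `BELOW_LOD` — they are kept in group
summaries by default (`includeBelowLod = TRUE`), because silently
dropping undetected cells inflates group means; the opposite behaviour is
one switch away.

No per-sample baseline is subtracted inside the window. Standards are
integrated with the identical rule, so the calibration intercept (the
0 fg standard included) carries the typical in-window background, and
subtracting the intercept during conversion removes it. This exchanges a
per-event correction for a calibration-level one and is exact insofar as
cell and standard windows contain comparable background; the residual
window-width mismatch between small cells and large standards is the main
systematic this choice tolerates (a percent-level effect under the
simulator's default conditions, visible in the end-to-end tests).

## Calibration, drift, and limits

Gelatin micro-droplet standards with nominal masses 0, 173, 351, 684,
1821 and 3455 fg are fully ablated and integrated like cells. Ordinary
least squares of response on mass, *with intercept*, gives slope $a$ and
intercept $b$; $r^2$ is the squared Pearson correlation. Replicates enter
individually (never pre-averaged), preserving residual degrees of
freedom. Weighted or robust regression is deliberately not offered.
Masses convert as $m = (S - b)/a$; a `slopeOnly` mode ($m = S/a$)
replicates the strict slope-only reading. Negative masses clamp to 0 fg
with `BELOW_LOD` unless `allowNegativeMass` keeps them for bias
diagnostics. A non-positive fitted slope is an error ("inverted
calibration"), not a warning.

Instrumental drift is modelled as a multiplicative sensitivity factor
anchored at repeated ablations of one reference mass (the highest in the
table by default, maximising counting precision per anchor): factors are
response ratios to the first anchor, piecewise-linearly interpolated and
clamped to the nearest anchor outside their span. All responses — cells,
standards, blanks — are divided by the factor at their acquisition time
before calibration. Anchoring one mass rather than refitting whole curves
per block needs the fewest standards; the cost is that drift *within* a
standard block is not corrected, which is why the simulator brackets its
ladder (below). Linear drift is corrected exactly between anchors,
because a ratio of linear functions sampled at the anchors interpolates
linearly in between.

Detection limits use the 3σ/10σ convention on the *integrated blank
responses*: LOD $= k_{LOD}\,\sigma_{blank}/a$ with $k_{LOD} = 3$, LOQ
with $k_{LOQ} = 10$. When only one blank exists the limits are undefined
and flagging is suppressed with a warning rather than invented.

## The simulator

`simulateRun()` generates one continuous acquisition with ground truth:

* Poisson counts per dwell around baseline + pulse expectation (a
  noiseless mode emits expectations exactly, for conservation tests);
* per-cell true masses from a zero-truncated normal — defaults mean
  1.83 fg, SD 0.27 fg, the published summary of resting human T-cell
  iron — or a moment-matched lognormal for heterogeneous (activated)
  populations;
* pulses Gaussian (default) or exponentially-modified Gaussian for
  tailing washout, with expected total counts = mass × sensitivity ×
  drift factor, normalised so all emitted counts land inside the event
  window;
* blanks (baseline-only windows) split half before, half after the cells;
* the six-mass standard ladder, `standardReplicates` blocks (default 2):
  the first block runs the ladder downward and the last upward, so the
  reference mass is ablated at the very start and very end and every
  other event falls between the drift anchors. This bracketing layout
  exists because the single-mass drift anchor leaves within-block drift
  uncorrected: with monotone block ordering that residual correlates
  with standard mass and biases the calibration intercept, whereas
  bracketing cancels it to first order (and exactly, for linear drift,
  once no event needs the clamped extrapolation region);
* optional linear sensitivity drift, `driftSlope` per second
  (default 0).

Fixed numerical defaults, chosen once on instrument-realism grounds:
dwell 10 ms, a typical quadrupole single-channel dwell; pulse FWHM
0.25 s, in the washout range of a low-dispersion ablation cell at a
20 µm spot (no pulse duration is published for this workflow, so this is
a declared assumption, configurable); 4 s per ablation window, enough
for the pulse support plus boundary search on both sides; sensitivity
10⁴ counts/fg and baseline 100 counts per dwell, which put a 1.8 fg cell
at ~1.8 × 10⁴ counts against a background the blank-mean threshold rule
must genuinely contend with; 20 blanks per run.

What the simulator does *not* emulate: aerosol transport physics and
washout memory between adjacent spots, spot-to-spot sensitivity
variation other than smooth drift, spectral interferences (assumed
removed upstream), droplet-volume variability of the standards, and cell
fragmentation or partial ablation. Passing tests therefore demonstrate
the correctness of the *analysis* under a faithful counting-statistics
model, not robustness to every artefact of real acquisitions.

## Numerical and degenerate-input choices

* Trace validity: strictly increasing times, uniform spacing within 1e-6
  relative, dwell within 1% of the median spacing; violations are
  errors with row numbers, never silent repairs.
* Event windows are half-open `[t_start, t_end)` so one sample can never
  belong to two adjacent windows; indices in `Peak` objects are 1-based
  inclusive, as everywhere in R.
* All-zero blanks give threshold 0 with a warning (a dead channel should
  be noticed, not crash a batch); zero blank spread gives LOD 0 with a
  warning.
* Apex ties → earliest index; equal-response drift anchors → factors
  exactly 1; times outside the anchor span → clamped factor.
* Exact Mann-Whitney p values are used for `min(n) ≤ 8` without ties,
  the tie-corrected normal approximation otherwise; no multiplicity
  correction by default (each panel's comparisons are reported as-is),
  Holm adjustment by flag.
* Replicate bulk measurements below the LOQ are excluded from means,
  never zero-imputed; a sample is BLQ only when all its replicates are.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
brute-force enumeration for peak boundaries (1000 random Poisson
segments of length ≤ 200), closed-form normal equations for the OLS fit,
full enumeration of rank assignments for the exact Mann-Whitney p (all
group sizes ≤ 6), hand unit-chains for the bulk conversion, and exact
count conservation for noiseless pulses. The end-to-end check simulates
100 cells at the defaults (seed 7 in the suite) and requires the
pipeline's group mean within 5% of the true population mean and
per-cell RMSE within 10%; drift correction is validated on matched
drift/no-drift runs of 50 identical-mass cells. These sizes keep the
whole suite well under a minute while leaving the statistical assertions
3σ-sized margins.

## Known limitations

* Overlapping or doublet ablations are flagged (`MERGED_SUSPECT`), not
  resolved.
* The intercept-based background removal assumes cell and standard
  windows see similar background totals; very wide standards against
  very narrow cells leave a small negative bias in cell masses.
* Single-mass drift anchoring cannot see drift within a standard block;
  run layouts should bracket (reference mass first and last), as the
  simulator does.
* The blank-derived threshold assumes blanks and cells share the same
  background; contamination localised to cell-bearing regions is
  invisible to it.
* LOD/LOQ follow the 3σ/10σ convention on integrated blank windows of
  the same nominal duration as cell windows; other window policies change
  the limits proportionally.
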