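---
title: "Degradation kinetics, validation statistics and fragment annotation with stabindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation kinetics, validation statistics and fragment annotation with stabindr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabindr)
library(dplyr)
```

## What the package models

A stability-indicating assay answers two questions about a drug substance:
how fast does it degrade under stress (acid, base, heat, light, oxidant),
and can the analytical method quantify the intact drug in the presence of
whatever the stress produced? `stabindr` implements the computational side
of that workflow for an HPLC-DAD / LC-ESI-QTOF-MS study: degradation
kinetics with half-life and shelf-life estimation, ICH Q2 validation
statistics, chromatographic system-suitability metrics, and
elemental-composition annotation of high-resolution fragment ions. A set
of seeded generators emulates the instrument outputs so the entire
pipeline is testable without instrument data.

The worked example threaded through the package is vortioxetine (VOR), a
thioether-containing antidepressant that degrades appreciably only under
oxidative and photolytic stress, producing seven characterized degradation
products (DP1–DP7).

## Degradation kinetics: the substitution method

Concentration–time series are fitted by linearising each candidate rate
law and running ordinary least squares:

| order | model | linearisation | k |
|---|---|---|---|
| 0 | $C = C_0 - kt$ | $C$ vs $t$ | $-$slope |
| 1 | $\ln C = \ln C_0 - kt$ | $\ln C$ vs $t$ | $-$slope |
| 2 | $1/C = 1/C_0 + kt$ | $1/C$ vs $t$ | $+$slope |

The order whose linearisation gives the highest $R^2$ wins (the
"substitution method"); exact ties go to the lower order and are flagged.
Two deliberate choices here:

* **$R^2$ on the transformed scale.** The comparison is between straight
  lines, exactly as the linearised kinetic plots are drawn; computing
  $R^2$ on back-transformed concentrations would favour the order with
  the mildest transformation rather than the best-fitting law.
* **Linearised OLS, not nonlinear least squares.** NLS would weight the
  data differently and is not what the substitution method does. The
  linearised fit is the reproduction target; nothing prevents a user from
  running `nls()` on `predict_conc()` if they want the alternative.

Half-life and shelf-life come from the closed forms
$t_{1/2} = 0.693/k$, $t_{90} = 0.105/k$ (first order) and
$t_{1/2} = 1/(kC_0)$, $t_{90} = 1/(9kC_0)$ (second order); zero-order
formulas ($C_0/2k$, $0.1\,C_0/k$) are the standard extensions. The
constants 0.693 and 0.105 are the traditional rounded values used in
pharmaceutical stability work and are the package default, because they
are what printed stability tables are computed with; `exact = TRUE`
switches to $\ln 2$ and $\ln(10/9)$. The difference matters at the second
decimal: $0.693/0.1043 = 6.64$ h but $\ln 2/0.1043 = 6.65$ h. Under the
default constants the identity "concentration at $t_{1/2}$ equals
$C_0/2$" holds to about $10^{-4}$ relative (the rounding of 0.693); under
`exact = TRUE` it is exact to machine precision.

**$C_0$ convention.** $t_{1/2}$ and $t_{90}$ for orders 0 and 2 depend on
$C_0$. The package uses the measured concentration at $t = 0$ by default
(overridable), which in a forced-degradation design is the nominal
working concentration — 20 µg/mL in the vortioxetine study. Using the
fitted intercept instead would fold fit noise into the reported
half-life.

```{r}
kin <- vortioxetine_kinetics()
kin
tibble::tibble(
  condition = kin$condition,
  t_half = mapply(half_life, kin$order, kin$k, kin$c0),
  t90    = mapply(shelf_life, kin$order, kin$k, kin$c0)
)
```

A full screen on simulated data:

```{r}
tc <- gen_time_course(1, k = 0.1043, c0 = 20, times = 0:6,
                      noise_rsd_pct = 2, seed = 42, replicates = 3)
scr <- select_model(tc, c0 = 20)
scr
```

## Mass-domain arithmetic and composition assignment

Monoisotopic masses use CODATA/NIST atomic values for C, H, N, O, S
(dumped to CSV by `write_element_masses()` for audit); the proton
(1.00727646 Da) and electron (0.00054858 Da) masses handle adducts and
charge states. `[M+H]+` with electron correction adds exactly one proton
mass. The formula grammar is plain Hill notation with no parentheses,
isotopes or in-string charges — charge state belongs to the ion
convention, not the formula.

`decompose_mass()` enumerates every CHNOS composition inside per-element
bounds whose ion m/z falls within a ppm tolerance of a target. The search
iterates C/N/O/S counts and solves the admissible hydrogen-count interval
from the mass window analytically, so it is exhaustive within bounds
without enumerating the H axis. Candidates are ranked by |ppm error|;
compositions with RDBE $\ge -0.5$ are preferred and more negative RDBE is
filtered by default (even-electron fragment cations legitimately produce
half-integer RDBE, so no nitrogen-rule filter is applied). The ranking
rule is |ppm| first because no more specific rule is defensible without
intensity modelling.

`annotate_peaks()` has two calculation modes:

* **computed** (default): calculated m/z derived from the element mass
  table under the adduct convention — the scientifically defensible mode;
* **provided**: each candidate carries its own calculated m/z.

The provided mode exists because published annotation tables are not
always reproducible from standard atomic masses: in the vortioxetine
table shipped with the package (`vortioxetine_fragments()`), the reported
"calculated" masses for most compounds differ from standard monoisotopic
arithmetic by far more than the reported ppm errors (e.g. the protonated
molecular ion C18H23N2S$^+$ computes to 299.1576 but is reported as
299.1981), while the reported (observed, calculated, ppm) triads *are*
internally consistent. Reproducing the reported ppm errors therefore
requires taking the reported calculated masses as inputs — exactly what
provided mode does. The default matching tolerance is 15 ppm, just above
the largest |error| in that table (11.35 ppm).

```{r}
fr <- vortioxetine_fragments()
ann <- annotate_peaks(
  transmute(fr, compound, condition, ion_type, mz = mz_observed),
  transmute(fr, compound, formula = ion_formula, mz_calculated),
  tolerance_ppm = 15, calc_mode = "provided"
)
build_annotation_report(ann) |> head(5)
```

## Validation statistics

`fit_calibration()` is OLS of peak area on concentration with
$LLOD = 3.3\,SD/|S|$ and $LLOQ = 10\,SD/|S|$. The "SD of response" is the
calibration residual SD $\sqrt{SSE/(n-2)}$ by default (ICH permits
several choices; the intercept SE is available via `sd_mode`). %RSD is
always computed with the sample (n−1) standard deviation. Percent
degradation uses the measured unstressed-sample area as the reference —
an explicit input, not the nominal concentration — which is why small
negative values are representable and returned unclipped.

```{r}
cal <- gen_calibration(slope = 49940, intercept = 31468,
                       noise_sd_area = 19976, seed = 7)
glance(fit_calibration(cal))
```

## System suitability

`measure_peak()` estimates the baseline as the median of the
window-edge samples (first/last 5%, at least 3 points) and the noise as
their MAD; a peak must rise 3× the noise above baseline. The apex is
refined by parabolic interpolation through the three highest samples and
the fractional-height crossings by linear interpolation between samples,
so metrics converge to their closed forms as the sampling grid refines.
Plate count uses the current compendial half-height formula
$N = 5.54\,(t_R/w_{1/2})^2$ (tangent variant $16\,(t_R/W)^2$ available);
the asymmetry factor is $b/a$ at 10% height and the USP tailing factor
$(a+b)/2a$ at 5%; both heights are the conventional ones, stated here
because published methods often omit them. The default column length for
N/m is 0.15 m (a 150 mm analytical column).

```{r}
trc <- gen_chromatogram(tibble::tibble(tr = 7, sigma = 0.0757,
                                       tau = 0.02, height = 1.2),
                        baseline_sd = 0.002, seed = 4)
peak_metrics(trc, window = c(6, 8), t0 = 1.6827)
```

## What the generators emulate — and what they do not

* `gen_time_course()`: exact rate-law decay times a log-normal
  multiplicative error of stated %RSD. Multiplicative, because peak-area
  noise scales with concentration (stress-test SDs are roughly
  proportional to the measured level, ~0.5–1% RSD in practice; 2% is
  used as a conservative stress level in the property tests).
* `gen_calibration()`: linear detector response with additive Gaussian
  area noise; defaults reproduce a realistic 1–100 µg/mL, 7-level,
  triplicate design.
* `gen_chromatogram()`: exponentially-modified-Gaussian peaks — the
  standard tailing-peak model, chosen because real methods report
  asymmetry > 1 but no shape data — plus linear drift and additive noise.
  The EMG trailing wing is evaluated through the scaled complementary
  error function with a reflection identity and an asymptotic tail, so
  the shape is finite over the whole trace; $\tau = 0$ reduces exactly
  to a Gaussian.
* `gen_fragment_spectrum()`: exact ion m/z times $(1+\varepsilon)$,
  $\varepsilon \sim N(0, \text{ppm} \times 10^{-6})$ — the multiplicative
  error structure of TOF mass accuracy.

Every generator takes a `seed` and evaluates under `withr::with_seed`,
so outputs are bit-reproducible and the caller's RNG stream is never
disturbed. At zero noise each generator inverts exactly through its
analysis stage; that is tested, and it is what makes the round-trip
properties meaningful.

What passing these tests does **not** show about real data: detector
saturation and nonlinearity, gradient artifacts, co-eluting
interferences, heteroscedastic area noise at the LLOQ, isotope patterns
and multiply-charged envelopes are all outside the noise models. The
generators validate the algorithms, not the instruments.

**Replicate structure.** Degradation studies typically inject each time
point in triplicate (n = 3), and the stochastic model-selection
properties in the test suite use that design: with single injections at
2% noise, first-order selection against the close second-order
alternative succeeds in only ~80% of replicates, while the triplicate
design raises this to ~96% — a genuine statistical statement about how
much replication the substitution method needs when candidate laws are
nearly collinear over a short sampling window. The generator default
remains a single injection per time point for generic use.

## Numerical choices and degenerate inputs

* Report rounding is half-up (2 decimals for percentages, ppm and hours;
  4 for k and $R^2$), matching how printed tables round; machine-readable
  outputs keep full precision.
* A zero-variance response (all areas equal, or constant concentrations)
  is flagged (`zero_variance`) rather than producing a numerically-zero
  slope and a nonsense LLOD; $R^2$ is reported as 0 for a constant
  series.
* Time courses must include $t = 0$ unless $C_0$ is given explicitly;
  orders 1 and 2 require strictly positive concentrations.
* Order-0 predictions are floored at zero with a warning.
* Composition-search bounds are closed integer intervals per element;
  an all-zero composition is excluded.
* Pipeline reports are byte-identical across reruns of one configuration;
  timestamps appear only in the log.

## Problem sizes used in the shipped tests

The test suite works at the scale of the underlying study: 6–7 point
time courses (200 Monte-Carlo replicates for the stochastic
properties), 7-level triplicate calibrations, traces of $\le$ 12,000
samples, and composition searches over bounds of roughly
C≤10, H≤20, N≤4, O≤4, S≤2 verified against an exhaustive nested-loop
oracle on 100 random targets. These sizes were chosen to exercise every
code path at the study's own dimensions.

## Known limitations

* Only CHNOS compositions and ±H adducts; no isotope-pattern scoring,
  no multiply-charged species.
* Single-peak measurement per window; no deconvolution or resolution
  between peak pairs.
* The DAD peak-purity index is not computed (no defined algorithm to
  implement); purity values in shipped data are carried as annotations.
* Arrhenius extrapolation across temperatures is out of scope; rate
  constants are condition-specific.
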