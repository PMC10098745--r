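---
title: "Methods: coaxial-cell permittivity extraction and the synthetic liver cohort"
author: "coaxperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coaxial-cell permittivity extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaxperm)
```

This vignette is the package's account of its science: the measurement
model, the extraction algebra and its numerical edge cases, what the
synthetic cohort generator does and does not emulate, and the design
decisions that were genuinely open.

## 1. The measurement model

A tissue sample of length $L$ fills the holder of a coaxial transmission
line; air lines of lengths $d_1$ and $d_2$ connect it to the calibrated
reference planes of a two-port VNA. Defaults are the real cell this package
targets: $L = 3$ mm, $d_1 = d_2 = 96$ mm, 50 $\Omega$ reference, 100 MHz to
2 GHz in 191 points (10 MHz spacing, so 1 GHz is a grid point).

Only the TEM mode is modelled. Below 2 GHz in a cell of these dimensions no
higher-order coaxial mode propagates, so this is not a restriction in the
intended band. The sample is assumed non-magnetic ($\mu_r = 1$); the
extraction returns permittivity only.

**Sign convention (package-wide).** Time dependence $e^{+i\omega t}$ and
$\epsilon = \epsilon' - i\epsilon''$, so passive media have
$\epsilon'' \ge 0$ and forward-propagating waves carry phase factors
$e^{-ikz}$. The convention is chosen so loss spectra plot positive.

With the normalized wave impedance $1/\sqrt{\epsilon}$ and the propagation
factor $T = e^{-i(\omega/c_0)\sqrt{\epsilon}L}$, the filled section has

$$\Gamma = \frac{1-\sqrt{\epsilon}}{1+\sqrt{\epsilon}},\qquad
S_{11} = \frac{\Gamma(1-T^2)}{1-\Gamma^2T^2},\qquad
S_{21} = \frac{T(1-\Gamma^2)}{1-\Gamma^2T^2},$$

implemented in `sampleSParams()`. The model is reciprocal and symmetric;
for lossless media $|S_{11}|^2+|S_{21}|^2 = 1$ to $10^{-9}$, a property the
tests assert.

## 2. Calibration triple and de-embedding

A session measures three sweeps: the loaded cell ("measurement"), a
short-circuit standard and the empty cell. `deembedSParams()` corrects
magnitude and phase separately:

$$|S_{ii}^{s}| = \frac{|S_{ii}^{m}|}{|S_{ii}^{sc}|},\quad
|S_{ij}^{s}| = \frac{|S_{ij}^{m}|}{|S_{ij}^{em}|},\quad
\varphi_{ii} = \varphi_{ii}^{m}-\varphi_{ii}^{sc}-\pi,\quad
\varphi_{ij} = \varphi_{ij}^{m}-\varphi_{ij}^{em}-kL,$$

with $k = \omega/c_0$. Conventions that the algebra itself does not fix,
decided here and verified by the exactness property
(de-embedding inverts the synthetic embedding to $10^{-9}$ per frequency):

* **Empty-cell span.** The empty-cell transmission reference is taken to
  span the full $d_1 + L + d_2$ path. This is why the $-kL$ term appears:
  the reference includes an air-filled holder the sample replaces. It is
  the only reading under which the identities above are exact.
* **Short placement.** The $-\pi$ correction is applied symmetrically to
  both ports, i.e. an ideal short (reflection $-1$) is referenced at each
  sample face.
* **Phase wrapping.** All phase arithmetic is done on principal values and
  re-wrapped to $(-\pi, \pi]$; the correction identities hold modulo
  $2\pi$, so wrapping loses nothing.
* **Reference magnitudes are used as measured.** Dividing by
  $|S_{ii}^{sc}|$ rather than assuming a unit-magnitude short means line
  loss in a real cell is compensated; for the ideal synthetic references
  the divisor is exactly 1.

Both ports are processed independently; no S11/S22 or S21/S12 averaging
happens at this stage (it is an option of the extraction instead).

## 3. Nicolson–Ross extraction

`extractPermittivity()` inverts the filled-section model per frequency.
The interface reflection solves a quadratic whose two roots are reciprocal;
`selectReflectionRoot()` keeps the root with $|\Gamma|\le 1$. Numerical
decisions:

* **Radical form.** The quadratic-discriminant form
  $\Gamma = X \pm \sqrt{X^2-1}$, $X = (S_{11}^2-S_{21}^2+1)/(2S_{11})$, is
  used with the principal complex square root; the equivalent product form
  $C=\sqrt{(S_{11}+S_{21}+1)(S_{11}+S_{21}-1)(S_{11}-S_{21}+1)(S_{11}-S_{21}-1)}$
  is implemented alongside and the two agree to $10^{-12}$ on random
  passive instances (tested). Because the physical root is re-selected by
  the magnitude rule, the sign printed in any particular rendering of the
  equations is irrelevant.
* **Tie-break.** For exactly lossless samples both roots can have unit
  modulus; the root with non-negative real normalized wave impedance
  $\mathrm{Re}\,(1-\Gamma)/(1+\Gamma) \ge 0$ is kept — deterministic and
  physically motivated.
* **Matched samples.** $S_{11}=0$ (an $\epsilon = 1$ "sample") leaves
  $\Gamma$ undefined; frequencies with $|S_{11}| < 10^{-10}$ take a
  transmission-only path $\epsilon = (i c_0 \ln T/(\omega L))^2$.
* **Branches.** $\ln T$ carries a $2\pi n$ ambiguity. Default: $n = 0$
  everywhere (`branchMode = "fixed"`). For the default cell and
  tissue-like media ($\epsilon' \le 80$, $f \le 2$ GHz, $L = 3$ mm) the
  electrical phase $(\omega/c_0)\mathrm{Re}\sqrt{\epsilon}\,L$ stays below
  $\pi$, so the principal branch is provably correct; the tests assert the
  precondition explicitly before relying on it. `branchMode =
  "continuity"` seeds the lowest frequency and then chooses $n$ per
  frequency to minimize $|\epsilon(f_k)-\epsilon(f_{k-1})|$, searching
  $|n| \le 10$. Since phase accumulates downward ($T = e^{-i\varphi}$),
  recovery on electrically long samples uses negative $n$; the test suite
  demonstrates both the failure of $n=0$ and the recovery by continuity on
  an 8× length cell.
* **Non-physical transmission.** $|T| \ge 1 + 10^{-6}$ on a nominally
  passive sample is a noise artifact: the frequency is flagged (flag 1)
  and a warning raised, but extraction continues. $T = 0$ is a hard error.
* **Port averaging.** Off by default. `portAverage = "reciprocal-mean"`
  (arithmetic mean of the reflections, sign-resolved geometric mean of the
  transmissions) is available for noisy measured data; on symmetric data
  it is the identity (tested).

The closed form is cross-checked against an independent oracle: a
brute-force least-squares inversion of the forward model over
$(\epsilon', \epsilon'')$, seeded by a coarse grid search, agrees with the
closed form to $10^{-8}$ relative on random passive instances.

## 4. Tissue models and anchor calibration

Liver tissue in this band is represented by a single-pole Debye model with
a static-conductivity loss term,

$$\epsilon(\omega) = \epsilon_\infty +
\frac{\Delta\epsilon}{1+i\omega\tau} - i\frac{\sigma_s}{\omega\epsilon_0},$$

(Cole–Cole broadening and extra poles are supported but unused by the
defaults). `calibrateAnchor()` fixes $(\Delta\epsilon, \sigma_s)$ in closed
form from a single complex anchor value given $(\epsilon_\infty, \tau)$,
and round-trips to $10^{-9}$ relative (tested).

The two canonical models are package constants:

| model | $\epsilon_\infty$ | $\Delta\epsilon$ | $\tau$ | $\sigma_s$ | $\epsilon(1\,\mathrm{GHz})$ |
|---|---|---|---|---|---|
| healthy | 6 | 36.14 | 10 ps | 0.500 S/m | $\approx 42.0 - 11.25i$ |
| fatty (HFS) | 6 | 25.10 | 10 ps | 0.3194 S/m | $\approx 31.0 - 7.31i$ |

The 1 GHz real parts (42 and 31) and the 35% loss diminution are the
group-level anchors the models are calibrated to. $\epsilon_\infty = 6$ and
$\tau = 10$ ps are plausible placeholder values for liver in this band — no
relaxation parameters are published for this cohort — and everything
downstream depends on them only through the anchored 1 GHz values, which is
why the calibration-from-anchor construction was chosen over fixing
$\Delta\epsilon$ directly.

## 5. The synthetic cohort generator

`generateCohort()` emulates the realized study conditions: 6 control and 10
HFS animals (the enrolment was larger; the defaults follow the cohort that
was actually measured), group anchors $\epsilon'(1\,\mathrm{GHz})$ of
$42 \pm 2$ and $31 \pm 3$ (mean ± SD), HFS loss at 65% of healthy.
Mechanics:

* Inter-animal variability enters through the 1 GHz anchor (truncated
  normal draw, bounded retries), which is then re-calibrated to a full
  Debye model. This keeps the printed group SDs directly enforceable,
  rather than guessing SDs for $\Delta\epsilon$ or $\tau$.
* The per-animal $\epsilon''$ target scales with the animal's own anchor
  relative to its group mean, times the group loss ratio — so the
  group-mean loss ratio equals the configured 0.65.
* Instrument noise: multiplicative magnitude noise (SD 0.5%) and additive
  phase noise (SD 0.5°), independent per frequency and parameter, applied
  to all three sweeps. These are typical bench-VNA repeatability figures,
  chosen once as an assumption — no noise level is published for the
  instrument in question.
* Biochemistry: hepatic triglycerides follow a linear-in-$\epsilon'$ mean
  ($\mathrm{TG} = 66 - 1.2\,\epsilon'(1\,\mathrm{GHz}) + N(0, 1.5)$,
  clipped to the group range: HFS in [20, 40] mmol/100 g as reported,
  control below 20 — [8, 19.5] by default, a choice, since only the HFS
  range is printed). This builds the negative TG–permittivity association
  into the cohort. Hepatic glucose is drawn uniformly inside overlapping
  group windows within [0.4, 0.6] mg/mg protein, emulating the reported
  non-separability of the groups on glucose alone. Plasma values and
  body/liver weights are non-authoritative placeholders carried for
  interface completeness.

**What passing tests do and do not show.** The generator produces exactly
TEM-consistent sweeps with ideal references and white instrument noise.
Real measurements add connector discontinuities, imperfect OSLT
calibration, cable drift, sample-loading variability (air gaps, compression)
and post-excision tissue drift — none of which are modelled. Tests passing
on synthetic cohorts validate the algebra, the statistics and the plumbing;
they do not validate hardware-specific error correction.

## 6. Statistics

`summarizeGroupSpectra()` reports per-frequency mean, sample SD ($n-1$) and
s.e.m. $= \mathrm{sd}/\sqrt{n}$. The ±10% band around the group mean is a
fixed fractional repeatability envelope (as drawn in this literature), not
a confidence interval, and is named accordingly (`band_lo`/`band_hi` with a
`bandFraction` argument).

`compareGroups()` runs Shapiro–Wilk per group, then a two-tailed unpaired
t-test. "Unpaired t-test" is read as Student's pooled-variance test — the
default meaning of the phrase in GraphPad Prism, the tool this analysis
chain mirrors — with Welch behind an option. Degenerate inputs: two
constant equal groups give $t = 0, p = 1$ (and an undefined Shapiro–Wilk,
reported as `NA`); constant unequal groups are an error. No
multiple-testing correction across frequencies is applied: the group
contrast is tested at a single stated frequency (1 GHz by default in
`analyzeCohortDir()`), matching how such cohorts are analysed.

`percentDiminution()` is $100(\bar x_{ctrl}-\bar x_{HFS})/\bar x_{ctrl}$.
Note a quirk the package deliberately exposes rather than hides: the 1 GHz
real-part anchors give $(42-31)/42 = 26.2\%$, while a commonly quoted
round figure for this contrast is 25% — whether that figure is
band-averaged or simply rounded is not stated anywhere, so the package
computes and reports, and asserts nothing against 25.

The Pearson correlation in `associationAtFrequency()` is this package's
choice of summary for the permittivity–biochemistry scatter (the source
material shows scatter plots only); $r$ is reported as `NA` for constant
covariates.

## 7. Problem sizes and runtimes

The test suite builds every fixture in code. Deterministic algebraic
properties run on 5–61-point grids; the full-band round-trip suite uses the
191-point default grid over $\epsilon' \in \{2, 10, 42, 80\} \times
\tan\delta \in \{0, 0.1, 0.5, 1\}$; the statistical recovery property uses
200 seeded cohorts at default size, and the type-I calibration of the test
chain uses 10,000 null replicates at $n = 6$ vs 10 — sizes chosen so the
Monte-Carlo error is small against the tolerances being asserted while the
whole suite stays interactive (well under a minute).

## 8. Known limitations

* Permittivity only: $\mu_r = 1$ is imposed; magnetic materials need the
  full NRW system.
* The classic Nicolson–Ross division-by-$S_{11}$ instability near
  half-wavelength resonances is not stabilized (no iterative
  Baker–Jarvis refinement); for the 3 mm cell in-band this regime is never
  entered, and the precondition is asserted rather than assumed.
* No VNA error-box modelling: inputs are assumed OSLT-calibrated at the
  reference planes.
* No uncertainty propagation from the S-parameters to $\epsilon$; the
  cohort-level spread is handled statistically instead.
* Tissue models are single-pole by default; broadband fits of measured
  spectra (multi-pole Cole–Cole) are out of scope because no measured
  spectra are available to fit.
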