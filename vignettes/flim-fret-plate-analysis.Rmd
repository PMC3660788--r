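---
title: "Methods: time-gated FLIM-FRET plate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-gated FLIM-FRET plate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the decay and noise
models, the reconvolution scheme and why it is built the way it is, what the
synthetic-data generator does and does not emulate, the numerical choices
that matter, and the known limitations.

## The assay

A donor fluorophore (a CFP-like fluorescent protein fused to HIV-1 Gag)
decays mono-exponentially with lifetime $\tau_D \approx 2950$ ps when free.
When Gag aggregates into virus-like particles at the plasma membrane, FRET
between tags shortens the donor decay to $\tau_F \approx 766$ ps
(homo-FRET between CFP tags; a hetero-FRET CFP/YFP pair behaves similarly
with $\tau_F \approx 713$ ps). A pixel's decay is a mixture of FRETing and
non-FRETing donors, so an N-myristoyltransferase inhibitor that blocks
membrane binding shifts the mixture towards the long lifetime in a
dose-dependent way. The instrument is a wide-field time-gated system: a
gated intensifier opens for a fixed width at programmable delays after each
excitation pulse, so the raw datum is a stack of photon-count frames, one
per gate delay.

## Gate model

Gates are boxcar integrals, not instantaneous samples: the expected count
in the gate at delay $t_k$ with width $w$ is
$\int_{t_k}^{t_k+w} (\mathrm{IRF} \otimes f)(t)\,dt$ where $f$ is the
multi-exponential decay. The default schedule is 16 gates equally spaced
over 0–8000 ps with $w$ equal to the spacing (contiguous gates), spanning
$\approx 2.7\,\tau_D$; expected counts are normalised over the schedule so
that the configured photon budget is the expected total per pixel. The
instrument response is Gaussian with 150 ps FWHM centred 500 ps after the
first gate opens (a delay is required so that no gated signal mass falls
before the first gate; see below). Counting noise is Poisson and is the only
noise source — the photon-counting regime is the stated precision model, and
the suite verifies the $1/\sqrt{N}$ law directly.

Internally the generator evaluates the Gaussian$\,\otimes\,$exponential
convolution in closed form (the exponentially modified Gaussian, computed
in log space so the early-time wing underflows instead of overflowing) and
integrates it over each gate by the trapezoid rule on a fine grid (10 ps
default) that contains every gate boundary exactly.

## Reference reconvolution

Rather than measuring the instrument response directly, the fitting is
calibrated by the measured gated decay $R(t)$ of a short-lifetime dye
standard with known $\tau_{ref}$ (DASPI-like, 50 ps). Because
$R = \mathrm{IRF} \otimes \tau_{ref}^{-1}e^{-t/\tau_{ref}}$ implies
$\mathrm{IRF} = R + \tau_{ref}\,dR/dt$, the predicted sample signal for
components $(\beta_i, \tau_i)$ is

$$ I(t) = I_0 \sum_i \beta_i \left[\tau_{ref} R(t) +
   \left(1 - \tfrac{\tau_{ref}}{\tau_i}\right)
   (R \otimes e^{-t/\tau_i})(t)\right]. $$

Both sides of the identity commute with the boxcar gate filter, so it holds
exactly between the *gated* reference and the *gated* sample. The causal
convolution is computed by an exponential recurrence that is exact for a
piecewise-linear $R$; `reconvolved_model()` applies it directly on whatever
grid the reference provides, and the test suite checks it against
brute-force numerical convolution to better than $10^{-3}$.

**Why the default path calibrates the reference parametrically.** On the
default schedule the reference is a spike of width
$\sim\sigma_{IRF}+\tau_{ref} \approx 120$ ps sampled by 533 ps gates: two or
three gates carry essentially all its mass. No sample-level interpolation
(linear, spline, or cumulative-mass reconstruction) can recover the curve
between such samples, and during development each of these variants produced
a 7–20 % systematic underestimate of fitted lifetimes, concentrated in the
rise gates. The default fitting path therefore fits the *position and
width* of a Gaussian instrument response — with $\tau_{ref}$ known — to the
measured reference counts by profiled nonlinear least squares (a 2-parameter
problem that 16 gate integrals constrain well), rebuilds the reference curve
on a fine grid, and applies the identity above there. With this scheme the
noiseless self-consistency error is $\ll 1$ ps and the Monte-Carlo bias at
$10^4$ photons is below 0.2 %, which the acceptance tests assert. The cost
is a parametric assumption (Gaussian IRF) that is exactly true for the
generator but only approximate for a real instrument; for finely sampled
references the nonparametric identity path needs no such assumption.

The IRF centre must sit at least its own tails after the first gate delay:
gated signal at negative delays cannot be measured, and its missing mass
biases every convolution term (measured at −16 % in lifetime during
development when the pulse sat too close to the gate origin).

## Fitting

* **Weights.** Poisson (Neyman) weights $w = 1/\max(y, 1)$ throughout,
  including every oracle, so implementation and oracle minimise the same
  objective.
* **Mono-exponential fits.** The amplitude enters linearly and is profiled
  out in closed form; the lifetime is then a one-parameter
  Levenberg–Marquardt iteration with analytic (spline-tabulated) shape
  derivatives, run vectorised over all pixels at once. Model shapes per
  lifetime are tabulated on a 320-point log grid (40 ps – 30 ns) and
  interpolated with natural cubic splines; the interpolation error is
  $\sim 10^{-9}$ relative, and `fit_monoexp()`/`fit_pixelwise()` agree to
  $10^{-6}$.
* **Initialisation.** Log-linear regression on the last half of the gates
  (deterministic, seed-free); amplitude from total counts.
* **Convergence.** Relative lifetime change below $10^{-6}$ or 200
  iterations; the `converged` flag is honest, and all-zero decays return a
  non-converged result with an undefined lifetime.
* **Thresholding.** Pixel-wise fitting only runs where the summed counts
  reach the photon threshold (200 by default); an image with no such pixel
  carries a `no_pixels` flag, which feeds the "no cells found" path of the
  plate statistics.
* **Bi-exponential global binning.** Step 1 pools every condition's counts
  and fits the shared short lifetime $\tau_2$ with $\tau_1$ fixed (profiled
  two-amplitude linear solve inside a 1-D golden-section search). Step 2
  fixes both lifetimes and solves each condition's amplitudes exactly
  (weighted 2×2 linear system with non-negativity by boundary refit).
  $\beta_1$ is reported in amplitude convention ($\beta_2 = 1 - \beta_1$),
  clamped to $[0,1]$ with a boundary flag. If $\tau_2$ comes within 50 ps of
  $\tau_1$ the model is flagged degenerate; if the short component carries
  no amplitude, $\tau_2$ is flagged unidentifiable. When replicate rows are
  present, $\tau_2$ is refit per row and its spread reported as a standard
  deviation.
* **Conventions.** Generator mixtures are *photon* fractions (each
  component normalised to unit photons); the ground-truth FRETing fraction
  and the fitted $\beta_1$ are *amplitude* (molecular) fractions.
  `amplitude_to_photon_fractions()` converts ($p_i \propto \beta_i\tau_i$).

## Synthetic plates

The generator emulates: elliptical, axis-aligned, non-overlapping cells
(semi-axes 9×7 ± 1 px at the default 64×64 scale — a scaled-down frame;
real fields are an order of magnitude larger) with a closed 3-px membrane
ring; membrane FRETing fraction following a 4-parameter Hill curve in dose
($f_{max} = 0.8$ at vehicle, residual $f_{min} = 0.05$ in the
myristoylation-deficient positive control, EC50 0.1 µM, slope 1 — chosen as
a realistic mid-range anchor for the 10 µM → 0.001 µM, $10^{4/8}$-ratio
dilution series); cytoplasm at 40 % brightness carrying 25 % of the
membrane's FRETing fraction (dimerisation without membrane binding);
pure-FRET debris discs (2–4 px) outside cells whose number scales with the
FRETing fraction, emulating debris shed by budding particles — this is what
biases intensity-threshold analysis and makes membrane segmentation widen
the assay window; optional "no cells found" wells; and a reference
measurement with $10^7$ photons.

It does **not** emulate: optical sectioning or its artefacts, camera read
noise or intensifier gain noise, photobleaching, cell-to-cell expression
variability, irregular cell shapes, autofocus failure modes, or
multi-exponential donor photophysics (the CFP-like donor is approximated as
mono-exponential, as the assay itself does). Passing tests therefore
demonstrate correctness of the estimators and pipeline logic under the
stated noise model, not robustness to every real-data pathology.

## Segmentation

The size-tuned nonlinear top-hat scores each pixel by
$\max(0,\ S_{close}(\mathrm{disc}_{r_{in}}) -
S_{distant}(\mathrm{annulus}_{r_{in}..r_{out}}))$ with neighbourhoods
clipped at image borders. The statistic pair is configurable; the default is
median/median. A distant-*maximum* variant was considered as the stricter
"any bright distant neighbour suppresses" choice, but it is analytically
degenerate for cells larger than the inner radius: every in-cell pixel then
has part of its own (bright) cell inside the annulus, so the whole cell
scores zero. The median tolerates up to half of each neighbourhood being
contaminated: the close median suppresses objects smaller than half the
inner disc (debris), while the distant median provides local background
reference without being captured by the cell's own pixels. Defaults
(inner 5 px, outer 12 px, sieve 100 px, erosion 3 px) are tuned to the
generator's 64×64 scale and exposed as user parameters, as is conventional
for this class of algorithm. Smoothing is binary closing then opening with
a 1-px disc; components are 8-connected; labelling is deterministic in
raster order. The membrane mask is the exact set difference
`mask & !erode(mask, depth)` with a disc structuring element
$\{(dr,dc): \sqrt{dr^2+dc^2} \le depth\}$.

## Plate statistics

* Well aggregation defaults to pooling all defined pixels/ROIs across FOVs
  (the pooled mean equals the count-weighted mean of per-FOV means; a
  per-FOV-mean mode is provided since the underlying choice is ambiguous
  in practice).
* $Z'$ arms default to per-well means of the control columns; any vector
  can be passed instead, which covers the documented fallback of
  substituting a high-dose column for a failed negative control.
* Percent inhibition anchors the low dose at 0 % (lifetime rises with
  inhibition) and is reported unclamped with an out-of-range flag.
* Missing ("no cells") wells are excluded from arms, never imputed.
* Dose–response tables pool repeat wells per dose; the Hill fit uses
  log-EC50 parameterisation with a residual bootstrap (199 replicates) for
  the EC50 interval, and flags a fit whose span is within twice the
  residual noise as unidentifiable.
* Drift checks fit ordinary least-squares slopes to column- and row-ordered
  well means; flagging is relative to a user-supplied assay window.

## Problem sizes and tolerances in the test suite

The suite runs entirely on generated data: a full 96-well, 1 FOV/well,
64×64, 16-gate plate for the end-to-end checks (Z′ consistency with its
closed form is asserted exactly; the desirability threshold 0.4;
dose-monotonicity within 2 SD; EC50 within a factor 2; membrane window at
least the intensity-threshold window); 1000-decay Monte-Carlo calibration
at $10^4$ photons (bias < 1 %) with 1000 decays per photon level for the
$1/\sqrt{N}$ ratios (within 15 % of 2); $10^6$-photon pooled decays for
global binning ($\tau_2$ within 30 ps, $\beta_1$ within 0.03); 100 random
mixtures for the reconvolution oracle ($<10^{-3}$); and brute-force oracles
on 16×16 images and 50 random shapes for the segmentation primitives. These
sizes keep the default run to a few minutes while leaving the statistical
assertions with comfortable margins.

## Known limitations

* The calibrated reference path assumes a Gaussian IRF; real gated
  intensifiers have asymmetric responses. The nonparametric identity path
  is exact but requires a finely sampled reference.
* Fixing $\tau_1$ from a positive control that itself carries residual
  FRET (as the assay design prescribes, and as the generator emulates with
  $f_{min} > 0$) transfers that bias into $\tau_2$ and $\beta_1$; the
  pipeline reports what the design measures, not the generator's hidden
  truth.
* Mean lifetimes from single-exponential fits of genuinely bi-exponential
  pixels are effective values; they order conditions correctly but are not
  population-fraction estimates — that is what global binning is for.
* No watershed splitting: touching cells merge into one object (the
  generator enforces separation, real data would not).
* Percent inhibition in lifetime space differs from the underlying
  fraction-space effect by the mild nonlinearity of the mixture-to-lifetime
  map (about 2 percentage points at mid-effect under default conditions).
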