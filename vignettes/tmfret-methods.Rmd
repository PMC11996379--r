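---
title: "Models and methods in tmfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tmfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmfret)
```

This vignette is the package's own account of the science it implements:
the decay model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.  It states no empirical result that the test
suite or `scripts/acceptance.R` do not themselves compute.

## The measurement

A pulsed laser excites a donor fluorophore (Acd, a noncanonical amino acid
with a long, nearly single-exponential lifetime); single photon arrival
times are histogrammed into a TCSPC decay of typically 4096 bins over a
50 ns window.  A metal-ion acceptor — here the cysteine-reactive
[Ru(bpy)₂phenM]²⁺ complex, R0 = 43.5 Å with Acd — quenches the donor by
FRET at a rate proportional to `(R0/r)⁶`, so every donor–acceptor distance
`r` in the ensemble contributes its own accelerated exponential.  The decay
therefore encodes the distance *distribution*, which for a two-state
protein domain is modeled as a sum of two Gaussians: the resting state
(component 1, longer distance by convention) and the active state
(component 2, weight `f_A2`).

Four traces make up one measurement: the sample decay, a buffer-only decay,
and the instrument response function (IRF, from a scatterer), with the
fourth "trace" being the model itself.  The fitted model is

```
Decay(t) = [shifted, background-subtracted IRF] * (A0·I_DA + f_B·I_B) + bkgr_dec
```

a discrete linear convolution (iterative reconvolution — the raw histogram
is fitted, never deconvolved).  `I_DA` combines a donor-only fraction `f_D`
(molecules with no functional acceptor) with the FRET-quenched ensemble
average; `I_B` is a fixed multi-exponential fitted to the buffer trace and
scaled by the acquisition-time ratio `f_B`.

### The two-acceptor extension

In a homotetramer with all subunits labeled, a donor faces both its own
subunit's acceptor (distribution ρ₁) and the closest intersubunit acceptor
(ρ₂, measured independently in a construct with the donor and acceptors on
different subunits).  Transfer rates add, and because the two distances are
independent the double integral over (r₁, r₂) factorizes into a product of
one-dimensional integrals per donor lifetime component.  The package
evaluates the factorized form; the test suite verifies it against a
brute-force double integral to 1e-6 relative.  ρ₂'s distances and widths
are held fixed and its state fraction is linked to ρ₁'s `f_A2`, because
both distributions report the same conformational equilibrium.  The
transfer term always enters the exponent with the quenching (negative)
sign; a positive sign would make FRET lengthen the lifetime.

## Parameters

The full vector (15 parameters plus the fixed ρ₂ set):

| name | meaning | units | typical handling |
|---|---|---|---|
| `f_D` | donor-only fraction | – | free (0–1) |
| `tau_D1, alpha_D1, tau_D2` | donor biexponential | ns, – | fitted on donor-only sample, then fixed |
| `R0` | Förster radius | Å | fixed (43.5 for Acd/Ru) |
| `rbar_1, sigma_1` | resting Gaussian | Å | free |
| `f_A2` | active-state fraction | – | free, or fixed 0/1 for single-state fits |
| `rbar_2, sigma_2` | active Gaussian | Å | free |
| `shift_irf` | IRF time shift | ns | free (sub-bin, linear interpolation) |
| `f_B` | buffer scaling | – | fixed to acquisition-time ratio |
| `A0` | amplitude | counts | free |
| `bkgr_dec` | flat decay background | counts/bin | free |
| `bkgr_irf` | flat IRF background | counts/bin | fixed to 0 |

Defaults worth knowing: the distance quadrature grid runs 2–150 Å in 0.1 Å
steps (trapezoid rule, density renormalized on the grid, truncation of more
than 0.1% of mass is an error); σ has a floor of 0.2 Å — twice the grid
step — below which the discretized Gaussian is jagged and its derivatives
meaningless; temperature for energetics defaults to 298 K (the published
SthK free energies are consistent with room temperature; sensitivity over
293–310 K is ±0.02 kcal/mol).

## Fitting

Weighted least squares on `(obs − model)/σ` with `σ = sqrt(max(counts, 1))`
(per-bin Poisson noise).  Descriptions of TCSPC fitting sometimes equate
the per-bin "standard deviation" with the decay itself, which conflates the
SD with the variance; the Poisson reading is statistically correct and is
the default, with the literal rule available as
`weighting = "as-printed"`.  Two consequences of
this *Neyman* weighting (σ from observed counts) are documented behavior,
not bugs: at low counts the estimator of a flat background is pulled toward
the harmonic mean (e.g. ≈4.7 for Poisson(6) data), and low-count tail bins
are slightly over-weighted downward.  Both effects vanish above ~100
counts/bin and are negligible for study-scale decays.

The optimizer is a small box-constrained Levenberg–Marquardt written in the
package (no LM implementation is available in the target library set):
forward-difference Jacobian with block-sparsity across decays in global
fits, an active-set treatment of bound-pinned parameters, convergence on
relative χ² change (1e-12) with a stall escape, and seeded multistart
(default 5 starts for FRET fits; start 1 is the declared initial point).
Fits are deterministic given (spec, start values, seed).

The fit window runs from the rising edge of the decay (located via the IRF
onset; the pre-pulse region estimates the background) to the end of the
record.  Component labels are tie-broken after the fit: component 1 is the
longer distance, a pure relabeling under which the model is exactly
invariant (in the two-acceptor model ρ₂'s labels are swapped along).

χ² profiles and surfaces re-optimize all remaining free parameters at each
grid point (true profiling, not slicing), warm-started from the neighboring
point, and are reported on the original fit's degrees of freedom so the
profile minimum is directly comparable to the joint reduced χ².

## Energetics and dose–response

`ΔG = −RT·ln(f_A2/(1−f_A2))` with R = 1.9872×10⁻³ kcal/(mol·K).  Fractions
of exactly 0 or 1 (from single-state fits) are rejected rather than
clipped: the energy diverges and only free-floating fractions are
physically meaningful.  ΔΔG = ΔG(ligand) − ΔG(apo) is invariant to any
constant domain-coupling offset, which is what makes it comparable across
constructs.  The dose–response uses the exact ligand-depletion quadratic
isotherm (protein concentration comparable to K_D); it is evaluated in the
cancellation-free form `2L/(s + √(s² − 4PL))`, which keeps the `[P] → 0`
hyperbolic limit accurate to machine precision.

## The synthetic world

`simulate_decay()` builds the expected sample and buffer curves from the
*noiseless* Gaussian IRF shape and the exact forward model, then draws
independent Poisson counts per bin; the measured IRF returned with the pair
is itself Poisson-sampled, as in a real scatter measurement.  The induced
model mismatch from fitting with the noisy IRF is of order the per-bin
signal amplitude (≈0.01 counts at the default budgets) — orders of
magnitude below shot noise.

Defaults are the study-scale acquisition: 50 ns window, 4096 bins, Gaussian
IRF of 0.5 ns FWHM centered at 2 ns, 10⁷ expected sample photons, 10⁶ IRF
photons.  Choices not fixed by published values, set once here:

* **Donor-only fraction**: 0.15 for single-cysteine (intrasubunit)
  constructs — a realistic incomplete-labeling fraction — and 0.05 for
  intersubunit/homotetramer scenarios, where a donor faces three acceptor
  sites and a fully unlabeled tetramer is rare.
* **Buffer**: one dim fast component (τ = 2 ns) at ~1% of the sample
  amplitude, plus 2 counts/bin of buffer-trace background; sample/buffer
  acquisition times 300/60 s, so `f_B = 5`.
* **IRF shift truth**: 10 ps; **decay background truth**: 5 counts/bin.
* **Mid-titration fractions** come from the published binding curve
  (K_D = 0.22 µM, [P] = 1.2 µM for the C-terminal heterotetramer); for the
  homotetramer, which has no published K_D, the same curve is rescaled to
  that construct's apo/saturating fractions.

What the generator does **not** emulate: photon-by-photon arrival (pile-up,
dead time, after-pulsing), detector IRF tails, multi-detector or anisotropy
channels, and vendor binary formats.  A green recovery test therefore
establishes that the analysis inverts its own forward model at realistic
photon budgets — not that instrument artifacts are handled.

## Identifiability, honestly

At 10⁷ photons, strong-FRET distances (29–42 Å with R0 = 43.5 Å) are
recovered to ~0.01–0.1 Å and state fractions to ~0.01 (the acceptance
tests compute these).  The weak-FRET intersubunit regime (r̄ = 54.1 Å,
transfer efficiency ≈ 0.2) is different: σ, `f_D` and r̄ trade off along a
near-flat, bimodal χ² valley — one basin collapses σ to its floor while
inflating `f_D`, the other sends `f_D` to 0 with σ near truth — and the
exact maximum-likelihood estimate of r̄ scatters with an SD of about 1 Å
across noise realizations.  This mirrors the σ–f_D and r̄–f_D correlations
reported for this system from measured-data χ² surfaces.  One acceptance
criterion asks
for 1 Å recovery in this regime at a fixed seed; it is met in only about a
third of seeds and is left red at the package's seed convention rather
than loosened (see the decisions ledger).  Fitting apo and saturating
conditions jointly, or fixing `f_D`, would shrink the scatter but is not
the prescribed single-decay protocol.

## Degenerate inputs and guards

All-zero observed traces, IRFs with no counts after background
subtraction, non-uniform time grids, truncated distance distributions,
buffer models with more than four components, fractions outside [0, 1],
flat titrations (K_D unidentifiable) and fully saturating titrations are
rejected with classed conditions (`tmfret_*_error`), and a near-singular
scaled Hessian at an optimum raises an identifiability warning.  A fit
specification with every parameter fixed performs a χ² evaluation without
optimization.
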