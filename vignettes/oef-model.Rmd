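---
title: "Modelling cerebral oxygen extraction from capillary transit times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebral oxygen extraction from capillary transit times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capox)
```

## The model and its assumptions

`capox` estimates the oxygen extraction fraction (OEF) of brain tissue from
two perfusion statistics: the mean transit time (MTT) and the capillary
transit time heterogeneity (CTH). The physical picture is a parallel network
of capillaries whose transit times $\tau$ follow a gamma distribution
$h(\tau;\alpha,\beta)$; each capillary unloads oxygen along its length
according to a flux proportional to the plasma–tissue oxygen tension
gradient, with hemoglobin acting as the oxygen buffer through the Hill
saturation curve

$$S(P) = \frac{P^h}{P^h + P_{50}^h}.$$

Along the normalized axis $x \in [0,1]$ of a capillary with transit time
$\tau$, the bound-oxygen concentration obeys

$$\frac{dC}{dx} = -k\tau\,\alpha_H\!\left(P_{50}
  \left(\frac{C}{B-C}\right)^{1/h} - P_tO_2\right),
  \qquad C(0) = S_a B,$$

where the first bracket term is the plasma tension recovered from $C$ by
inverting the Hill curve. The capillary extracts
$Q(\tau) = 1 - C(1)/C(0)$, and the tissue OEF is the transit-time average
$\mathrm{OEF} = \int_0^\infty h(\tau)\,Q(\tau)\,d\tau$ with
$\mathrm{MTT} = \alpha\beta$ and $\mathrm{CTH} = \sqrt{\alpha}\,\beta$.

Key assumptions, stated plainly:

* **Bound oxygen only in the transported pool.** The inflow condition is
  $C(0) = S_a B$; dissolved plasma oxygen (under 1% of content) enters only
  through the gradient term. This choice reproduces both published anchor
  points of the extraction ceiling (0.60 at 21.8 mmHg, 0.50 at 25 mmHg),
  which would discriminate against a mis-grouped plasma term; the package
  refuses to load if its default constants drift off these anchors.
* **A single, constant tissue tension** $P_tO_2$ along the capillary and
  across the brain. Partial-volume effects in perfusion MRI make
  tissue-specific tensions impractical; the model follows that choice.
* **CTH is the standard deviation** of the transit-time distribution — the
  gamma parameterization is fixed by $(\mathrm{MTT}, \mathrm{CTH})$ moments.
* **No Bohr effect**: $P_{50}$ does not vary with temperature or pH, and
  there is no intravascular diffusion resistance term.

## Parameters

| parameter | meaning | unit | default | origin |
|---|---|---|---|---|
| $P_{50}$ | half-saturation tension | mmHg | 26 | literature value of the original model |
| $h$ | Hill coefficient | — | 2.8 | literature |
| $B$ | bound-O₂ capacity | mL O₂/mL | 0.1943 | literature |
| $\alpha_H$ | O₂ solubility | mL O₂/mL/mmHg | $3.1\times10^{-5}$ | literature |
| $S_a$ | arterial saturation | — | 0.95 | normal arterial blood |
| $P_tO_2$ | tissue O₂ tension | mmHg | 21.8 | calibrated (ceiling 0.6) |
| $k$ | transfer rate constant | 1/s | 68 | calibrated (cohort mean) |

The two calibrated parameters are the scientific crux. In the
$k \to \infty$ limit blood equilibrates with tissue instantly and the
transit-time distribution drops out, leaving the closed-form ceiling
$1 - S(P_tO_2)/S_a$; `calibrate_pto2()` inverts this analytically (no
root-finding on the ODE is needed). With $P_tO_2$ fixed, `calibrate_k()`
matches the model OEF to an observed PET OEF by Brent root-finding on
$\log k$ over $[10^{-3}, 10^6]$ s⁻¹ — the log scale because calibrated
rate constants spread over nearly a decade across subjects and OEF
saturates in $k$. OEF is strictly increasing in $k$, so the root is unique;
a converged calibration satisfies $|\mathrm{OEF}(k) - \mathrm{target}|
\le 10^{-6}$.

## Numerical choices

**Capillary equation.** $Q$ depends on $(k, \tau)$ only through $u = k\tau$:
substituting $s = k\tau x$ makes the equation autonomous. The package
therefore solves one initial-value problem per constants set (via
`deSolve::lsoda`, rtol $10^{-9}$, atol $10^{-12}$) and reads off the
solution at every requested $u$ — quadrature nodes, voxels and subjects all
share a single solve. `lsoda`'s automatic stiff/non-stiff switching handles
the growing stiffness in $u$; beyond $u = 10^5$ the state is within
numerical noise of the tissue equilibrium $C_{eq} = B\,S(P_tO_2)$ and is
clamped there analytically (the equilibrium decay scale is $u \approx 190$,
so $u = 10^5$ overshoots it five-hundred-fold). During integration the state
is clamped to $[C_{eq}, B(1-10^{-12})]$; the exact solution never leaves
this interval, so the clamp only guards round-off.

**OEF integral.** Gauss–Legendre quadrature with 256 nodes between the
$10^{-7}$ and $1-10^{-7}$ gamma quantiles. Both discarded tails carry
density mass $10^{-7}$ with $Q < 1$, bounding the truncation error by
$2\times10^{-7}$. White matter implies a shape $\alpha \approx 0.69 < 1$,
whose density diverges at $\tau = 0$ — but the integrand $h(\tau)Q(\tau)$
behaves as $\tau^{\alpha}$ there because extraction vanishes linearly in
$\tau$, so no substitution is needed; the quadrature agrees with a
$10^5$-step Riemann oracle to better than $10^{-4}$ across the study's
parameter box (this is a test). The lower quantile cut also lets the same
256 nodes resolve near-degenerate distributions (tiny CTH); exactly zero
CTH short-circuits to $Q(\mathrm{MTT})$.

**Degenerate inputs.** Tissue tensions at or above the arterial-equivalent
level leave no extraction gradient; all operations reject this case
explicitly rather than returning 0 silently (the ceiling function offers a
`"zero"` mode for plotting). PET OEF targets at or above the ceiling are
unreachable at any finite $k$ and are reported as exclusions with reasons,
never dropped.

**Voxel maps.** `oef_map()` evaluates exactly by default; the optional
lookup grid (64×64, log-spaced, bilinear in log coordinates) trades an
absolute error below $10^{-3}$ OEF for two orders of magnitude in speed,
and is validated against exact evaluation in the tests.

## The synthetic cohort

No subject-level data are published for this design, so the package ships a
generator (`generate_cohort()`) that emulates the *statistical shape* of a
healthy elderly cohort: per-region MTT/CTH with the reported means and
ranges (white matter 4.52 s [3.14; 6.42] / 5.45 s [3.82; 8.31]; gray matter
3.40 s [2.35; 4.60] / 4.08 s [2.85; 6.07]), a per-subject transfer rate
constant spread (lognormal, median 68 s⁻¹, truncated to 22–175), and 10%
multiplicative observation noise on PET OEF — the reported day-to-day
variability. Distributional choices the data do not pin down, made once:

* **Lognormal margins** for MTT, CTH and $k$ (positive, right-skewed, as
  transit-time statistics are), with the reported range read as the
  2.5–97.5 percentile band and enforced by inverse-CDF truncation.
* **MTT–CTH dependence**: Gaussian copula with Spearman correlation 0.8 —
  heterogeneity tracks mean transit time across tissue types — exposed in
  `cohort_config()`.
* **Noise placement**: multiplicative on the forward-model OEF, clipped
  into $(0, \text{ceiling})$ with clip counts reported.

Passing tests on this cohort demonstrate *self-consistency* — exact
parameter recovery without noise, bounded bias with noise, determinism
under a seed, and the qualitative agreement pattern (positive model–PET
correlation; compression of the model's between-subject OEF range when one
common $k$ is applied to subjects whose true $k$ varies). They do not
demonstrate that real white-matter physiology follows a lognormal, that
real PET noise is multiplicative, or that the model is unbiased on real
scanners.

## Averaging order, and why it matters

The model is concave in its inputs near the operating point. Evaluating it
at cohort-*mean* MTT/CTH with the cohort-mean $k$ therefore yields a higher
OEF than averaging per-subject model OEFs — the package's worked example
gives 0.382 at the white-matter mean inputs and 0.350 at the gray-matter
mean inputs, a little above the reported cohort-mean model OEFs (0.37,
0.33), which were averaged across subjects (and voxels) *after* applying
the model. The same mechanism appears in calibration: inverting noisy OEF
observations through a saturating forward model inflates the arithmetic
mean of per-subject rate constants (the inversion is convex), so the
cohort-mean $k$ recovered from noisy synthetic cohorts runs several percent
above the generating value while the median stays nearly unbiased — which
is why `calibrate_cohort()` reports both. Neither gap is a solver artifact;
both survive cross-checking against brute-force oracles.

## Problem sizes

The shipped tests run the full stack at the sizes a desk check needs:
256-node quadrature against $10^5$-step Riemann sums over a 2×2×3
parameter box, capillary solutions against fixed-step RK4 oracles (up to
$10^6$ steps for the worked-example transit time), cohorts of 68 subjects,
and 20-seed replication of the noisy-calibration experiment. The acceptance
script recomputes the four headline quantities deterministically in under a
second each.

## Known limitations

* The model inherits the original constants; no Bohr-effect or hematocrit
  adjustment is offered.
* Calibration assumes one $(P_tO_2, k)$ pair for the whole brain; per-region
  calibration is deliberately not implemented.
* The PET arm is a minimal one-tissue-compartment simulator/fitter for
  synthetic end-to-end testing — it performs no delay, dispersion or
  partial-volume correction and is not a substitute for a clinical kinetic
  toolbox.
* Agreement analysis reports two region-level tests without multiplicity
  correction, mirroring the study design it emulates.
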