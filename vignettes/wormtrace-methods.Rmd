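---
title: "Models and methods behind wormtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrace)
```

## The scientific question

Short double-stranded DNA appears, in several single-molecule experiments,
far more flexible than the worm-like chain (WLC) model predicts. One
proposed explanation is intrinsic "kinkability": even small bends would be
localized kinks rather than smoothly distributed curvature, as in the
linear sub-elastic chain (LSEC) picture. The alternative explanation is
that the apparent excess flexibility at the shortest length scales is a
measurement artifact of tracing filament contours in AFM images.
`wormtrace` implements the full computational apparatus needed to examine
this question on synthetic data: equilibrium simulation of planar discrete
chains under harmonic (WLC) and kinkable (LSEC) bending potentials, a
virtual AFM that renders chains into height images, a sub-pixel
prediction–correction contour tracer with a centerline refinement step, a
bisector-shift model of the irreducible localization noise set by the 2 nm
width of the double helix, and the bend-angle statistics that turn traced
contours into persistence-length estimates.

## Chain models

A molecule is a planar phantom chain (self-crossings allowed) of beads at
fixed steps, one bead per base pair (0.34 nm). Bend angles between
successive segments are drawn i.i.d. from the Boltzmann distribution of a
per-segment bending energy $E(\theta)$:

* **Harmonic (WLC).** $E(\theta) = k_BT\, l_b\, \theta^2 / (2\,\ell)$ for
  segment length $\ell$, the planar convention in which the bend-angle
  variance at tangent separation $L$ is $\langle\theta^2\rangle = L/l_b$
  and the tangent correlation decays as
  $\langle\cos\theta(L)\rangle = e^{-L/2l_b}$. This is the convention of
  the AFM-on-surface literature for molecules equilibrated in a plane, and
  it is what makes the reference stiffness $l_b = 56$ nm reproduce the
  measured angle variances.
* **Kinkable (LSEC).**
  $E(\theta) = q\theta^2$ for $\theta < \theta_0$ and
  $E(\theta) = q\theta_0^2 - \frac{q}{k}\theta_0(\theta_0-\pi)
  \left[1 - \left(\frac{\theta-\pi}{\theta_0-\pi}\right)^{2k}\right]$
  beyond, with defaults $\theta_0 = 2^\circ$, $k = 2$,
  $q = 110$ kcal/mol. The potential is convex only in a negligible core
  and concave beyond, so bends concentrate into kinks. It is applied to
  $|\theta|$; distributions are symmetric in the signed planar angle.

Temperature only enters through $k_BT$ when converting $q$ (kcal/mol) to
Boltzmann weights; we use $k_BT = 0.593$ kcal/mol (298 K, room
temperature, the adsorption condition). Whether $q$ was quoted at 293 or
298 K changes the weights by under 2% and is invisible at the precision of
any test here.

Harmonic sampling uses a normal draw truncated to $(-\pi,\pi)$ by
redrawing (the truncated mass is astronomically small for
$l_b/\ell \gg 1$). LSEC sampling inverts the cumulative distribution on a
$10^{-4}$ rad grid of $|\theta|$ and attaches a random sign — fully
deterministic given the R random seed, with no rejection loop.

```{r lsec, fig.width = 5, fig.height = 3.5, eval = FALSE}
set.seed(1)
th <- sample_bend_angles(energy_model("lsec"), n = 1e5)
autoplot(neg_log_distribution(tibble::tibble(theta = th)),
         linearized = TRUE)
```

At a single base-pair step the LSEC distribution is visibly non-Gaussian
(curved in the $-\ln P$ vs $\theta^2$ coordinates that straighten a
Gaussian); resampled at one helical turn (3.4 nm, ten steps) it is already
near-Gaussian by the central limit theorem. That convergence is why local
kinkability cannot perturb statistics beyond roughly one helical turn, and
it is asserted quantitatively in the test suite (weighted $R^2$ of the
linearized fit below 0.95 per step, above 0.98 per turn).

## Digitized contours and the chord correction

AFM contours are digitized with link lengths $\ell_0 \geq$ one helical
turn, much coarser than a base pair. To emulate that, simulated chains are
resampled by keeping every $m$-th bead, $m = \mathrm{round}(\ell_0/0.34)$
($m = 10, 21, 41$ for $\ell_0 = 3.5, 7, 14$ nm), dropping the remainder.
Index stepping (rather than chord-length stepping) is used because the
resampled vertices must coincide exactly with beads; for stiff chains the
difference between the two conventions is second order.

The direction of an $m$-bead chord is approximately the *average* of the
$m$ underlying tangent directions. Writing the angle between adjacent
chords as a weighted sum of the per-bead bends, the weights rise linearly
from 0 to 1 across each chord, giving

$$\mathrm{Var}(\theta_{\text{chord}}) = \frac{\ell}{l_b}
\left[(s-1)m + \frac{2m^2+1}{3m}\right]$$

for chords separated by $s$ links ($\ell$ = bead step), instead of the
naive $s\,m\,\ell/l_b$. At $s = 1$ this is a factor $2/3$: ignoring it
inflates the apparent $l_b$ by 50% at the shortest separation and produces
a spurious separation dependence ($\approx 84, 67, 63$ nm at
$L = 7, 14, 21$ nm for a 56 nm chain). `estimate_lb()` therefore uses the
effective separation
$L_{\text{eff}} = \ell\,[(s-1)m + (2m^2+1)/(3m)]$ by default (the
continuum limit $L(1 - 1/3s)$ for traced contours, whose underlying
"stride" is not an integer), which makes variance- and slope-based
estimates both recover the generating stiffness and agree across
separations — the chain-length independence that is the scientific
conclusion of this analysis. The correction can be disabled with
`chord_correction = FALSE` to reproduce the naive estimator.

```{r chord, eval = FALSE}
set.seed(1)
chains <- sample_chains(energy_model("harmonic", lb = 56), 100, 4363)
contours <- resample_with_stride(chains, 7)
estimate_lb(tangent_angles(contours, 1), n_boot = 100)
```

Bend angles are always measured on a non-overlapping partition: the angle
between link $i$ and link $i+s$ with $i$ advancing by $s$, so each bend
between adjacent links enters exactly one measured angle and a contour
with $n$ links yields $\lfloor (n-1)/s \rfloor$ angles.

## Estimators, binning and uncertainty

`estimate_lb()` offers the variance estimator
$l_b = L_{\text{eff}}/\langle\theta^2\rangle$ and a slope estimator:
count-weighted least squares of $-\ln P$ against $\theta^2$ over
$|\theta| \le 60^\circ$ using bins with at least 5 counts,
$l_b = 2 L_{\text{eff}} \times \text{slope}$. Histograms use a 0.05 rad
default bin width and report the folded $|\theta|$ distribution (the
signed distribution is symmetric). Standard errors come from a bootstrap
over molecules — not over angles — because angles within one molecule
share its conformation; 1000 resamples by default. The fit window and bin
width are deliberate defaults, config-exposed, since the published
analysis does not pin them down.

## The virtual AFM

`render_image()` renders a contour into a height grid: the noiseless
height at a pixel is $H\exp(-d^2/2\sigma^2)$ with $d$ the distance from
the pixel center to the contour *polyline* (never per-vertex splats, which
would imprint bead spacing), plus i.i.d. Gaussian background noise.
Defaults: apparent height $H = 1.5$ nm and cross-section width
$\sigma = 2.5$ nm (apparent FWHM $\approx 6$ nm, a tip-broadened ridge
well above the 2 nm physical diameter), background noise 0.1 nm RMS —
typical of flattened tapping-mode scans of DNA on mica in liquid. Images
are zero-baseline, i.e. flattening is assumed already done. Pixel sizes of
1.95 and 3.9 nm mirror the two scan settings studied.

The helical undulation of the centerline — the height maxima of a scanned
double helix follow a wavy line inside the 2 nm enveloping cylinder — is
modeled by `undulate_centerline()`: a perpendicular sinusoidal offset of
amplitude up to 1 nm (half the envelope) and period 3.5 nm (one turn)
applied to the bead-resolution chain before rendering.

`make_fixture_set()` bundles all of this into seeded image/ground-truth
pairs. Phantom chains of thousands of beads almost always self-cross in
the plane; since crossed molecules are not traceable (and were not traced
in real experiments), fixtures redraw chains whose distant stretches
approach within 5 nm. This conditioning slightly favors straighter
conformations; its effect on *local* bend statistics at separations of a
few nm is well below the estimators' bootstrap uncertainty for the
molecule lengths used here.

## Tracing and refinement

`trace_molecule()` is an iterative prediction–correction tracer. From two
seed points at a chain end it repeatedly: predicts one link ahead along
the previous direction; corrects the direction three times using the
height-weighted integral
$\vec X = \int_0^{10\,\text{nm}} Z(\vec x(s))\, \vec x(s)\, ds$ taken over
a segment perpendicular to the prediction, centered on the predicted
point, with position vectors from the previous accepted vertex (composite
midpoint rule at a quarter-pixel step); then makes the final step with
exactly the required link length, so every chord is $\ell_0$ to machine
precision. Heights anywhere in the plane come from bilinear interpolation
of the pixel grid — the tracer works at sub-pixel resolution. Tracing
stops cleanly when the interpolated height at the next vertex falls below
25% of the running median vertex height (ridge lost / molecule end), when
the correction segment leaves the image, or when the direction reverses.
Segments partially outside the image are integrated over their inside
part and the resulting vertex is flagged.

`refine_trace()` implements the centerline refinement: sample the trace
polyline at half-pixel intervals; at each sample locate the ridge maximum
along a 10 nm perpendicular; iteratively delete points whose interior
turning exceeds 90° (in strongly bent regions the perpendicular search
can jump ahead of or behind the reference link); re-step the pruned
broken line with exact chord $\ell_0$; repeat until the maximum vertex
displacement drops below 0.05 px or ten rounds.

One numerical choice deserves emphasis. Under bilinear interpolation a
cross-section profile is piecewise linear, so directly maximizing it on a
fine grid sticks to pixel centers and biases the crest by up to half a
pixel. The perpendicular maximum is therefore located by a coarse
half-pixel search followed by a quadratic fit to the *logarithm* of five
pixel-spaced samples — exact for a Gaussian ridge cross-section — which
localizes noiseless crests to better than 0.02 px and is the reason the
refinement meets its 0.1 px accuracy floor.

`bundle_spread()` quantifies tracing reproducibility: for a set of traces
of one molecule it reports, at matched arc-length stations along a
reference trace, the lateral standard deviation and the maximum pairwise
distance of the per-trace nearest points. Refinement contracts
deliberately perturbed bundles onto the centerline, with at least 90% of
the arc under one pixel of spread.

## The bisector-shift noise model

The axis of the double helix cannot be localized better than its 2 nm
width allows, an error *inversely proportional to* $\ell_0$ in angle
terms. `apply_bisector_noise()` models it exactly as an irreducible
vertex-level noise: every interior vertex of a digitized contour is
shifted along the bisector of its two links by a signed uniform magnitude
on $[-a/2, +a/2]$ (endpoints, whose bisector is undefined, move along the
perpendicular to their single link; they carry no angle anyway). Shift
amplitudes of 1 and 2 nm are the physically motivated range. Uniform
shifts of variance $a^2/12$ add $6\,\mathrm{Var}(\varepsilon)/\ell_0^2$
to the variance of adjacent-link angles, which collapses the apparent
$l_b$ at $\ell_0 = 3.5$ nm (from 56 to below 20 nm at $a = 1.5$ nm)
while moving estimates made with $\ell_0 \geq 10.5$ nm links by under
10% — the signature that reconciles WLC elasticity with the apparent
short-scale softening. Note that the protection of long separations comes
from tracing with long links: measuring $L = 10.5$ nm as three links of a
noisy $\ell_0 = 3.5$ nm contour still inherits the short-link noise
($4\,\mathrm{Var}(\varepsilon)/\ell_0^2$, a 14–39% depression at
$a = 1$–2 nm), so the package's noise experiment evaluates each
separation at $\ell_0 = L$.

## Problem sizes and determinism

The package's own checks run at desk scale, chosen so every stochastic
assertion sits several standard errors from its threshold: 500 molecules
of 4363 beads for the 7 nm persistence-length recovery (about $10^5$
angles, recovering the generating value to well under 5%), $10^6$ draws
for per-base-pair sampling checks, 300–400 molecules for distribution
shapes, and 30–40 molecules of 800–1000 beads for the rendered-and-traced
experiments. All stochastic code draws from R's RNG only, so a single
`set.seed()` (or the `seed` field of `experiment_config()`, which is
mandatory) reproduces any run bit for bit; pipeline outputs carry the
seed and a configuration hash.

## What the virtual experiment does and does not show

Passing tests on this synthetic pipeline demonstrate that the algorithms
are implemented correctly and that the claimed mechanisms behave as
described on images whose ground truth is known exactly: the tracer and
refinement localize Gaussian ridges to sub-0.1 px; digitization plus the
chord correction recover the generating stiffness without separation
dependence; vertex-level width noise reproduces the short-scale softening
pattern. Two features of real scans are deliberately not claimed:

* **The helical undulation is not resolvable in image space.** With a
  3.5 nm period against a 1.95 nm pixel (Nyquist wavelength 3.9 nm) and a
  2.5 nm ridge width, distance-based rendering plus pixel sampling
  attenuates a 1 nm amplitude undulation to a crest wiggle of ~0.1 nm
  RMS. The undulation's *statistical* effect must therefore be modeled at
  the contour level — which is exactly what the bisector-shift noise
  does — rather than expected to emerge from rendered images.
* **The unrefined tracer's bending inflation does not reproduce here.**
  On constant-width Gaussian ridges the raw prediction–correction tracer
  errs by *smoothing* (its 10 nm height-weighted window averages real
  bends away), so unrefined apparent $l_b$ comes out a few percent high,
  not low. The inflation seen with the original algorithm on real data
  stems from image imperfections — fluctuating apparent width, locally
  noisy wide spots that drive zigzags — that a constant-width renderer
  does not emulate. What does carry over: refinement strictly tightens
  perturbed bundles and moves estimates toward the generating value, and
  at two helical turns the refined virtual experiment recovers the
  generating stiffness to within the image-resolution limit (pixel-scale
  low-passing of the centerline biases traced estimates upward by
  roughly 5–10% at a 1.95 nm pixel; the bias vanishes at finer pixels).

## Known limitations

Planar chains only (no 3D, twist, excluded volume, or sequence-dependent
stiffness); equilibrium sampling only (no Brownian-dynamics kinetics); one
molecule per rendered image with crossing conformations excluded by
default; a Gaussian tip-convolution proxy with constant apparent width;
and no automatic molecule detection — batch tracing is seeded from ground
truth (or a coordinates file for real images).
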