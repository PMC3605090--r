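---
title: "Methods: rigid cores, rotation coordinates and the diffusion-landscape bridge"
author: "riboLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid cores, rotation coordinates and the diffusion-landscape bridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboLandscape)
```

This vignette documents the models behind `riboLandscape`, the
assumptions they rest on, the numerical choices made where the design
was genuinely open, and what the synthetic-data validation does and
does not demonstrate about real trajectories.

## The scientific problem

tRNA translocation through the ribosome is carried by collective
rearrangements — rotation of the 30S body against the 50S subunit,
swiveling of the 30S head against the body, and displacement of the
tRNAs themselves.  Given (i) a trajectory sampling spontaneous
fluctuations around one functional state and (ii) endpoint structural
models of the rearrangement, the framework answers: *how fast can each
rearrangement be, given the free-energy barrier in its path — and
conversely, what barrier heights are compatible with observed rates?*
The bridge between the two is an effective diffusion coefficient along
each collective coordinate.

## Rigid-core identification

Collective rotations should be measured from atoms that move *as a
body*.  `iterativeExclusion()` finds such sets: for each threshold
$\varepsilon$ in a strictly decreasing schedule (default 5, 4, 3, 2,
1.5, 1 Å), it repeatedly (1) superposes every sampled frame on the
current surviving set, (2) computes per-residue RMSF (per-atom
root-mean-square deviation about the mean position, averaged over the
residue's non-hydrogen atoms), and (3) removes **all** residues with
RMSF $\ge \varepsilon$, until none exceeds the threshold, then steps
down.  Design choices a reader should know:

* **Batch removal.**  All residues at or above the threshold are
  removed per pass, not one at a time.  This makes the procedure
  deterministic and order-invariant (both are tested properties); a
  residue once removed is never re-admitted.
* **Boundary comparison.**  Removal uses $\ge \varepsilon$, so the
  converged set satisfies the *strict* inequality RMSF $< 1$ Å for
  every member — the final guarantee asserted in the tests.
* **Alignment set.**  Each RMSF pass self-aligns on the *current*
  surviving set.  Early passes are therefore contaminated by mobile
  residues, but these dominate the RMSF ranking and are removed first;
  the planted-membership tests confirm exact recovery despite the
  contamination.
* **Reference configuration.**  Fluctuations are measured about the
  time-average configuration (one alignment refinement pass, matching
  the behaviour of the standard `g_rmsf`-style tooling); a
  `reference = "first"` flag selects the first frame instead.
* **Analysis window.**  By default the first 1000 ns at a 1 ns stride,
  clipped to the available trajectory; the window actually used is
  recorded in the audit log.

The RMSF pass after the final removal is recomputed before the
schedule advances, so the audit log makes every decision inspectable.

## Rotation coordinates from endpoint models

Measuring a rotation from a single atom pair is hostage to that pair's
local fluctuations.  The package therefore *idealizes* the moving core
in every frame: the reference configuration of the core is rigidly
superposed onto the frame's core atoms (Kabsch, proper rotations only),
and all further geometry is read off the fitted — internally rigid —
copy.  Tested consequences: the idealized copy's internal distances
match the reference to $10^{-9}$ Å, and the variance of the resulting
angle series is no larger than either the raw-pair-vector variance or
the variance when idealizing over a candidate set polluted with mobile
residues.

The coordinate itself is built by `findMaxRotationPair()`:

1. express both endpoint models in the fixed-core frame (for body
   rotation the 50S core is fixed; for head swivel the 30S-body core is
   fixed — this ordering makes the two angles separable);
2. idealize the moving core of each model;
3. score every unordered pair of P atoms by the angle between its
   vector in the two idealized models, and take the maximizer (ties
   broken by larger inter-atom distance, then lexicographic atom key,
   with a message);
4. the plane normal is the unit cross product of the two orientations
   of the winning vector; the in-plane classical orientation is the
   reference direction; counter-clockwise rotation viewed down the
   normal is positive (signed via `atan2`).

`computeAngle()` then evaluates any frame: superpose on the fixed core,
idealize the moving core, project the pair vector into the plane, take
the signed angle.  The result is invariant under global rigid
transforms of the frame to $10^{-6}$ degrees (tested), and the
evaluation errors out when the projected vector shrinks below
$10^{-6}$ of its length (vector nearly parallel to the rotation axis).

A geometric caveat the synthetic generator is designed around: for a
rotation by $\alpha$ about an axis, a pair vector only changes
direction by the full $\alpha$ when it is perpendicular to the axis.
The generator therefore snaps the moving-core atoms' axis coordinates
to a few discrete levels, guaranteeing exactly-perpendicular pairs, so
the prescribed rotation is recoverable without projection bias and the
pair search can be checked against an exhaustive oracle.

The tRNA position coordinate is a centroid-to-centroid landmark
distance (`landmarkDefinition()`).  The conventional "elbow" selection
comes from external structural definitions, so the package ships the
mechanism, not a hard-coded preset.

## Effective diffusion from mean-squared displacement

For a scalar coordinate $x(t)$ sampled uniformly,
$\mathrm{MSD}(\tau)$ averages $(x(t+\tau)-x(t))^2$ over **all**
(overlapping) frame pairs at each lag on the native sampling grid.
Diffusive dynamics give $\mathrm{MSD}(\tau) = 2D\tau$ (one-dimensional
convention used throughout, for angles and distances alike), so
`fitDiffusion()` returns half the ordinary-least-squares slope over a
user-chosen window $[\tau_{\min}, \tau_{\max}]$.

* **Burst phase.**  The initial super/sub-linear regime is excluded by
  $\tau_{\min}$; typical values are about 30 ns for the rotation
  angles and about 10 ns for the tRNA coordinate.  An elbow-detection
  helper (`suggestTauMin()`) exists but is never applied silently.
* **Window length.**  Overlapping-pair MSD estimates have variance
  growing with lag, so the fit should stay in the early linear regime:
  the validation suite fits lags 10-300 of $10^5$-point series (0.3 %
  of the span).  At windows an order of magnitude longer the estimator
  is noticeably noisier.
* **Quality flags.**  A correlation coefficient below 0.95 raises a
  `low_correlation` warning (diffusive fits on the original data
  report 0.97-0.99).  A `non_diffusive_curvature` flag fires when a
  quadratic term both improves the residual sum of squares by more
  than 50 % *and* contributes more than 20 % of the fitted MSD at the
  window end.  The magnitude condition matters: because overlapping-pair
  MSD noise is strongly correlated across lags, the RSS criterion alone
  false-positives on genuinely Brownian series, while ballistic
  ($v^2\tau^2$) curves trip both conditions.
* **Negative slopes** floor $D$ at zero with an explicit flag rather
  than returning a negative diffusion coefficient.
* **Split-half uncertainty.**  `splitHalf()` estimates $D$
  independently on the two contiguous halves of a series; since rates
  depend on $D$ and barrier essentially through $D e^{-\Delta F}$, a
  swap of $D_1$ for $D_2$ at fixed observed rate shifts the inferred
  barrier by $|\ln(D_1/D_2)|\,k_BT$ (`barrierShift()`).
* **Confinement bias.**  $D$ fitted from motion confined in a basin is
  biased low as the fit window approaches the relaxation time — the
  package reproduces this directionally on harmonic-well Langevin
  data; reported coefficients from basin-confined data should be read
  as lower bounds.
* **Roughness.**  `roughness()` inverts
  $D_\mathrm{eff} = D_\mathrm{free}\,e^{-(\varepsilon/k_BT)^2}$ for
  $\varepsilon$, reported in $k_BT$ and kcal/mol ($k_BT = 0.596$
  kcal/mol at 300 K, the conversion default; defined only when
  $D_\mathrm{eff} \le D_\mathrm{free}$).

## The landscape-rate bridge

Free-energy profiles are parameterized on $[0, L]$ with endpoint
minima at zero and one transition state of height $\Delta F^\ddagger$
(in $k_BT$) at $x_\mathrm{ts}$:

* `piecewise_parabola` (default): two inverted parabolas,
  $F(x) = \Delta F^\ddagger\,[1 - ((x - x_\mathrm{ts})/x_\mathrm{ts})^2]$
  left of the peak and the analogous branch of width
  $L - x_\mathrm{ts}$ right of it;
* `quartic_smooth`: $\Delta F^\ddagger (1 - s^2)^2$ on the same
  piecewise-linear coordinate $s$ — a double-well quartic rescaled to
  the same three constraints, with zero-slope, finite-curvature
  endpoint minima.  It exists because the Kramers approximation needs
  genuine basin curvature and because rate robustness should be
  checked across functional forms.

`mfpt()` integrates
$T = D^{-1}\int_0^L e^{F(x)}\int_0^x e^{-F(x')}\,dx'\,dx$ by nested
adaptive quadrature (relative tolerance $10^{-6}$); on a flat profile
this reduces to $L^2/(2D)$ exactly, and the implementation is checked
against an independent dense-trapezoid double sum to 0.1 % and against
direct Euler-Maruyama first-passage simulation to 10 %.  Boundary
convention: reflecting at the starting minimum, absorbing at the
destination; `from = "right"` mirrors the inner-integral bound for the
reverse transition.

**Directional versus two-state rates.**  The one-directional rate
$1/T$ is *not* robust to where the peak sits: the basin weight of the
MFPT product scales linearly with $x_\mathrm{ts}$, so moving the peak
from 3 to 12 units of a 15-unit domain changes $1/T$ fourfold.  The
observable rate of a reversible two-state transition is
$k = 1/T_\mathrm{fwd} + 1/T_\mathrm{bwd}$ (`twoStateRate()`), whose
asymptotic peak-position dependence is
$1/(x_\mathrm{ts}(L - x_\mathrm{ts}))$ — a spread of
$56.25/36 \approx 1.56$ for peaks at 3/7.5/12, within the factor-of-two
robustness the framework relies on.  `robustnessScan()` therefore uses
the two-state rate, while `rateVsBarrier()` and `invertBarrier()` keep
the one-directional convention (pinned by the flat-landscape closed
form $2D/L^2$, the natural "no barrier needed" reference for rate
inversion).  Rates across the two *functional families* at identical
geometry differ by a factor of 2-4, because the quartic's Gaussian
basin weight and the parabola's linear-slope basin weight differ
inherently; shape robustness holds within a family, and barrier bounds
quoted from this package should state the family used.

**Kramers approximation.**  For substantial barriers
($\ge 2\,k_BT$ required, quantitative from $\approx 8\,k_BT$),
`kramersRate()` returns
$k = (D/\pi)\sqrt{\kappa_0 |\kappa_\ddagger|}\,e^{-\Delta F^\ddagger}$
with curvatures in $k_BT$ per unit² (one-sided curvatures combined by
geometric mean for the piecewise family).  The prefactor is $1/\pi$
rather than the textbook $1/2\pi$ because the starting minimum sits at
the reflecting domain edge: the basin is a half-well, halving its
partition function.  Against the quadrature oracle the relative error
decreases monotonically with barrier height — about 27 % at
$5\,k_BT$, under 25 % from $8\,k_BT$, about 11 % at $14\,k_BT$ (these
are the oracle-computed values frozen in the validation suite).

Two consequences of the endpoint-constrained shapes are worth
flagging, because they differ from naive exponential intuition.  The
curvatures scale with the barrier height
($\kappa \propto \Delta F^\ddagger / w^2$), so
$\ln k = \mathrm{const} + \ln \Delta F^\ddagger - \Delta F^\ddagger$
exactly for the Kramers form: the log-slope is $-1 + 1/\Delta
F^\ddagger$, the rate-barrier curve is log-*concave*, and the fitted
attempt frequency $\nu$ (slope-constrained fit of
$\ln k = \ln\nu - \Delta F^\ddagger$, `attemptFrequency()`) drifts
with the fit window in proportion to the geometric-mean barrier of the
window.  All three behaviours are asserted against closed forms or the
trapezoid oracle in the test suite.  $\nu$ remains what it is meant to
be — a descriptive prefactor over a stated barrier range, scaling
linearly in $D$ and as $1/L^2$.

**Barrier inversion.**  `invertBarrier()` solves the monotone
rate-barrier relation by root bracketing (relative tolerance
$10^{-6}$, bracket $[0, 50]\,k_BT$ expanded as needed).  When the
observed rate is that of a multi-step process, the result is an upper
bound on any substep's barrier; a rate at or above $2D/L^2$ returns 0
with a `no barrier required` flag.  Coordinate spans are user
parameters: only the 22 Å tRNA displacement ships as a default; the
angular spans between translocation endpoints depend on which endpoint
models are adopted and must be supplied.

## Synthetic data: what it does and does not show

`genAssemblyTrajectory()` emulates exactly the features the analysis
relies on: internally rigid cores (per-axis Gaussian jitter, default
0.2 Å — sub-Å as in the rigid-core premise), a prescribed relative
rotation path, and an unanchored Gaussian-random-walk periphery
(default step 3 Å per frame per axis) guaranteeing arbitrarily large
RMSF separation from the cores.  Default sizes (25 + 25 core residues,
20 mobile, two heavy atoms per residue) keep a full
iterative-exclusion run under a second while leaving a 15-fold RMSF
separation between populations.  `genLangevin()` integrates the
overdamped Euler-Maruyama update
$x \leftarrow x - D F'(x)\,dt + \sqrt{2 D\,dt}\,\eta$ with reflecting
walls for confined runs, a mandatory seed, and a step guard
($D|F'|_{\max} dt < 0.1\sqrt{2 D dt}$) that rejects drift-dominated
steps; Gaussianity of free-diffusion increments is itself tested.

Passing these tests demonstrates that the *operations* are correct on
data satisfying their assumptions.  It does not demonstrate that real
rRNA satisfies them: the generator has no solvent, no sequence, no
tethered periphery (real peripheral residues are anchored and their
RMSF saturates), no coordinate-dependent diffusion, and its rotations
follow a prescribed path rather than emerging from a force field.
Core counts and diffusion coefficients from the original
microsecond-scale trajectory are therefore documented expectations,
not reproducible targets at this scale.

## Problem sizes and numerical defaults

The validation suite runs at desk scale by choice: $10^5$-point series
for diffusion recovery (20 seeds per decade of $D$ across
0.01-10 units²/ns), 500-800 Langevin passages per MFPT cross-check at
2-4 $k_BT$ barriers with $dt = 0.01$-0.02, 60-frame assemblies for the
20-seed core-recovery sweep, and $10^4$-point trapezoid grids for the
quadrature oracle.  Superposition requires $\ge 3$ non-collinear
points and rejects reflections; selections with missing residues,
empty candidate sets, non-uniform time grids, indistinguishable
endpoint models, and $D_\mathrm{eff} > D_\mathrm{free}$ all fail fast
with named errors rather than degrading silently.
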