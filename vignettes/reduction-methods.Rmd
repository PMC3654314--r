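---
title: "Rotation-method reduction on a curved PSD: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-method reduction on a curved PSD: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdred)
```

This vignette documents the measurement model psdred implements, the
parameters that matter, what the synthetic generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## Geometry model

The instrument is a two-axis diffractometer: the crystal rotates
continuously about the vertical axis ($\varphi$), an image frame is read
out every $\Delta\varphi$, and a cylindrically curved position-sensitive
detector (radius $L$, horizontally curved, vertically flat) records each
frame. Laboratory conventions: incident beam along $+\hat x$, rotation
axis $+\hat z$, the in-plane diffraction angle $2\theta_B$ opening toward
$+\hat y$, $\varphi$ right-handed about $+\hat z$. Angles are degrees at
every interface and radians internally; channels are 0-based and
fractional, so centre-of-gravity coordinates flow through unchanged.

Channels map to angles through four constants and one coupling:

$$2\theta_B = 2\theta_c + c_x\,(X - X_0 - s\,(Y - Y_0)), \qquad
  \chi_d = \arctan\{c_y\,((Y - Y_0) + s\,(X - X_0))\}.$$

* $c_x$ (degrees/channel) is exact for a cylindrical detector: equal
  horizontal channel steps subtend equal $2\theta_B$ arcs.
* $c_y$ (tangent units per channel) enters through an arctangent because
  the detector is flat vertically: a channel step is a step in
  $\tan\chi_d$, not in $\chi_d$. A small-angle linear mode
  (`chi_mode = "linear"`) is kept for cross-checking; at
  $\chi_d = 20^\circ$ the two differ by more than a degree, so the
  tangent form is the default.
* The slope $s$ is modelled as a small *rotation of the channel axes*
  relative to the laboratory axes, entering both conversions with
  opposite signs. This was an open design point: a shear applied to the
  $X$ conversion alone would leave layer lines exactly horizontal, and
  then the calibration protocol that extracts the slope from the tilt of
  the layer lines could never determine it. The rotation form keeps the
  documented $X$-correction $X - X_0 - s(Y-Y_0)$ verbatim *and* makes
  the slope observable: a layer line drawn on the face has tilt $-s$.
  The inverse transform is closed-form:
  $dx = (u + s v)/(1+s^2)$, $dy = (v - s u)/(1+s^2)$ with
  $u = (2\theta_B - 2\theta_c)/c_x$, $v = \tan\chi_d / c_y$.

A detector direction gives the scattering vector (no $2\pi$ convention,
$|q| = 1/d$):

$$\hat s = (\cos\chi_d \cos 2\theta_B,\; \cos\chi_d \sin 2\theta_B,\;
\sin\chi_d), \qquad Q_{lab} = (\hat s - \hat x)/\lambda, \qquad
q = R_z(-\varphi)\, Q_{lab},$$

and the total scattering angle obeys
$\cos 2\theta = \cos\chi_d \cos 2\theta_B$.

### The packaged instrument profile

The `"hanaro"` profile carries the curved-detector machine constants:
$c_x = 0.2614$, $c_y = 0.003917$, $s = 0.0041$,
$(X_0, Y_0) = (181.50, 94.135)$, arm angle $40^\circ$, $L = 530$ mm,
512-channel readout. Two of the printed ranges required interpretation:

* The elevation range is stored as $(-18.43^\circ, +34.5^\circ)$. The
  negative sign of the lower bound is our reading (the source table's
  formatting collapses it); it is strongly supported by the physics: at
  $\lambda = 0.8912$ Å on NaCl the layer elevations are
  $\chi_d(l=-2) = -18.42^\circ$ and $\chi_d(l=+3) = +28.3^\circ$ while
  $l=-3$ and $l=+4$ fall at $\mp 28.3^\circ/39.2^\circ$ — exactly the
  reported "layers $-2$ to $+3$ captured, $l=-2$ partial at the
  boundary" behaviour, which the acceptance suite checks.
* The active $Y$ window is stored as $(9.06, 269.60)$ channels — the
  image of the elevation range under $Y = Y_0 + \tan\chi_d / c_y$, about
  260 channels high, consistent with the 252-channel active height of
  the readout. The printed window $(100, 360)$ would exclude the equator
  $Y_0 = 94.135$ entirely and is not usable as-is; both bounds remain
  plain config values that a user can override.

## Simulator

`predict_spots()` solves the rotation-method diffraction condition for
every reflection: with $q = UB\,h$, a crossing at rotation $\varphi$
satisfies $(R_z(\varphi) q)\cdot\hat x = -\lambda |q|^2/2$, i.e.
$\rho\cos(\varphi - \delta) = -\lambda|q|^2/2$ with
$\rho = \sqrt{q_x^2+q_y^2}$ — zero, one (tangent) or two solutions
(entry/exit branch). Reflections with $\rho < |\lambda|q|^2/2|$ never
cross: that is the blind region, reported as "no solution" rather than
clamped. Both branches are rendered and kept as separate observations
downstream; the reduction averages branch duplicates of one $hkl$ with
$1/\sigma^2$ weights, treating each crossing as an independent
measurement of the same $|F|^2$.

`render_frames()` deposits each spot as a separable Gaussian:
pixel-integrated ($\Phi$-difference) profiles in $X$ and $Y$, and a
Gaussian partition of the total intensity over frames in $\varphi$,
truncated at $4\sigma$, wrapping across $0/360^\circ$ for full-circle
scans. Defaults $\sigma_x = 1.34$, $\sigma_y = 1.13$ channels are the
instrument point-spread FWHM (3.16 and 2.66 channels) divided by 2.355;
$\sigma_\varphi$ models mosaic spread plus beam divergence. Intensities
are user-assigned — there is no structure-factor physics, no extinction,
no absorption — so tests can only validate *geometry, bookkeeping and
statistics*, not scattering physics. Poisson noise is optional and
seed-reproducible.

The demo profile uses a 320 × 240 face, $\Delta\varphi = 1^\circ$
(360 frames) and $\sigma_\varphi = 0.6^\circ$, i.e. spots span about
three frames as real mosaic reflections span several 0.2° frames. These
sizes make a complete simulate→reduce cycle run in seconds while keeping
every algorithmic regime (multi-frame spots, both branches, window
boundaries) exercised; they are study conditions, chosen once.

## Peak search and integration

Seeds are 8-neighbourhood local maxima above the user threshold,
processed in decreasing height. The square box (default 11 channels) is
re-centred on the background-subtracted centre of gravity until the
centre pixel is stable (max 20 iterations; oscillation is flagged, the
last centre kept; ties broken by `round`). Background is the mean of the
box's 1-pixel border rim — the original package's "successive masking" is
not specified anywhere, so the rim estimator is our stated substitute —
and the net intensity is $\sum(\text{inner}) - n_{inner}\bar b$ with

$$\sigma^2 = \textstyle\sum(\text{inner}) +
  (n_{inner}/n_{rim})^2 \sum(\text{rim}),$$

the Poisson propagation including the background-estimate variance.
Claimed inner pixels are masked so no pixel feeds two peaks; overlapping
reflections are handled greedily (strongest first) and are best-effort
only — the integration scheme assumes each reflection is isolated within
its box, and no deconvolution is attempted.

Merging is single-linkage over $(X, Y)$ within `xy_tol` (default 1.5
channels) and frame distance $\le$ `gap_tol` + 1 (default strictly
consecutive), wrapping across the scan boundary for 360° scans. A 3D
peak is *partial* when its span touches the first/last frame of a
non-circular scan, a member box touches the face edge, or its centroid
leaves the active window. By default the integrated intensity is the
exact sum of member nets. When the stack is available the group is
re-integrated with a fixed box over its span extended by one frame each
side: the leading/trailing frames of a spot hold a few percent of its
mass but fall below any sensible threshold, and without them the
integral is biased low by $\sim 1\sigma$ under counting noise. One frame
(not more) of extension is used because reflections of adjacent layer
index can pass within a few channels of the same face position a few
degrees of $\varphi$ later; wider extensions start swallowing their
rising edge. With this scheme the pull distribution
$(I - I_{true})/\sigma$ on seeded Poisson stacks is centred
($|\mu| < 0.1$) with unit width ($0.95$–$1.0$), which the test suite
checks on 600+ spots.

## Indexing

*Vector minimum.* Candidates are the observed $q$ and all pairwise
differences, sorted by length and merged (up to sign) into running-mean
clusters. The nominal merge radius is $10^{-4}$ Å⁻¹, but it adapts to
$2\%$ of the shortest candidate length: centre-of-gravity noise on real
(and rendered) data exceeds $10^{-4}$, and without the adaptive radius
the shortest-candidate list fills with noisy copies of one basis vector.
Cluster averaging also beats the noise down. The shortest linearly
independent triples (|det| above $10^{-6}$ Å⁻³) are tried in order until
one integer-indexes at least 80% of the observations within the 0.1
indexing tolerance; the winning basis is polished by least squares
against the points it indexes. The residual is measured in fractional
$hkl$ units — the natural scale for "0.1 reciprocal-space distance" —
and is configurable.

*Two/three-reflection constructions* are the classical ones: $B$ from
the cell, $U$ from aligning the orthonormal frames spanned by
$(Bh_1, Bh_2)$ and $(q_1, q_2)$; or $UB = [q_1 q_2 q_3][h_1 h_2 h_3]^{-1}$
with no cell assumed. Norm mismatches beyond 2% and collinear or
coplanar inputs are hard errors.

*Monte-Carlo with a known cell* samples orientations uniformly on SO(3)
(normalised Gaussian quaternions, mandatory seed). Trials are scored on
the twelve shortest observed $q$ only — low-order reflections move
slowest in index space under misorientation, so a coarse random hit is
recognisable there, which cuts the required trial count by orders of
magnitude — and the best trial is grown by iterated polish/re-index
cycles (tolerance $2\times$ then $1\times$) over the full set.

*Bravais assignment* reduces the basis to a Buerger-type shortest cell
(iterated pair subtraction, sign-normalised so the angles are all acute
or all obtuse) and tests metric signatures in decreasing symmetry order:
cubic P, F (all-60° primitive), I (all-109.47°), rhombohedral,
hexagonal, tetragonal P, orthorhombic P and C, monoclinic P (unique axis
carried to $b$ by a cyclic permutation, $\beta \ge 90$ by a double sign
flip), triclinic P. Tolerances: 0.2% on lengths, 0.2° on angles. The
integer map $m = UB_{conv}^{-1} UB_{orig}$ is verified to be integral
before a candidate is accepted. Other centerings (oF, oI, tI, mC) fall
through to a lower-symmetry description; that is a documented
limitation, not a failure mode — the lattice is still correct, just not
maximally symmetrised.

*Refinement* is linear least squares of the nine UB elements against
indexed $(h, q)$ pairs (three independent regressions sharing one design
matrix), with cell standard uncertainties by the delta method through
the reciprocal metric. On noise-free data it reproduces the generator UB
to $10^{-10}$; under $10^{-3}$ Å⁻¹ Gaussian $q$ noise the recovered cell
covers the truth within 3 s.u., and the residual norm never increases.

## Calibration

The fits run in the documented order — $c_x$/$X_0$ from arm stepping,
then $Y_0$/slope/$c_y$ from layer lines, then $\lambda$ — each consuming
the previous results.

* **Arm scan:** a fixed equatorial reflection is imaged while the
  detector arm steps (5° default). $X$ moves linearly with the arm angle
  at slope $-1/c_x$; the sign convention (spot moves to lower $X$ as the
  arm angle grows) is asserted and would be caught immediately on a
  mirrored instrument. $X_0$ is only identifiable when the reflection's
  true $2\theta_B$ is known (cell and wavelength), so it is reported
  only when that is supplied — the wavelength is calibrated *later* in
  the chain, and pretending to know $X_0$ before it would be circular.
* **Layer lines:** peaks of a full rotation are clustered in $Y$ by gap
  splitting, each band fitted with a Siegel repeated-median line (single
  spurious peaks cannot tilt a band), the common tilt giving $s$, the
  $l=0$ band's height at $X_0$ giving $Y_0$, and the band heights
  $\tan(\arcsin(\lambda l / c))/c_y$ giving $c_y$ by a weighted linear
  fit. Band indices $l$ are assigned by searching the integer offset
  that best explains the spacings (with $c_y > 0$ enforced). A
  single-band input yields $Y_0$ and slope with $c_y$ flagged unfitted.
* **Wavelength:** each indexed equatorial reflection gives
  $\lambda_i = 2 d_{hkl}\sin\theta_i$ from its $X$ channel; the estimate
  is the mean with scatter-based s.u. Noise-free simulated spots at the
  primary wavelength return it to better than $10^{-3}$ Å; seeded
  0.2-channel noise gives t-interval coverage between 90 and 99% over
  200 replicates (checked in the suite).

## Lorentz correction and classification

For the fixed-$\chi$ rotation geometry the Lorentz factor is

$$L = \frac{1}{\cos\chi_d\,\sin 2\theta_B},$$

which reduces to $1/\sin 2\theta$ on the equator. Because the literature
states this form by citation rather than derivation, the test suite pins
it against an independent numerical oracle: the finite-difference speed
at which the rotating reciprocal point crosses the Ewald sphere,
$L = 1/(\lambda\,|dg/d\varphi|)$ with
$g(\varphi) = |R_z(\varphi)q + \hat x/\lambda| - 1/\lambda$ — agreement
within 0.1% on 100 random reflections. Inside the blind-region guard
($\cos\chi_d \sin 2\theta_B \le 10^{-3}$) the correction is refused and
the reflection flagged rather than silently scaled.

Classification matches predictions to observations greedily by
(frame, X, Y) distance inside a $\varphi$ window, one observation per
prediction, then applies the 0.1-criterion on the fractional-index
residual: `good_peak` within, `no_good_peak` when a peak sits nearby
(within $3\times$ the tolerance — our operational definition of
"nearby") but fails it, `no_peak` when nothing is there, and
positional labels for predictions off the scanned $\varphi$ range
(`out_of_expected_region`, defined here as on-face but outside the scan;
the original label's exact region is undocumented and our reading is
flagged in the output) or off the active area
(`out_of_experimental_area`). `partial` propagates from the integration
flag. The labels are exhaustive and mutually exclusive by construction.

## Numerical choices and degenerate inputs

Angles in degrees at interfaces, radians internally; all file formats are
plain text except the raw frame binaries (little-endian by definition of
the dialect, 4-byte full / 2-byte reduced with saturation at 65535 and a
warning). Channel round trips are exact to $10^{-9}$; rotations compose
to $10^{-12}$. Degenerate inputs fail loudly: non-positive cell
discriminants, coplanar index triples, rank-deficient designs, singular
UB, truncated binary frames (error names the frame), schema violations
(error names row and column), fixed-width export overflow (error names
the reflection).

## Known limitations

* No absorption, extinction or polarization corrections, no scaling or
  merging across scans beyond entry/exit branch averaging, no structure
  refinement.
* No profile fitting or deconvolution of overlapped spots; dense
  patterns degrade gracefully (flagged, best-effort) rather than being
  modelled.
* Bravais search does not symmetrise oF/oI/tI/mC centerings.
* The simulator emulates layer-line structure, multi-frame spots,
  partial boundary peaks and Poisson statistics, but not detector
  efficiency maps, delay-line nonlinearity, γ background, harmonics or
  resolution-function anisotropy; passing tests demonstrate correctness
  of the reduction chain, not detector physics.
* Prediction coverage counts vary by a few percent with crystal
  orientation at the demo face size (window boundary effects); only a
  rotation about the scan axis leaves coverage exactly invariant.
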