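---
title: "Methods: multi-parametric single-cell mechanics with cellmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-parametric single-cell mechanics with cellmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

cellmech implements an integrated analysis for experiments that combine
traction force microscopy (TFM), AFM force spectroscopy, fluorescence
recovery after photobleaching (FRAP) and fluorescence correlation
spectroscopy (FCS) on single adherent cells grown on elastic polyacrylamide
substrates. The scientific question the pipeline serves is whether the
traction a cell (or a single focal-adhesion region) exerts on its substrate
covaries with the unbinding kinetics of adhesion proteins such as zyxin.
Because raw microscopy data for such studies are rarely deposited, the
package ships a seeded synthetic-data generator for every stage, so each
estimator can be validated against known ground truth.

## Substrate elasticity from AFM force curves

An approach force-distance curve on a soft gel consists of a flat baseline
followed by a contact branch. For a conical tip of half-opening angle
$\alpha$ indenting an incompressible elastic solid, the force-indentation
law is

$$F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan\alpha\;\delta^2 ,$$

with Young's modulus $E$, Poisson's ratio $\nu$ (0.5 for polyacrylamide)
and indentation $\delta$. `fit_sneddon()` linearizes this as $F$ versus
$\delta^2$ and converts the slope; the error follows from linear-fit
theory.

The contact point is not observable directly. `find_contact_point()` uses
an exhaustive piecewise-model search: every interior sample is tried as the
split between a constant baseline and a quadratic contact branch, and the
candidate minimizing the total squared residual wins (ties to the earliest
candidate). The winning position is then refined continuously between its
neighbouring samples by one-dimensional minimization of the same objective;
without that refinement the fitted modulus inherits a bias of order 0.1 %
from the sampling grid alone. The default fit window, $\delta$ between 10 %
and 90 % of the maximum indentation, excludes both the noisy toe region near
contact and any deep-indentation nonlinearity; it is configurable. The tip
half-angle has no default — it is instrument metadata the user must supply.

Aggregation follows the convention of force-spectroscopy campaigns: each
experiment contributes the mean of its accepted curve fits, and the
substrate value is the mean of per-experiment means with the standard error
taken across experiments.

## Deformation fields by multi-pass PIV

Substrate deformation is read from pairs of fiducial-bead images: PRE (cell
attached, substrate deformed) and POST (cell removed, substrate relaxed).
The displacement extraction is windowed cross-correlation, refined over a
schedule of interrogation windows (default 64, 32, 16 px, 50 % overlap),
each pass seeding the next with integer predictor offsets so the final
small windows only measure a sub-pixel residual.

Per window the package computes the *normalized* cross-correlation: the
correlation is evaluated by zero-padded FFTs together with the per-lag
overlap sums of each window's intensity and squared intensity, so that each
lag is scored by the correlation coefficient over the actual overlap
region. This choice matters: the raw circular correlation of aperiodic
windows carries a triangular $(n-|d|)/n$ envelope, and bead images whose
spots are truncated by window edges then produce a systematic bias of the
interpolated peak towards integer displacements (we measured up to
0.25 px at 16-px windows with 2-px spot sigma). With per-lag normalization
the same configuration recovers imposed sub-pixel translations with
~0.05 px RMS error. Sub-pixel peak position uses 3-point Gaussian
interpolation per axis with a parabolic fallback where correlation values
are non-positive; the per-window signal-to-noise ratio is the ratio of the
highest correlation peak to the second peak outside a 7×7 exclusion zone
(the zone must clear the main peak's own shoulder).

Spurious vectors are handled with the standard cascade: an SNR filter
(default threshold 1.3), a global filter (beyond 3 sd from the field mean),
a local filter (beyond 2.5 local sd from the 3×3 neighbourhood median) and
an optional mask for regions without beads. Deviations below 0.05 px are
never flagged — they are within peak-interpolation accuracy, and without
that floor an essentially perfect field would have windows flagged on
numerically zero variance. Flagged windows are replaced by their nearest
valid neighbour (ties to the lowest grid index), so downstream inversion
always receives a complete field. Rigid stage drift between acquisitions is
estimated by the same normalized correlation on a user-chosen quiet region
and removed by bilinear resampling; the in-focus plane pair of a z-stack is
chosen by running a coarse single-pass PIV on every pair and keeping the
pair with the largest mean displacement.

## Traction reconstruction (regularized FTTC)

For an elastic, isotropic half-space the surface displacement is the
convolution of the traction with the Boussinesq response; in Fourier space
the relation is algebraic, $\hat u(k) = G(k)\hat T(k)$, with

$$G(k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\
-\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix}.$$

`fttc_inverse()` solves the zeroth-order Tikhonov problem per mode,
$\hat T = (G^\top G+\lambda^2 I)^{-1}G^\top\hat u$. Numerical choices:

* the $k=0$ mode is set to zero, which enforces global force balance; after
  cropping a padded grid the window mean is subtracted again so the
  returned field is balanced exactly;
* grids are zero-padded to twice their extent by default, pushing the
  implicit periodic images away from the field of view (removable with
  `pad = FALSE`, which makes forward plus inverse an exact pair on the
  periodic domain);
* on even grids the unpaired Nyquist modes have no negative-$k$ partner, so
  the odd-in-$k$ off-diagonal entry of $G$ is zeroed there; without this
  the operator maps real fields to non-real ones and the inversion is wrong
  at those modes.

The half-space assumption requires gel thickness and patch size large and
small, respectively, against the field of view; with ~50 µm gels and
deformations below 1 µm this holds comfortably.

The regularization parameter is chosen by the L-curve criterion
(`select_lambda()`): residual norm $\rho(\lambda)$ (over the measured
window) against solution norm $\eta(\lambda)$ on a log-spaced grid (default
28 points over 7 decades scaled to the mid-band singular value of $G$),
curvature from first and second finite differences of
$(\log\rho,\log\eta)$ after 5-point smoothing, corner at maximum curvature,
ties to the smaller $\lambda$. One behaviour of this criterion deserves
emphasis, because it is a property of the operator and not of the
implementation: FTTC's inverse amplifies noise only linearly in $k$, so
white displacement noise concentrates its solution-norm cost at the highest
wavenumbers, whose singular values lie *below* the band occupied by the
traction signal. The curvature corner for noisy data therefore sits at or
below the corner found for the same field without noise — the selected
$\lambda$ does not grow monotonically with the noise level. What does hold,
and what the test suite verifies over seeds, is that inverting noisy data
at the L-curve $\lambda$ is consistently more accurate than inverting at
$\lambda = 0$.

Cell-level summaries apply a mask — segmented from a fluorescence image by
Otsu threshold, morphological closing and largest connected component, or
rasterized from a hand-drawn polygon — to the deformation and traction
maps: mean deformation magnitude $D$, mean traction magnitude $T$, and
total force $F = T \times \text{area}$. Sub-cellular summaries average
$|T|$ over a square window of ~20 µm² centred on each probed
focal-adhesion region; averaging several adhesions reduces the error of
attributing traction to a single ~2.5 µm² adhesion.

## FCS: diffusion from intensity autocorrelation

`compute_acf()` estimates
$G(\tau)=\langle\delta I(t)\,\delta I(t+\tau)\rangle/\langle I\rangle^2$
by sub-record averaging: the trace is cut into non-overlapping sub-records
(default $2^{13}$ samples), each mean-subtracted, zero-padded to twice its
length (so the FFT correlation is linear, not circular), normalized
per lag by the number of contributing products, and divided by the squared
sub-record mean; curves are averaged and per-lag standard errors reported.
Dark sub-records are excluded and counted. The estimator agrees with a
direct $O(N^2)$ lag-sum to $10^{-10}$, which the suite asserts.

Fitting uses the 3D-Gaussian-volume diffusion model

$$G(\tau)=\sum_i G_{0i}\left(1+\tau/\tau_{Di}\right)^{-1}
\left(1+\tau/(\omega^2\tau_{Di})\right)^{-1/2},\qquad
\tau_{Di}=\frac{w_r^2}{4D_i},$$

with the aspect ratio $\omega$ fixed from calibration. Fits are weighted by
the inverse squared per-lag SE when available, after resampling onto a
quasi-logarithmic lag grid so every decade carries comparable weight. The
two-component path runs the Levenberg–Marquardt core directly because a
degenerate (single-species) curve collapses the components onto each other
and the converged Jacobian is singular — a legitimate outcome that the fit
reports as a collapse note rather than an error. `choose_model()` then
prefers the 1-component description when the 2-component times collapse
within their joint SE or when any 2-component parameter is poorly
determined (relative SE above 50 %) while the simpler fit's residual is not
substantially worse. The detection volume is calibrated with a dye of known
diffusion coefficient (fluorescein, 425 µm²/s) by inverting
$w_r=\sqrt{4D\tau_D}$.

The Brownian-dynamics generator simulates point emitters in a periodic box
weighted by a 3D-Gaussian detection profile with Poisson photon counting.
Two of its artefacts are worth knowing: the fixed number of molecules in a
closed box suppresses the Poisson number fluctuations of an open volume
(visible as a small negative offset at long lags, growing with molecule
count), and sub-record mean subtraction absorbs correlation tails slower
than the sub-record length — with $\omega=5$ the axial decay is
$\omega^2\tau_D$, so sub-records should span many axial times (the test
suite uses $2^{16}$ samples at 50 kHz for this reason).

## FRAP: unbinding kinetics

When unbound protein diffuses much faster than its binding kinetics
(reaction-dominant limit), the recovery of a photobleached adhesion region
reflects dissociation alone, $F(t)=m(1-e^{-k_{\rm off}t})$, with mobile
fraction $m$; the residence time is $t_{\rm res}=1/k_{\rm off}$, always
derived from the unrounded fitted rate. The double normalization in
`normalize_frap()` first references the bleached-adhesion intensity (above
the cytoplasm level) to a control adhesion in the same cell,
$I_{\rm FRAP}=(I_{\rm PH\text{-}FA}-I_{\rm Cyt})/(I_{\rm C\text{-}FA}-I_{\rm Cyt})$,
cancelling any multiplicative acquisition photobleaching shared by the
regions, then anchors the curve between the first post-bleach value and the
pre-bleach mean. The generator constructs region intensities so this
normalization recovers $F(t)$ to machine precision at zero noise, including
under a per-frame acquisition-bleach decay — a round trip the suite checks
at $10^{-12}$.

`fit_recovery()` is an unweighted nonlinear least-squares fit (a weighted
option exists), initialized from the late-time plateau and the half-rise
time, with box constraints $k_{\rm off}\in(10^{-4},10)$ s$^{-1}$ and
$m\in(0,1.5)$ to stabilize the optimizer; solutions touching a bound, a
mobile fraction above 1, or a fitted span shorter than $1/k_{\rm off}$ are
flagged rather than silently accepted. The default acquisition schedule is
the usual two-rate protocol: frames every 1 s for 40 s, then every 4 s for
another 40 s, with at least 5 pre-bleach frames.

## Joining modalities

`region_average_traction()` ties each FRAP site to its local traction;
`correlate_mech()` fits the ordinary least-squares line and Pearson $r$
between residence time and traction at either the cellular level (cells on
substrates of different stiffness) or the subcellular level (regions of one
or more cells on the same substrate); regressions are unweighted by default
with a weighted option, since error bars on both axes make weighting a
modelling choice rather than a default. Group contrasts use the two-sided
Mann–Whitney rank-sum test, exact for group sizes up to 12 without ties
(verified against exhaustive enumeration in the suite) and
normal-approximated with tie correction otherwise.
`simulate_cell_experiment()` wires every stage together with a residence
time linearly coupled to regional traction, and `build_report()` joins the
per-cell and per-region tables and computes both correlations, emitting
byte-identical tables for identical seeds.

## What the generator does and does not emulate

The synthetic scenes reproduce the features the estimators rely on:
elliptical ~2.5 µm² adhesion patches of uniform stress at the cell
periphery pulling centripetally, exact force balance (enforced by a
uniform correction of the patch stress vectors, and again on the rasterized
grid so the zero Fourier mode vanishes), linear-elastic half-space
response, ~40 nm beads rendered as Gaussian spots (default sigma 2 px at
69 nm pixels) with Poisson photon and Gaussian read noise, single
exponential recovery with shared acquisition bleaching, and Brownian
emitters in a 3D-Gaussian volume. They do not emulate: optical aberrations
or depth-dependent PSFs, bead polydispersity or aggregation, substrate
nonlinearity or finite thickness, photophysics beyond bleaching (blinking,
triplet states), or spatially resolved diffusion during FRAP. Passing tests
therefore certify the estimators under the stated model, not robustness to
every optical artefact of real data. Default bead density (0.3 µm⁻²) and
spot brightness are stated configuration, not values inferred from any
specific instrument; the test suite mostly uses a denser 1.2 µm⁻² field so
that 16-px interrogation windows carry signal.

## Problem sizes and reproducibility

Every generator is a pure function of its parameters and an explicit
integer seed. The test suite runs scenes of 48 µm at 64×64 inversion
grids, bead images of ~260 px, a 60 s Brownian FCS trace at 50 kHz, 100–200
seeded FRAP fits, and a forward-model validation against real-space
Boussinesq quadrature on a 1024² grid — sizes chosen so the full suite
completes in about a minute while each check retains its statistical power.
The acceptance script (`scripts/acceptance.R`) regenerates its inputs from
scratch at whatever seed it is given.

## Known limitations

* The padded forward/inverse pair loses information where the displacement
  field is cropped at the window edge; with a margin of twice the cell
  radius the round-trip error is ~5 % in L2 and concentrated at the
  boundary.
* The L-curve corner does not track the noise level upward for this
  operator (discussed above); users who need noise-adaptive regularization
  should compare reconstructions across the $\lambda$ grid that
  `select_lambda()` returns.
* PIV windows below 16 px with spot sigma 2 px leave few beads per window;
  the SNR filter then discards a substantial fraction of windows, which the
  nearest-neighbour interpolation fills from sparser support.
* The FRAP model assumes the reaction-dominant limit; fast-diffusing
  contributions appear as an early-time excess the single-exponential fit
  absorbs into its parameters.
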