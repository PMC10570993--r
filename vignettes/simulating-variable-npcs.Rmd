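---
title: "Simulating structurally variable NPCs: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating structurally variable NPCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcsim)
```

## Why simulate ground truth

Single-molecule localization microscopy resolves individual nucleoporins,
but its noise floor is of the same order as the structural variability of
the nuclear pore complex itself. Analysis software (fitting, clustering,
particle averaging) therefore cannot be validated against real data alone:
the "true" variability of any imaged pore is unknown. `npcsim` generates
coordinate datasets in which every pore's geometry and irregularity are
known exactly, together with ground-truth features fitted to the noise-free
coordinates. Downstream photophysics simulators turn the exported
localization tables into realistic images; the feature tables stay behind
as the answer key.

## The model

A *rotational unit* lists the fluorophore attachment sites of the selected
Nups in one spoke: axial position $z_j$, radius $r_j$, angle $\alpha_j$, and
a subcomplex tag (CR, BRCR, IR, BRNR, NR). Angles are measured
counter-clockwise viewed from the cytoplasmic side; the cytoplasmic side is
$+z$; all lengths are nm (ångström inputs are divided by 10 at load time).
Selecting labels fixes a global angular offset: single-channel selections
centre the mean angle at zero; multichannel selections with a reference
channel centre the reference channel's mean instead, shifting all channels
equally, so the reference Nup is directly comparable between single- and
multichannel runs. Assembly reflects the $g$ selected sites $s$ times
(default $s = 8$) around the central axis at offsets $2\pi k/s$, producing
$m = g\,s$ *nodes* in $g$ bands.

### Geometric variability

Seven operators modify the assembled model. Axial operators act per *side*:
the subcomplex with the greatest mean $z$ is the cytoplasmic side (CS), the
least the nucleoplasmic side (NS); bands of sandwiched subcomplexes receive
values interpolated linearly in their mean $z$ — the minimal scheme
consistent with "interpolated", applied uniformly to height displacement,
twist angle, shift offset and tilt rotation angle. With only one subcomplex
selected, axial operators are inapplicable and warn instead of failing.

* **height** $d$: all $z$ are rescaled affinely about the model mean $z$ so
  the CS–NS mean-$z$ difference equals $d$. Rescaling (rather than moving
  one side) keeps the model centred; only $z$ changes.
* **twist** $\theta$: each band rotates about the axis by $w(\theta -
  \theta_{\mathrm{current}})$, $w$ its side weight (NS 0, CS 1). The
  measured twist is the circular mean over spokes of the per-spoke
  difference between circular-mean CS and NS node angles, wrapped to
  $(-\pi, \pi]$; circular means avoid wrap artefacts that raw averages of
  angles would create.
* **tilt** $\kappa$: each side independently draws a unit vector from a von
  Mises–Fisher distribution about $+z$ (inversion sampling of the polar
  cosine) and rotates rigidly about its own centroid so its normal aligns
  with the draw; smaller $\kappa$ means more tilt. Rotating about the side
  centroid (not the central axis) keeps tilt from doubling as a lateral
  shift; whether the original implementation does the same is unknown, so
  this is a documented package choice.
* **shift**: each side translates laterally by an independent
  $N(0, \sigma^2)$ draw per axis.
* **radius**: all lateral coordinates scale by $r_{\mathrm{new}}/\bar r$,
  so label spacing grows in dilated pores.
* **elongation** $q$: see below — implemented as forces, not as a direct
  coordinate map.
* **symmetry** $s$: the geodesic (arc) distance between adjacent same-band
  Nups is held constant, $\bar r_{\mathrm{new}} = \bar r\, s_{\mathrm{new}}/s$,
  and each band keeps its offset from the mean radius. Arc length is the
  geodesic on a circle; this reading makes 9- and 10-fold pores wider, as
  observed. (The chord reading, scaling by
  $\sin(\pi/s)/\sin(\pi/s_{\mathrm{new}})$, differs by <1% at $s = 8$
  versus 9 and is noted as the alternative.)

Any continuous parameter $X$ may carry an SD, in which case each NPC draws
$X' \sim N(X, \sigma^2)$; rotational symmetry is discrete and is never
resampled. Operators apply in a fixed order — symmetry, radius, height,
twist, tilt, shift, then force-based deformation, then axial offsets —
discrete/scaling first, rigid motions next, forces last. The order matters
(e.g. radius rescaling after shift would scale the shift too) and is fixed
package-wide.

### Irregular variability

Each band is an independent spring system: radial springs anchor nodes to
the central axis (the membrane's contribution), circumferential springs
connect each node to its $2h$ nearest same-band neighbours
(protein–protein contacts), $h = 2$ by default — fewer neighbours deform
jaggedly, more cost time. Stiffness is $k_c(h') = K/\ell_0(h')$, so shorter
springs are stiffer, and $k_r = k_c(h_{\max})/2$, so radial springs are the
weakest, reflecting the assumption that protein–protein interactions beat
protein–membrane ones. The exact published constants are not available;
$K = 98.69$ is fixed from the closed-form equilibrium of a uniformly loaded
ring so that a uniform radial force of 10 dilates the default ring
(radius 50 nm, $s = 8$, $h = 2$) by 2 nm:
$f = \delta\,[k_r + \sum_{h'} 4 k_c(h') \sin^2(\pi h'/s)]$.

Scalar forces on all $m$ nodes are drawn jointly from
$N(0, \mathrm{cov}')$ with
$\mathrm{cov}(x_i, x_j) = \exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$ and
$\mathrm{cov}' = (D_{\mathrm{mag}}/3)^2\,\mathrm{cov}$: the user magnitude
$D_{\mathrm{mag}}$ (nm) is three marginal SDs, covering ~99.7% of draws.
Sampling jointly over all bands (not per band) is what keeps adjacent bands
coherent. Distances enter the kernel with every node's lateral radius
replaced by the global mean $\bar r$ (angle and $z$ kept), so concentric
bands of different radius receive identical forces and stay concentric.
$\sigma = 0.5\,\bar r$ by default: small enough for irregular global
shapes, large enough for local coherence.

Each scalar force becomes a *radial, planar* force. We take radial to mean
radial at the node's current position: the force keeps its signed magnitude
and direction along the node's instantaneous lateral unit vector
(potential term $-f_i \lvert x_i \rvert$). Under this reading the force
field exerts zero torque at every configuration, so deforming forces can
never rotate or flip a band — which is the stated reason for using radial
forces. The alternative reading (a force vector frozen at the initial
direction) is *not* rotation-safe: rigid rotation of a band leaves the
spring energy unchanged while the work term varies as $-C\cos\phi$ with
$C = \sum_i f_i \cdot x_i$, so whenever the sampled net force points inward
($C < 0$) the unrotated equilibrium is rotationally unstable and the band
relaxes toward a $\pi$-rotated state; we observed exactly that in ~12% of
bands at $D_{\mathrm{mag}} = 20$ before adopting the rotation-invariant
form.

Equilibrium is computed per band by direct minimization of the total
potential (z frozen), not by integrating damped dynamics: a damped Newton
iteration with analytic gradient and Hessian, Levenberg regularization, a
3 nm per-node step cap and monotone energy decrease. The step cap and
monotone decrease confine the iteration to the basin a damped physical
system would settle into; the exactly neutral rigid-rotation mode is
penalized in the Hessian (orthogonal to the gradient, so unbiased) and
projected out of each step. Convergence requires every node's residual net
force below $10^{-6}$; the largest residual is recorded in the model's
provenance and asserted in the tests.

**Axial offsets** reuse the same kernel and equalized distances with
magnitude $O_{\mathrm{mag}}$ (default $D_{\mathrm{mag}}/2$) from an
independent random stream, added directly to $z$ — axial resolution in SMLM
is poor enough that spring coupling in $z$ would be invisible, and skipping
it keeps the spring model two-dimensional.

**Elongation** is force-based: the target is an ellipse with the area of
the circle of radius $\bar r$, axis ratio $q$, and uniformly random
orientation $\phi_0$. The force on node $i$ is the constant
$f_{e,i} = k_e\,(\rho_{\mathrm{ellipse}}(\phi_i - \phi_0) - r_i)$, the
radial gap to the ellipse at the node's azimuth, added to the stochastic
forces before relaxation. The published sampling formula is unavailable;
the proportional-gap force is the simplest scheme with the required
behaviour. Because it is a constant force (not a spring to the ellipse),
the gain must match the effective per-node stiffness of the elliptic mode:
$k_e = 0.95$ was calibrated once so that $q = 0.8$ relaxes to a fitted
axis ratio within 5% of $q$; exact recovery of $q$ is *not* a contract of
the force-based route.

### Feature extraction

Circle and ellipse fits share a plane: the total-least-squares plane
(centroid plus the two leading principal directions; the normal is the
direction of least variance, sign-fixed to $+z$). Circles are fitted in
plane algebraically (Kåsa) and refined by Gauss–Newton on radial
residuals; ellipses by the numerically stable direct conic fit
(Halir–Flusser) refined by Nelder–Mead on exact point-to-ellipse geometric
distances (Eberly-style root finding), in scale-normalized coordinates so
the fit is equivariant under global rescaling. Three or more non-collinear
points define a circle (three give the circumcircle, RSS 0); five are
needed for an ellipse. RSS is always the sum of squared *3D* shortest
distances to the curve — in-plane residual plus out-of-plane offset — so
out-of-plane irregularity counts. At $D_{\mathrm{mag}} = 0$ the band RSS is
0 to machine precision: all measured RSS is attributable to irregular
deformation, which is what makes it the irregularity readout.

Per-band fits, per-subcomplex fits (all bands with the same tag pooled into
one point set), and a per-NPC record equal to the arithmetic mean of the
band records (circle radii are averaged, not ellipse-derived radii) are
reported, plus twist, height, and the angle of each fit normal to the axis
(tilt). Bands with fewer than three surviving nodes yield an NA row rather
than an error. The comparison ratio `sd_sim/sd_real − 1` quantifies whether
a simulated dataset has too little (negative) or too much (positive) radius
variability relative to a user-supplied real-data SD; real SDs are inputs,
never recomputed from microscopy data here.

## The synthetic reference unit

All tests and the default pipeline use `synthetic_tworing_ru()`: one
C-terminal site on the CR and one on the NR, radius 53.7 nm, 50 nm ring
distance — the geometry of the C-terminally tagged outer-ring scaffold Nup
most used as an SMLM reference standard. It emulates the band structure,
ring separation and radii of tables derived from pseudoatomic models, but
not multi-copy Nups (g per ring > 1), per-band radius/angle offsets, or the
full five-subcomplex anatomy; tests passing on it show the machinery is
correct, not that any particular real Nup's geometry is reproduced. Tables
for real models can be generated from local PDB files with `ru_from_pdb()`
(the numeric values are deliberately not bundled: they must come from the
depositions, not be invented) and are loaded with `load_model_table()`,
whose CSV schema round-trips exactly.

The eight shipped class presets cover commonly observed or hypothesized
variability. The 14° twist, the 9.6° second twist mode, and 9-fold symmetry
are reported values; the remaining magnitudes (10% smaller radius, 20 nm
smaller ring distance, q = 0.8, 3 nm shift SD, tilt κ = 50) are editable
defaults chosen to be clearly visible against the reference geometry, since
the published per-class values are not in the main text.

## Randomness and reproducibility

One master seed drives everything. Named streams (parameters, forces,
axial, tilt, shift, elongation, labelling) derive independent sub-seeds per
NPC, so enabling one variability type never perturbs another's draws and
sweep cells sharing a master seed are comparable. Runs with the same
configuration and seed write byte-identical CSVs (doubles are serialized at
17 significant digits); only the metadata timestamp differs.

## Sizes, tolerances, degenerate inputs

Default problem sizes used by the test suite and the acceptance script:
1000 NPCs per cell for the 3 × 3 radius-SD × deformation sweep (9000 total,
about 80 s), 40–100 NPCs for population-level property checks,
$10^4$–$10^5$ draws for distributional checks with 4–5 σ Monte-Carlo bands.
Geometric operators are identities at their neutral parameters to
$10^{-9}$ nm; twist set/measure round-trips to $10^{-9}$ rad; exact-data
fits recover parameters to $10^{-6}$. Degenerate inputs fail loudly:
collinear points for circle fits, under-determined ellipses, nodes on the
central axis (radial direction undefined), non-positive-definite
covariances beyond a $10^{-10}$ relative jitter, relaxation residuals above
tolerance.

## Limitations

* Variability is static per NPC; no dynamics or transport-coupled motion.
* Bands are mechanically independent; coherence across bands comes only
  from force correlation, not inter-band springs.
* The central axis is straight — no nuclear envelope curvature; per-NPC
  placement in a field of view is a rigid export-time translation.
* Photophysics (blinking, localization error, background) is out of scope:
  the hand-off is the coordinates CSV.
* The model replicates observed or hypothesized variability; it does not
  predict true NPC mechanics.
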