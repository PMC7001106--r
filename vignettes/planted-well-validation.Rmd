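---
title: "Mapping lipid interaction sites and validating free-energy estimators on planted-well membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lipid interaction sites and validating free-energy estimators on planted-well membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsite)
```

## The scientific problem

Ion channels and other membrane proteins often carry specific interaction
sites for minority lipids — phosphoinositides such as PIP$_2$ at clusters of
basic residues, cholesterol at grooves between transmembrane helices — and
the strength and selectivity of these interactions is quantified from
coarse-grained simulation data by a standard chain of analyses:

1. **Site mapping**: time-averaged occupancy densities of lipid head groups
   on a volumetric grid, thresholded into connected high-density components;
   distance-to-site traces; per-residue contact-duration fingerprints.
2. **Free-energy profiles**: umbrella sampling along an in-plane
   distance-type reaction coordinate, unbiased with the weighted histogram
   analysis method (WHAM), summarised by the well depth of the bulk-zeroed
   potential of mean force (PMF).
3. **Alchemical cross-check**: relative binding free energies
   ($\Delta\Delta G$) between lipid species from free energy perturbation
   over a $\lambda$ ladder, estimated with the multistate Bennett acceptance
   ratio (MBAR), compared against the difference of PMF well depths.
4. **Geometric characterisation** of bound poses: hydrogen-bond counts over
   time and superposition-based ligand RMSD traces.

Every step of that chain is easy to get subtly wrong, and on real simulation
data there is no ground truth to catch the error.  memsite therefore pairs
the full analysis chain with a **synthetic membrane whose answers are known
in advance**: lipids diffuse by overdamped Langevin dynamics in the membrane
plane, binding sites are radial Gaussian wells of *chosen* depth, and the
estimators are accepted only when they return the planted numbers.

## The surrogate membrane model

Mobile particles (lipid head groups, ligands) move in the periodic membrane
plane by the Euler–Maruyama update

$$x \leftarrow x + \frac{D}{k_BT}\,F(x)\,\Delta t + \sqrt{2D\,\Delta t}\;\eta,
\qquad \eta \sim \mathcal N(0, 1),$$

at $T = 310$ K ($k_BT = 2.5775$ kJ/mol).  Protein and site-anchor particles
never move.  The potential landscape is built from three primitives:

* **Site wells** $U(r) = -D_0\,e^{-r^2/2\sigma^2}$ with $r$ the in-plane
  minimum-image distance to the anchor.  $D_0 \ge 0$ (kJ/mol) is the planted
  depth, $\sigma$ (nm) the width; wells act only on their configured species.
* **A soft protein wall**, harmonic for $r$ inside a core radius, which
  keeps lipids off the pore axis; the wells sit on its rim, like a binding
  pocket at the protein–lipid interface.
* **Harmonic biases** on a signed in-plane coordinate: umbrella windows
  $\tfrac{k}{2}(s - s_i)^2$ and an off-axis lateral restraint.

Two deliberate simplifications (and what they mean for the tests):

* **Lipids do not interact with each other.**  The analyses validated here
  are single-molecule site statistics; the dilute limit is also what makes
  the planted depth an exact target (below).  Crowding, lipid–lipid
  correlations and finite-size competition effects of real membranes are
  *not* emulated, so passing tests say nothing about those.
* **Motion is quasi-2D** (x, y periodic, z fixed per leaflet).  Flip-flop,
  membrane undulations and 3D solvent exchange are out of scope.

The default surrogate diffusion coefficient is $D = 0.1$ nm$^2$/ns.  No
claim is attached to this number — coarse-grained lipid diffusion constants
are model artefacts anyway — it simply sets how many independent site visits
a given wall-clock budget buys.

### Mixed-bilayer composition

`build_bilayer()` reproduces an in-vivo mimetic plasma-membrane composition:
outer leaflet PC:PE:SM:GM3:CHOL = 40:10:15:10:25, inner leaflet
PC:PE:PS:PIP$_2$:CHOL = 10:40:15:10:25.  Species counts are
largest-remainder apportionments of fraction $\times$ count (ties broken by
species name, so builds are reproducible), which makes the overall PIP$_2$
mole fraction exactly 5% for equal leaflet sizes:

```{r composition}
sys <- build_bilayer(bilayer_spec(lipids_per_leaflet = 200), seed = 1)
overall_mole_fraction(sys, "PIP2")
```

## Why the planted depth is the exact PMF ground truth

The reaction coordinate is the *signed* projection $s$ of the head-group
displacement from the site-anchor COM onto an in-plane axis (signed, because
the default window ladder starts at $-0.7$ nm, behind the anchor, which an
unsigned distance cannot reach).  During umbrella and alchemical sampling
the tagged lipid is, by default, clamped to this axis
(`lateral_mode = "axis"`), so the sampled system is exactly one-dimensional
and its free-energy profile is the potential evaluated along the axis:
$G(s) = U(s)$ up to a constant.  A radial Gaussian well of depth $D_0$
therefore yields a bulk-zeroed PMF with $\min_s G = -D_0$ *by construction*,
and the recovery tests compare the estimator output against $-D_0$ directly.

The alternative `lateral_mode = "restraint"` samples the off-axis coordinate
under a finite harmonic restraint $k_\text{lat}$ (default 100
kJ/mol/nm$^2$).  The reconstructed profile then carries a well-curvature
entropy term

$$\Delta G_\text{lat} = \frac{k_BT}{2}\,
  \ln\!\Big(1 + \frac{D_0}{\sigma^2 k_\text{lat}}\Big),$$

about $+2.1$ kJ/mol for $D_0 = 37$, $\sigma = 0.3$, $k_\text{lat} = 100$ —
the sampled minimum is genuinely shallower than $-D_0$ because the well
squeezes the lateral fluctuations.  This mode is provided for studying
exactly that restraint artefact; the depth-recovery guarantees hold in the
axis-clamped mode.

## Umbrella sampling and WHAM

The reference ladder is 38 windows evenly spaced on $[-0.7, 3.0]$ nm
(0.1 nm spacing) with $k = 500$ kJ/mol/nm$^2$; each window starts at its
centre and the first 25% is discarded as burn-in.  All windows are
integrated simultaneously (one independent walker per window), which keeps
the full ladder at roughly the cost of one long run.

`wham()` iterates the standard self-consistent equations on a shared
histogram grid (bin width 0.05 nm) in log space, to a tolerance of $10^{-8}$
kJ/mol on the window offsets (cap $10^5$ iterations).  Three numerical
choices deserve explanation:

* **Disconnected ladders fail loudly.**  If the windows' occupied bins do
  not form a connected graph, the relative offsets across the gap are
  undetermined; `wham()` reports the window centres flanking the gap instead
  of returning an arbitrary profile.
* **Bins with fewer than `min_count = 25` pooled samples are dropped.**
  Bins past the last window centre are reached only by one window's far
  tail; their $-k_BT\ln n$ values fluctuate by several kJ/mol and, for
  shallow wells, an edge bin can otherwise masquerade as the global
  minimum.  The floor only trims these undersampled edges — interior bins
  hold thousands of samples at reference sampling.
* **Bulk zeroing** sets the mean of $G$ over $s \in [2.5, 3.0]$ nm (the
  outermost 0.5 nm of the ladder) to exactly zero; the well depth is then
  simply $\min_s G$.  Any other convention would shift all depths by a
  common constant.

The integrator step for umbrella work is $\Delta t = 0.004$ ns.  The
Euler–Maruyama scheme inflates the stationary variance of a harmonic
coordinate of stiffness $\kappa$ by $1/(1 - \kappa D \Delta t / 2 k_BT)$;
at the stiffest point of the ladder ($\kappa \approx 911$ kJ/mol/nm$^2$:
umbrella plus well curvature $D_0/\sigma^2$) this is a 7% width inflation,
which propagates to a systematic depth error of a few tenths of a kJ/mol —
an order of magnitude inside the $\pm 2$ kJ/mol acceptance band, while the
longer step halves the statistical error at fixed cost.  Repeat-run
calibration (six seeds, 20 kJ/mol well): mean $-19.7$, SD $0.45$ kJ/mol at
reference sampling.

**Errors** come from a block bootstrap: each window's series is resampled in
blocks whose length is set by its integrated autocorrelation time (so
correlated samples are not counted as independent), the profile is rebuilt,
and the SD of the well depth over resamples is reported.
**Convergence** is monitored by recomputing the profile on sample prefixes
and reporting the largest change between successive checkpoints, restricted
to bins that both checkpoints sample adequately.

## The alchemical route and its conventions

`run_alchemical()` interpolates two site potentials,
$U_\lambda = (1-\lambda)U_A + \lambda U_B$, over 21 evenly spaced
$\lambda$ windows (10% burn-in each), sampling on the reaction-coordinate
axis with a flat-bottom confinement (free for $|s| \le 1$ nm, harmonic 500
kJ/mol/nm$^2$ outside).  The confinement defines the bound-state volume; it
is identical at both endpoints, so its contribution to the *relative* free
energy cancels and no additive correction is applied — this is the
restraint/volume convention for all reported $\Delta\Delta G$ values.  The
quadrature oracle used in the tests integrates $e^{-U_\lambda/k_BT}$ over
the same confined Hamiltonian.

`mbar_ddg()` solves the MBAR self-consistency equations by Newton iteration
on the reduced window offsets (gauge $f_0 = 0$), with a sequential
exponential-averaging initialisation, and reports
$\Delta G = k_BT\,(f_{\lambda=1} - f_{\lambda=0})$.  The quoted uncertainty
is the asymptotic estimate from the inverse observed-information matrix of
the same objective; with correlated dynamics samples it is optimistic (it
assumes independent draws), which is why tolerance checks in the tests rely
on planted truth and repeat runs, not on this estimate.  For two states the
implementation must agree with an independently coded Bennett acceptance
ratio solver (`bar_ddg()`, root-finding on the implicit equation) to better
than 0.05 kJ/mol — a regression guard against the easy-to-miss sign and
normalisation errors in these estimators.

A genuine physical point, worth stating because the two routes are *not*
estimating identical quantities: the PMF route reports the difference of
profile minima, while the alchemical route reports the difference of
bound-state free energies, which includes the well-width entropy.  For
same-width Gaussian wells the leading difference is
$\tfrac{k_BT}{2}\ln(D_{0,B}/D_{0,A})$ — about $-0.8$ kJ/mol for the
37 → 20 kJ/mol conversion, so the two routes agree within about 1 kJ/mol,
comfortably inside the 3 kJ/mol consistency band used throughout.

## Site mapping choices

* Density deposition is **nearest-voxel** (0.1 nm grid): per-frame-mean
  normalisation then conserves mass exactly (grid sum = mean selected
  particle count), which is testable to machine precision.  A smoothing
  kernel would look nicer and conserve nothing.
* Site detection thresholds at a *fraction of the global peak* (function
  default 0.5) over 6-connected components, ordered by peak then voxel
  index (deterministic).  Two practical parameters: the pipeline preset
  lowers the fraction to 0.35 because symmetry-related sites hold small
  integer numbers of lipids (a 2-lipid site has twice the peak of a 1-lipid
  site), and an absolute occupancy floor `min_peak = 0.05` makes a
  *well-free* system report zero sites instead of labelling diffuse noise.
* Contact durations use a **dual cutoff** (open below 0.55 nm, close above
  1.0 nm — conventional bead-scale values, both configurable) per
  (residue, lipid molecule) pair on the minimum particle–particle distance;
  an event still open at the trajectory end is counted at its censored
  length.  Contact-map colour scales map mean durations linearly to
  $[0, 1]$ with the maximum at 1; an all-equal table maps to 1 and an
  all-zero table to 0 (the degenerate cases are defined, not accidental).
* Distance-to-site traces use head-group **COM to anchor COM** (projected
  in-plane); on multi-site systems each molecule can instead be measured
  against the site it occupies at the final frame (`site_of = "eventual"`).
  Contact fingerprints deliberately use particle minima, not COM, mirroring
  per-residue fingerprint conventions.
* Whether per-residue durations should be pooled over the four chains of a
  tetramer is a reporting choice; `residue_contact_durations()` exposes
  `per_chain` and reports pooled values by default.

## Geometry metrics

Hydrogen bonds are geometric: donor–acceptor distance $\le 0.35$ nm and
deviation of D–H$\cdots$A from linearity $\le 30^\circ$ (0° = collinear —
stated this way to avoid the "angle $\ge 150^\circ$" ambiguity).  No
energetic scoring.  Results are criterion-sensitive; both thresholds are
arguments.

Superposition is a Kabsch fit via SVD with a determinant correction
(proper rotations only, collinear fit sets rejected); ligand RMSD series
superpose the *protein* selection onto the reference frame and never fit
the ligand itself, so a drifting copy shows its drift.  The test suite
cross-checks the fit against an independent reference implementation and
asserts invariance under random rigid motions.

## Problem sizes and reproducibility

Reference sampling — chosen as the point where the estimator scatter
(repeat-run SD $\approx 0.3$–$0.5$ kJ/mol per depth) sits well inside the
$\pm 2$ kJ/mol recovery band: 38 windows $\times$ 51 000 retained samples
(umbrella), 21 windows $\times$ 19 800 retained samples (alchemical),
40 000 steps for the mixed-bilayer binding run (400 lipids).  The `ci`
preset cuts these by roughly 4$\times$ for quick iteration.  One root seed
drives everything; per-stage streams are derived with documented offsets so
any stage can be re-run in isolation, and identical configuration + seed
reproduces every table bit for bit.

## Known limitations

* The Brownian surrogate validates estimators, not membranes: no
  lipid–lipid interactions, no leaflet coupling, no protein flexibility.
* The MBAR uncertainty assumes independent samples (see above).
* The Euler–Maruyama step leaves a sub-0.5 kJ/mol systematic in recovered
  depths; halve `dt` if that matters for a use case.
* PIP$_2$ regio-isomers are treated as one species; the synthetic tags are
  labels, not chemistry.
* The OpenDX writer emits the standard z-fastest layout with 6-significant-
  digit values; round trips are exact only to that precision.
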