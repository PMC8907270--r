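---
title: "Methods: a Cellular Potts Model of normal-senescent cell mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Cellular Potts Model of normal-senescent cell mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(senCPM)
```

# The biological question

Senescent cells in a confluent breast-cancer monolayer (MDA-MB-231) are
enormously enlarged, non-motile obstacles.  Motile (normal) cells that
touch them tend to crawl along their boundary for a while, tracing
circular arcs; how long they stay and how persistently they move
depends on how sticky the normal-senescent interface is.  That
stickiness, the interfacial energy `E_sn`, cannot be measured directly.
senCPM implements the simulation-based inference that estimates it: a
lattice model of the two-cell-type mixture is scanned over `E_sn` and
the senescent target size, and the parameter pair is read off the
intersection of two level curves - where the simulated mean angular
speed of an orbiting cell and the simulated mean pair distance equal
their experimentally measured values.

# The model

Each cell is a connected set of sites on a periodic square lattice
(medium is id 0).  Dynamics proceed by copy attempts: a target site is
drawn uniformly, a source site uniformly from its 8 Moore neighbors,
and the proposal to copy the source's cell id onto the target is
accepted with the Metropolis probability (1 for energy change
$\Delta H \le 0$, $e^{-\Delta H/T}$ otherwise; the equality case is the
continuity limit of the downhill branch).  One Monte Carlo step (MCS)
is as many attempts as there are lattice sites and corresponds to
2 minutes.

The energy has three parts:

$$H_{constr} = \lambda_A \sum_i (A^*_i - A_i)^2
             + \lambda_P \sum_i (P^*_i - P_i)^2, \qquad
  H_{adh} = \sum_{\langle xy \rangle} E_{\sigma_x\sigma_y}
            (1 - \delta_{c_x c_y}),$$

$$\Delta H_{pers} = -S \sum_i \Delta x_i \cdot \hat p_i,$$

with per-cell areas $A_i$ (sites), perimeters $P_i$ (von Neumann
boundary-edge counts), interfacial energies by phenotype pair (more
negative = stickier), and a polarity vector $p_i$ updated once per MCS
by the net centroid displacement with memory loss,
$p \leftarrow p + \Delta r - p/\tau$.

## Parameters

| parameter | value | meaning |
|---|---|---|
| $\lambda_A$, $\lambda_P$ | 1, 1 | constraint strengths |
| $A^*_{normal}$ | 100 sites (3600 µm²) | normal target area |
| shape factor | 0.9 | $P^* = 0.9 \times$ lattice-disk perimeter of $A^*$ |
| $E_{nn}$ | −65 | normal-normal interface energy |
| $E_{sn}$ | control (≈ −20) | normal-senescent interface energy |
| $E_{nm}=E_{sm}=E_{mm}$ | 0 | medium energies |
| $S$ | 2.8 (normal), 0 (senescent) | persistence strength |
| $\tau$ | 4 MCS | polarity memory time |
| $T$ | 10 | fluctuation amplitude |
| calibration | 6 µm/site, 2 min/MCS | from $A^* = 100$ sites = 3600 µm² |

The senescent target area $V^{sen}_{target}$ (µm², divided by 36 to get
sites) and $E_{sn}$ are the two control parameters of the study; the
senescent perimeter target scales with $\sqrt{V^{sen}_{target}}$
automatically through the shape-factor rule.

## Conventions the model statement leaves open

Several lattice-level choices are not dictated by the model equations;
we fixed each once, for the following reasons, and they are not tuning
knobs:

* **Neighborhoods.**  Copy-attempt sources come from the Moore
  neighborhood; both the perimeter measure and the adhesion interfaces
  are counted over von Neumann edges.  We also explored extended
  (Moore) adhesion kernels: they stabilize the isolated pair but make
  the confluent tissue much too viscous (residence times roughly
  double, persistence times collapse), so the plain edge convention is
  used throughout.
* **Perimeter target.**  The reported shape parameter 0.9 is read as a
  dimensionless factor on the boundary-edge count of the lattice disk
  of the cell's target area.  A 100-site disk has 44 boundary edges, so
  $P^*_{normal} = 39.6$; this reading reproduces the calibrated-point
  angular speed, whereas a smooth-circle reading ($0.9 \cdot
  2\sqrt{\pi A}$) slows the orbiting cell well below the measured
  level.
* **Persistence magnitude.**  $\Delta x_i$ is the hypothetical
  center-of-mass shift of the affected cell *scaled by its area*, i.e.
  the displacement contributed by the copied site (order one lattice
  constant).  An unscaled centroid shift would be of order $1/A$ and,
  at $S = 2.8$ and $T = 10$, produce no persistent motion at all; with
  the scaled convention the model reproduces superdiffusive single-cell
  motion (MSD exponent ≈ 1.7 vs ≈ 1.0 for $S = 0$) and the documented
  ordering of energy components (perimeter > persistence > area in
  mean |ΔH|).
* **Zero polarity.**  Cells start with a random unit polarity scaled to
  0.01 lattice units; a cell with exactly zero polarity contributes no
  persistence energy.  This removes the startup singularity of
  $\hat p$ without biasing direction.
* **ΔH = 0.**  Accepted with probability 1.
* **Connectivity.**  Fragmentation is not forbidden;
  `count_fragments()` audits it (cells stay connected in practice at
  the study parameters).
* **Senescent-senescent energy.**  Not needed in any scenario
  (senescent disks are placed apart); defaults to $E_{nn}$ and is
  configurable.

## Numerical bookkeeping

The engine maintains per-cell area, perimeter and centroid sums
incrementally; property tests compare them against full recounts and
brute-force Hamiltonian differences (≤ 1e-9 per accepted attempt).
Centroids are tracked in *unwrapped* coordinates so trajectories have
no periodic jumps; this requires every cell to span less than half the
domain, and the scenario builders enforce that (`check_half_domain`).
Relative pair vectors are reduced to the minimal image before the polar
decomposition.  All randomness flows from a single 64-bit generator
seeded explicitly; identical seeds give bit-identical runs.

Physical perimeters are reported as boundary-edge count × 6 µm × π/4:
the staircase count overestimates Euclidean contour length by 4/π for
isotropically oriented boundaries (Cauchy-Crofton), and the π/4 factor
is the standard unbiased correction.  The dimensionless shape index
$p = P/\sqrt{A}$ inherits this convention; in raw edge-count units the
same cells read ≈ 27% higher.  This estimator choice is the main
source of systematic uncertainty when comparing simulated shape
indices with image-derived ones (see Limitations).

# Scenarios

* **Pair** (`build_pair`/`simulate_pair`): one senescent disk at its
  target area in the domain center, one normal disk seeded touching its
  boundary; 100 MCS burn-in before measurement.  The default domain
  side comfortably exceeds both the pair extent and twice the
  senescent diameter.
* **Confluent** (`build_confluent`/`simulate_confluent`): senescent
  disks placed without overlap, the rest of the lattice tessellated
  among normal cells by nearest-seed assignment under the periodic
  metric - zero medium sites, contiguous cells.  The default domain
  side makes the requested cell counts confluent at their target areas
  (91 normal + 1 senescent → side 100).  The multi-senescent variant
  used for persistence statistics is fixed at 150 normal + 5 senescent
  cells on a 140 × 140 lattice (counts again confluent at target); the
  number of senescent cells in the reference simulation being reproduced
  is not stated, so this is a package choice.

# Synthetic trajectory generator

`generate_orbit_trajectories()` emulates the *experimental* orbit
cohort so the analysis pipeline is testable without the simulator: per
cell, an orbit radius from the measured distance distribution
(mean 124.30 µm, sd 40.46 µm, truncated positive), a tangential speed
from the measured speed distribution (mean 1.79, sd 0.53 µm/min),
angular integration at $v/R$ with white angular noise
(0.02 rad/√min), white radial noise (5 µm), and chirality flips as a
Poisson process (rate 1/500 min⁻¹, i.e. at most about one abrupt
reverse turn per trajectory, matching their described rarity); 60
cells, 1-min frames, 400 min.  The generator does **not** emulate cell
shape, pseudopod activity, host-boundary irregularity, or correlated
(non-white) noise; passing recovery tests on it therefore validates
the estimators' arithmetic, not their robustness to every feature of
real microscopy data.

`generate_contact_durations()` draws gamma residence times as ground
truth for the fit-recovery tests.

# Trajectory statistics

* **Polar decomposition** (`to_polar`): $R(t)$, $\theta(t)$ about a
  fixed or per-frame host centroid.
* **Rectification** (`unwrap_and_rectify`): 2π-unwrapping, then sign
  flips of angular increments wherever the windowed mean
  $d\theta/dt$ (15-frame centred moving average; configurable) opposes
  the initial chirality, so occasional reverse turns do not cancel the
  accumulated rotation.
* **Speeds**: $\omega_k = \Delta\theta_k/\Delta t$ on the rectified
  angle; $v_{\theta,k} = R_k\,\omega_k$ with mid-interval $R$.  The
  `fit_A_over_R()` regression of per-cell $\bar\omega$ on $1/\bar R$
  without intercept returns the tangential-speed constant with a 95%
  CI and an AIC comparison against an $R$-independent model.
* **Pair observables** (`pair_observables`): all orbital statistics are
  averaged over *in-contact* frames (shared boundary edge), mirroring
  the experimental protocol in which trajectories are recorded while
  the cells form an attached pair.
* **Contacts** (`detect_contacts`): interface mode reads the recorded
  boundary-edge counts (contact = ≥ 1 shared edge; 1-frame gaps
  bridged, because membrane fluctuation at $T = 10$ produces frequent
  one-step flicker); distance mode thresholds the centroid gap at the
  sum of equivalent-circle radii + 6 µm when areas are available.
  Single-frame episodes get one frame interval of duration; episodes
  touching the record boundary are flagged censored and excluded from
  duration statistics.
* **Gamma fits** (`fit_gamma`): maximum likelihood with moment starts,
  computed on mean-rescaled durations for numerical stability (MLE is
  scale-equivariant).
* **Persistence** (`direction_autocorrelation`,
  `fit_persistence_time`): mean dot product of unit step directions at
  each lag, conditioned on both vectors being fully in (or fully out
  of) contact, mixed pairs dropped; exponential decay fitted over lags
  4-300 min (the one-frame lag is excluded to avoid frame-noise bias;
  at 2-min CPM frames that means starting at 4 min).

# Phase scan and calibration inversion

`run_scan()` simulates the pair scenario at every grid point of
(`E_sn`, `V_target_sen`) with independent derived seeds, computes the
per-replicate observables, and averages time-first then
replicates-unweighted (the order fixes the variance bookkeeping; the
reference procedure does not specify one).  Per-point checkpoints make
interrupted scans resumable.  `extract_level_curve()` contours the
gridded maps by marching squares (via `grDevices::contourLines`,
bilinear interpolation) with band curves at level ± Δ;
`intersect_levels()` computes all pairwise segment intersections with
axes rescaled to comparable units, picks the intersection nearest the
centroid of the band-curve intersections when several exist, and
reports a non-identifiable diagnosis with nearest-approach geometry
when none exists.  The default desk scale is a 5 × 5 grid over
$E_{sn} \in [-60, -5]$ and $V^{sen}_{target} \in [1, 6] \times 10^4$
µm² with 8 replicates × 1500 measured MCS per point; the reference
calibration used 60 replicates at the final point and longer runs, so
the desk-scale estimate carries one-grid-cell uncertainty by
construction.

# Problem sizes used by the tests and scripts

Chosen so the full suite and the acceptance script each finish within
minutes on a single core: pair runs 2000 measured MCS (3 seeds),
confluent residence runs 5 × 3000 MCS (91 + 1 cells), persistence runs
2 × 3000 MCS (150 + 5 cells), scans 5 × 5 × 8 × 1500 MCS.  These are
scaled-down versions of the reference 10⁴-MCS, 30-60-replicate runs;
dispersion of the resulting statistics is correspondingly larger.

# Known limitations

* The shape index depends strongly on the perimeter estimator: our
  π/4-corrected value at the calibrated point is ≈ 3.93, the raw
  edge-count value ≈ 5.0, and reported image-derived values sit in
  between; comparisons at the second decimal are not meaningful.
* The contact-conditioned persistence ratio measures ≈ 1.8-2.0 here
  versus ≈ 2.8 in the reference simulation; the multi-senescent
  scenario geometry (unknown in the source) and platform-level
  conventions both plausibly contribute.
* The residence-time distribution contains many one-to-two-frame
  flicker episodes, pulling the fitted gamma shape below 1 even when
  the mean matches; a minimum-duration filter would raise the shape
  but is deliberately not applied.
* No chemotaxis/secretory field is modelled (secreted chemoattractants plausibly explain part of the
  experimental-vs-simulated contact-time gap), no 3D lattice, no biochemical sub-models.
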