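---
title: "Torsion parameterization and duplex dynamics analysis with pnadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion parameterization and duplex dynamics analysis with pnadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnadyn)
```

## Scope and motivation

Gamma-modified peptide nucleic acids (gamma-PNAs) carry a substituent --
commonly a methyl group or a miniature poly(ethylene glycol) (miniPEG)
chain -- on the backbone gamma-carbon. Simulating such molecules with a
CHARMM-style force field requires torsion terms and partial charges for
the substituent linkage that the published force field does not cover,
and judging the effect of the substituent on a duplex requires a set of
trajectory analyses: superposed RMSD/RMSF, Watson--Crick hydrogen-bond
occupancy, backbone torsion distributions, principal-component
conformational substates, and a helical-bend estimate that works for PNA
(whose geometry defeats the usual DNA helicoidal-parameter programs).

`pnadyn` implements both halves as plain R functions over small S3
containers, plus synthetic generators that produce ground-truth-known
inputs for every analysis. Quantum-chemical target generation, molecular
dynamics propagation, and base-stacking/helicoidal analyses performed by
external engines are deliberately out of scope: scans arrive as tables,
structures and trajectories as multi-model PDB.

## The torsion energy model and the fitting loop

A torsion term is the standard CHARMM Fourier term

$$E(\phi) = \sum_i k_{\chi,i}\,\bigl(1 + \cos(n_i \phi - \delta_i)\bigr),$$

with force constants $k_\chi \ge 0$ (kcal/mol), integer multiplicities
$n \in \{1,\dots,6\}$ and phase offsets $\delta$ (degrees). Keeping
$k_\chi$ non-negative and letting $\delta \in \{0, 180\}$ absorb the
sign follows common CHARMM practice; both sets are configurable
arguments of `fit_series()` because published parameter tables vary.

The discrepancy between a model profile and a target profile is the
**pairwise error**: relative energetics are only defined up to an
additive constant, so for each unordered pair of grid points $i<j$ we
compare the energy *differences* and take the RMS of
$(m_i - m_j) - (t_i - t_j)$ over all pairs. This statistic is symmetric,
offset-invariant, and for an $n$-point grid equals
$\sqrt{2n/(n-1)}$ times the population SD of the per-point residual, so
minimizing it is ordinary least squares with a free intercept. The
protocol literature cites a pairwise error analysis without printing a
formula; the RMS-over-pairs reading is our design choice, and the
simpler RMSD-after-mean-alignment variant is available via
`pairwise_error(..., method = "rmsd")` for comparison.

`fit_series()` takes the target profile and a molecular-mechanics
baseline profile (the MM surface with the fitted torsion absent or
frozen -- always an input, since evaluating a full force field is out of
scope) and minimizes the pairwise error of `baseline + series` over the
allowed $(n, \delta)$ basis. The solver is cyclic coordinate descent
with a non-negativity clamp on each $k_\chi$, over mean-centered basis
columns. Two entry points share it:

* `method = "ls"` starts from zero. On the default uniform 15-degree
  full-turn grid the cosine columns are mutually near-orthogonal, so
  this converges in a couple of sweeps and is effectively the linear
  least-squares solve.
* `method = "refine"` starts from a supplied series and corresponds to
  iterative amplitude tuning of an existing parameter guess (e.g.
  raising one $k_\chi$ from an initial-guess value until the target is
  matched).

Convergence is declared when the final pairwise error is at or below
`tol`, default 0.2 kcal/mol -- the customary acceptance threshold for
this kind of fit. The solver itself iterates to numerical stationarity
(coefficient updates below 1e-13, cap 10,000 sweeps); the tolerance
never stops it early, and a fit that ends above tolerance is reported
`converged = FALSE`, never silently accepted. Grids with fewer points
than basis functions are a hard error rather than an underdetermined
fit.

Scan bookkeeping follows the usual protocol: profiles are sampled every
15 degrees over a full turn (`scan_spec()`, which also records the
1e4 kcal/mol.radian^2 harmonic restraint as provenance metadata only),
energies are min-shifted to zero, and `check_scan_periodicity()` flags a
profile whose 0- and 360-degree endpoints disagree -- the signature of
the scan relaxing into a different conformer -- and recommends the
standard remedy, a backward re-scan from 360 to 0. Scan tables read with
`wrap = FALSE` keep both endpoints for exactly this check; the default
`wrap = TRUE` maps angles into [0, 360) and treats any resulting
duplicate angle as a hard error.

## Charge edits

Two deterministic bookkeeping operations cover the electrostatic side of
a substituent linkage. `aggregate_hydrogen_charge()` folds a substituted
hydrogen's partial charge (+0.09 e in the CHARMM aliphatic convention)
onto its carbon, conserving the group net charge exactly -- for a
gamma-carbon at -0.02 e this yields +0.07 e. `repair_neutrality()`
adjusts one designated atom by exactly the difference between the
current and the target net charge, so a residue left at +0.03 e by the
edits returns to neutrality by moving, say, a backbone nitrogen from
-0.33 e to -0.36 e; with `target_net = 0` on a terminal methyl group it
expresses the net-zero-methyl convention. Charges are carried at full
precision; rounding to the 2-decimal CHARMM style happens only in
`write_charge_table(..., digits = 2)`.

## Trajectory metrics

`superpose()` is the Kabsch least-squares rigid-body fit (SVD of the
cross-covariance, determinant forced to +1). `rmsd_series()` superposes
every frame on a chosen reference frame over the selection by default;
`fit = FALSE` gives raw laboratory-frame RMSD, since reference tools
differ on this. `rmsf()` aligns the chosen frame window to its first
frame, averages, re-aligns to that average once, and reports each
selected atom's RMS deviation from the final mean -- the standard
align-to-running-average scheme.

Hydrogen-bond occupancy uses the common geometric criterion: a frame
counts when the donor--acceptor distance is at most 3.5 Angstrom *and*
the D--H--A angle is within 30 degrees of linearity, i.e. at least 150
degrees. The angle is measured at the hydrogen (D-H-A); some tools
measure H-D-A instead, which gives systematically different occupancies,
so this choice is worth checking when comparing numbers across codes.
Occupancy is monotone non-decreasing in both cutoffs, a property the
test suite verifies on cutoff grids. Frames are weighted equally and no
smoothing is applied.

Torsions use the standard atan2 construction with the IUPAC sign
convention (cis = 0, clockwise positive viewed from the first atom),
reported in (-180, 180]; under this convention the angle is invariant to
reversing the atom order. `torsion_histogram()` bins (-180, 180] with a
bin width that must divide 360 and returns probabilities that sum to 1.

Selections are explicit index vectors from `select_atoms()`; residue
indices are 1-based as deposited. The "central six base pairs" of an
8+8 duplex are residues 2--7 and 10--15 -- a configuration choice, never
hard-coded, because the backbone atom list of a gamma-PNA topology is
itself a naming convention of the force field in use.

## Conformational substates

`coord_covariance()` builds the essential-dynamics covariance over the
3N Cartesian coordinates of the selected atoms,
$c_{ij} = \langle (x_i - \langle x_i\rangle)(x_j - \langle x_j\rangle)\rangle$,
averaging over frames with the 1/n convention (a `normalization =
"n-1"` switch is provided, since conventions differ and the choice
rescales eigenvalues without changing directions). Frames are first
superposed onto the first frame over the same selection -- mandatory by
default, because rigid-body drift otherwise dominates the spectrum; a
flag disables it for parity experiments.

`pca_substates()` eigendecomposes the covariance (eigenvalues
descending, signs fixed by making each mode's largest-magnitude
component positive so degenerate spectra still decompose reproducibly).
`choose_dims()` implements the two usual scree readings: smallest
cumulative-fraction dimension at a threshold, or the maximum-curvature
elbow. `project_frames()` gives the PC coordinates;
`cluster_substates()` runs Lloyd k-means (via `stats::kmeans`) with 10
random restarts under a fixed seed, keeping the lowest within-cluster
sum of squares; `centroid_frames()` returns each cluster's
representative frame -- the member nearest its centroid, ties to the
lowest frame index. The substate count k is user-specified (typical
analyses use k = 4 for a perturbed ensemble, k = 1 for a quiescent
one); `silhouette_scan()` provides guidance, not an automatic choice.
Whether clustering acts on all kept dimensions or on a 2-D projection
is up to the caller via `project_frames(model, dims)`; our default
examples cluster on the kept dimensions.

## The helical-bend estimator

PNA duplexes adopt wide, slowly twisting P-form-like helices that DNA
helicoidal-parameter programs do not handle, so the bend is estimated
directly: each designated base pair contributes the best-fit plane
through the four ring nitrogens (N1 and N3 of both bases), and the bend
is the angle between the two plane normals, folded into [0, 90] degrees
because a plane normal carries an arbitrary sign. The phrase "normal
vectors for the geometric centers of N1 and N3" admits a second
reading -- the vector joining the two per-base N1/N3 midpoints -- which
ships as `method = "midpoint"` for sensitivity analysis; note it mixes
helical twist into the angle and is therefore not interchangeable with
the plane-normal default. Default pairs are the second and
second-to-last of the duplex (residues 2:15 and 7:10 in an 8+8 layout),
where fraying has not yet destroyed the plane but the lever arm spans
the helix.

## The synthetic generators, and what they do not show

`build_duplex()` places rigid six-atom pseudo-bases (N1, N3, a ring
carbon, and one N2--H2/O2 donor--acceptor triplet per base) on a
helical axis: 8 base pairs, rise 3.35 Angstrom and twist 17.5 degrees
per step by default -- the slowly twisting helix regime of PNA
duplexes -- with sequence CCGTACGG and its antiparallel complement
(strand 2 numbered so pair i is residues (i, 2n+1-i)). The programmed
bend is applied as a uniform per-step tilt about a fixed axis and is
*defined* as the plane-normal angle between the two default
measurement pairs, so generator truth and metric agree exactly at zero
noise. Within each pair both hydrogen bonds are built at D--A = 2.9
Angstrom, exactly linear.

`build_trajectory()` adds isotropic Gaussian thermal noise (0.1
Angstrom per coordinate by default -- small against the 2.9 Angstrom
bond geometry, large enough to make superposition and covariance
non-trivial) and two scheduled perturbations: `break_hbond` pushes a
pair's acceptors 1.5 Angstrom along the H-to-A direction (D--A 4.4
Angstrom, past the 3.5 cutoff), and `shift_basin` displaces strand 1 by
a fixed vector, which survives superposition as internal motion and
creates separable PCA basins. `synth_scan()` plants a known torsion
series on a smooth two-harmonic baseline with optional Gaussian noise.
All generators are deterministic under a seed and return their ground
truth alongside the data.

These fixtures are deliberately minimal. They contain no force-field
physics: no sequence-dependent geometry, no correlated thermal motion,
no solvent, no gradual fraying, and pseudo-bases are rigid. Passing the
recovery suites therefore demonstrates that the *estimators* are
correct -- that the bend metric returns the constructed bend, that the
substate pipeline separates constructed basins, that occupancy counts
constructed contacts exactly -- not that any simulation of a real
duplex would reproduce published trajectories. Problem sizes in the
test and acceptance runs (24-point scans, 50-replicate fits, 100- and
400-frame trajectories of the 96-atom duplex, 11-model ensembles) were
chosen as the smallest sizes at which each statistical claim is
meaningful.

## Numerical choices and degenerate inputs

* Pairwise error is computed from centered residuals
  ($n\sum d_c^2 - (\sum d_c)^2$ over pairs), avoiding the catastrophic
  cancellation the uncentered identity suffers when two profiles differ
  by a large constant.
* Superposition requires at least three non-collinear selected atoms;
  collinearity (second singular value ~ 0) is a hard error, as is a
  best-fit plane through (near-)collinear anchors.
* Eigenvector sign fixing: largest-magnitude component positive.
  K-means ties and centroid-frame ties break to the lowest index.
* Angles: interfaces are degrees; `[0, 360)` for scans (with the 360
  endpoint admitted only for pre-wrap periodicity checks), `(-180,
  180]` for torsions, `[0, 90]` for bends.
* The PDB writer emits fixed 8.3 coordinate columns; round trips are
  exact to 3 decimals. Occupancy/B-factor are ignored on read, written
  as 1.00/0.00. Parameter-stream round trips are exact at the written
  4/2-decimal precision.
* Iteration caps (10,000 solver sweeps, 100 Lloyd iterations x 10
  restarts) are reported, never silently exceeded.

## Known limitations

The toolkit analyses coordinates; it never computes molecular-mechanics
energies, so the baseline profile's physical validity is the caller's
responsibility. The hydrogen-bond module needs donor/hydrogen/acceptor
indices supplied explicitly (no topology perception). Binary trajectory
formats are not read -- multi-model PDB is the portable reference path,
and anything else should be converted upstream. The bend metric
presumes the anchor nitrogens exist under their deposited names
(`N1`/`N3`); no renaming heuristics are applied, and bend *direction*
(major- vs minor-groove) is not assigned.
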