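---
title: "Quantifying the alpha5 helix-switch: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the alpha5 helix-switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixswitch)
```

## The problem

Receptor-catalyzed nucleotide exchange in heterotrimeric G proteins runs
through the C-terminal α5 helix of the Gα subunit. Its far C-terminal
peptide (GαCT) binds in the cytoplasmic crevice of the activated receptor
and, between the GDP-bound intermediate complex and the nucleotide-free
complex, undergoes a characteristic screw-like repositioning — the
*helix-switch*: a rotation of roughly 60° about the helix axis combined with
a translation of about 1.5 Å along it. Geometrically this is exactly a
one-position shift of the peptide's contact register with two conserved
receptor probes: the arginine at generic (Ballesteros–Weinstein) position
3.50 and the main-chain carbonyl at 3.54. `helixswitch` implements the
measurements this picture requires: rigid-body and screw geometry, docking
pose clustering and register classification, interface characterization, and
per-frame trajectory metrics with event detection — together with seeded
synthetic generators so that every estimator can be validated against a
known ground truth without external coordinates.

## Geometry estimators

**Kabsch superposition.** `kabsch_superpose()` solves the weighted
least-squares rigid superposition by SVD of the weighted covariance matrix,
with the reflection branch excluded, so the returned rotation always has
determinant +1. Collinear point sets leave the rotation underdetermined and
are rejected with an explicit error. The tests verify optimality against a
brute-force search over a million uniformly sampled unit quaternions.

**Restricted screw fit.** Given a fixed axis (point $p$, unit direction
$\hat u$), `screw_about_axis()` finds the angle $\theta$ and axial slide $d$
minimizing the RMSD between pose A rotated/slid about the axis and pose B.
The axial and perpendicular parts decouple, giving the closed form

$$ d = \overline{(b_i - a_i)\cdot\hat u}, \qquad
   \theta = \operatorname{atan2}\Big(\sum_i \hat u\cdot(a_i^\perp\times b_i^\perp),\;
                                     \sum_i a_i^\perp\cdot b_i^\perp\Big), $$

with the sign following the right-hand rule about the N→C axis direction and
angles reported in degrees within (−180, 180]. The residual RMSD after
applying the fitted screw is always reported; because the screw family is a
subset of the rigid motions, this residual can never undercut the free
Kabsch RMSD (a property the test suite asserts).

**Free screw (Chasles) decomposition.** `chasles_decompose()` recovers the
unique screw axis, angle and slide of an arbitrary proper rigid transform;
below 0.1° of rotation the motion is reported as a pure translation (angle
0, axis along the translation) because the axis location becomes numerically
meaningless. It serves as a cross-check for the restricted fit and powers
the axis estimator below.

**Helix-axis fitting.** A helix is the orbit of a fixed screw motion: the
transform carrying residues $1..n{-}1$ onto residues $2..n$ *is* the
per-residue screw. `fit_helix_axis()` therefore Kabsch-fits the
one-residue-shifted Cα trace onto itself and Chasles-decomposes the result;
the axis is the screw axis, the twist its angle, the rise its slide. For
ideal helical points this is exact at any length ≥ 5. We initially
implemented the common alternative — a total-least-squares line through
sliding 4-residue Cα centroids — and found it measurably biased for 11-mers:
at ~100°/residue a 4-residue window does not cancel the winding, the
centroids trace a small residual helix, and the fitted direction tilts by
~0.8°, inflating the apparent rise by ~0.02 Å. The screw-symmetry fit has no
such bias and also showed the best noise robustness in a Monte-Carlo
comparison (direction error at σ = 0.2 Å over 100 seeds: mean 0.96°, max
2.8°, versus 1.3°/3.0° for the centroid line). The screw-fit residual is
exposed as `fit_rmsd` with a 1.0 Å sanity bound that flags (rather than
fails) suspect fits.

**Tilt.** `tilt_angle()` reports the angle between the helix axis and the
membrane plane, i.e. $\arcsin(\hat u\cdot\hat n)$ for the membrane normal
$\hat n$ (default the z axis, the usual membrane-simulation convention),
positive when the axis leans toward the normal.

## Pose analysis

Docking poses share the receptor frame, so `pairwise_rmsd_matrix()` computes
in-frame RMSD by default (a flag enables re-superposition). Backbone atoms
are the default selection here and in the screw fit; whether all-atom or
backbone-only fitting is preferable is data-dependent, so both are a flag
away. `single_linkage_cluster()` implements single linkage at a fixed cut
height as connected components of the graph with edges at distance ≤ cutoff
— the documented behavior of standard docking-pose clustering tools — with
clusters ranked by descending occupancy (ties broken by lowest member index)
and the medoid (minimal summed within-cluster distance) as representative.
The full dendrogram is never needed and not built.

Contact fingerprints record hydrogen-bond, cation-π and apolar contacts
between peptide residues and receptor positions, the receptor side expressed
in generic numbering wherever the anchor-propagated map covers it (unmapped
residues keep their author number and are flagged, never dropped).
`classify_pose()` reduces the fingerprint to per-probe peptide offsets from
the C-terminus and asks whether one uniform register shift explains all of
them: shift 0 is the nucleotide-free-like register (offset −1 at 3.50,
offset −8 at 3.54), shift +1 the GDP-intermediate-like register. Offsets are
anchored at the C-terminus so that Gs- and Gt-numbered peptides are handled
identically without any cross-G-protein alignment; contradictory probes
yield `"other"` with diagnostics, never a silent pick.

## Interface analysis

All detector thresholds live in `interaction_criteria()` and are echoed into
every report:

| quantity | default | unit |
|---|---|---|
| H-bond donor–acceptor distance | 3.5 | Å |
| D–H…A angle (when H present) | ≥ 120 | ° |
| antecedent–D…A angle (no H) | ≥ 90 | ° |
| cation–π centroid distance | 6.0 | Å |
| cation–π off-normal angle | ≤ 45 | ° |
| apolar C/S contact distance | 4.5 | Å |
| bridging-water cutoff | 3.5 | Å |
| single-linkage cluster cutoff | 1.5 | Å |
| SASA probe radius | 1.4 | Å |
| SASA quadrature points | 960 | — |

Crystallographic "potential hydrogen bonds" imply heavy-atom geometry
without hydrogens, hence the antecedent-angle proxy; when explicit hydrogens
are present the D–H…A criterion takes over. Solvent-accessible surface area
uses Shrake–Rupley quadrature on a deterministic golden-spiral lattice with
an element-based radius table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
P 1.80 Å), so results are bit-reproducible for a given point count. Buried
interface area is reported in both conventions — the half-burial
$(\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB})/2$ as the headline
and the factor-2 total alongside — since published interface areas use
either. One numerical caveat is inherent to the method: the integrand is an
indicator function, so a fixed quadrature lattice leaves a small orientation
dependence of the total area (measured ≤ 0.43% over random rotations at 960
points, ≤ 0.28% at 1920); the closed-form accuracy targets (1% for an
isolated sphere, 2% against the analytic two-sphere cap formula) hold with
margin. Interface waters are counted by the bridging rule: a water oxygen
within the cutoff of at least one heavy atom of *each* partner.

## Trajectory metrics and switch detection

Frames are first Kabsch-aligned on a receptor/scaffold selection, making all
peptide metrics receptor-frame quantities. The rotation series fits the
restricted screw from the reference pose to each frame about an axis fitted
once on the reference helix and held fixed — this keeps the angle
well-defined even if the helix bends slightly; a per-frame axis is available
behind a flag. The RMSD series deliberately does *not* re-superpose the
peptide: translation within the crevice is part of the signal. Running
averages are centered moving means with shrunken edge windows (no invented
padding). Time axes come from a sidecar CSV (`frame,time_ns`) or a uniform
step, since the multi-model PDB format has no time record.

No numeric switch criterion is standard in the literature, so the package
operationalizes "adopts a conformation maintained for the remainder of the
simulation": a switch is called at the first time the smoothed
RMSD-to-target drops below `rmsd_switch` (default 2.0 Å) and stays below it
for at least `min_persist_fraction` (default 0.8) of the remaining frames,
after smoothing with a 5-frame window. Detection is monotone in the
threshold by construction. All three knobs live in the configuration and are
echoed into the event record.

## The synthetic generators

The generators are first-class, tested code; they define the conditions
under which the estimators are validated.

**Ideal helix builder.** Backbone atoms are placed residue-by-residue from
canonical internal coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O
1.231, CA–CB 1.521 Å; angles 111.2°/116.2°/121.7°, all overridable). The
default dihedrals are φ = −64°, ψ = −42°: with the standard bond
geometry the textbook α-helical pair (−57, −47) produces a noticeably
stretched helix (rise 1.558 Å/residue), and no dihedral pair reaches the
canonical (1.50 Å, 99.6°) exactly, so the defaults were calibrated once to
land closest to canonical geometry — rise 1.526 Å and twist 98.46°/residue —
and frozen.

**Switch trajectories.** The 11-mer helix (the peptide length the underlying
experiments share) sits axis-in-plane inside a static 24-atom scaffold cage;
frame $t$ applies the screw $\theta(t) = \theta_\mathrm{target}\,
\sigma((t-t_0)/w)$, $d(t) = d_\mathrm{target}\,\sigma(\cdot)$ with a
logistic ramp, plus i.i.d. Gaussian coordinate noise. Defaults mirror the
reported switch: $\theta_\mathrm{target} = 60°$, $d_\mathrm{target} =
1.5$ Å, onset 50 ns into a 101-frame, 1 ns/frame run, noise σ = 0.3 Å. The
ramp width of 1 ns encodes the switch-like (fast, then stable) character of
the observed transitions; it is configurable down to an abrupt step. An
optional `tilt_target` ramps an additional out-of-plane tilt for validating
the tilt metric. Ground-truth tables (θ, d, tilt per frame) accompany every
trajectory; tests compare against these, never against re-derived truths.

**Pose sets.** Cluster centers are screw placements of the helix about its
own axis spaced to a target adjacent-center RMSD (default 3.0 Å); members
add per-coordinate jitter (default 0.15 Å, i.e. pairwise within-cluster
RMSD ≈ 0.37 Å, far below the 1.5 Å clustering cutoff, as expected of
converged re-docked poses). Default occupancies 11/6/13 keep distinctly
sized clusters for unambiguous rank checks.

**Interface scenes.** Scenes use an analytically parametric helix (exact
cylindrical coordinates: twist 100°, rise 1.5 Å per residue) rather than the
internal-coordinate builder, because the exact one-residue screw symmetry is
the point: the functional atoms of the four register residues (Gln384 NE2,
Arg385 NH1, Tyr391 ring centroid, Glu392 OE1) are placed at identical
cylindrical offsets, so screwing the peptide by (−100°, −1.5 Å) moves
residue $k{+}1$ exactly into the slot residue $k$ occupied — and a single
fixed receptor scaffold (an arginine probe at 3.50, a main-chain carbonyl
probe at 3.54, and a connecting strand kept out of contact range) satisfies
*both* registers with detector-compliant geometry. Bridging waters sit on a
small circle between the 3.54 probe pair, within 2.5 Å of both partners;
bulk waters are placed 30–40 Å out. A small coordinate jitter (0.02 Å) and a
seeded global rigid motion make every seed a distinct, frame-independent
test case.

**What the generators do not emulate** — and hence what passing tests do not
show about real data: side-chain rotamer variability and induced fit,
backbone flexibility and partial unfolding during the switch, correlated
(non-i.i.d.) thermal motion, a realistic 7-transmembrane crevice with
competing contact partners, and crystallographic water networks. The
generators validate the estimators and detectors, not the biology.

## Numerical conventions and degenerate inputs

Coordinates are Å throughout; times are ns; angles are degrees in
(−180, 180] with the right-hand rule about the N→C axis. Author residue
numbering is never rewritten; alternate locations keep the
highest-occupancy conformer (ties by altloc letter) with a logged message;
waters are ordinary atoms. Out-of-range coordinates on write are an error,
never silent truncation. Empty selections are flagged, not fatal; empty
models, mismatched atom counts, asymmetric distance matrices, collinear
point sets and on-axis screw fits all fail with named errors. Generic-number
lookups outside the anchored segments are explicit misses (strict error or
`NA` by choice); two anchors that disagree on a segment's offset are an
error, not an average.

## Problem sizes

The validation suite runs on desk-scale inputs chosen as the package's
standard test conditions: 11-mer peptides (55 atoms), 101-frame
trajectories, pose sets of 17–30 poses, scenes of ~230 atoms, 100-seed
Monte-Carlo batches for noise calibration, and a 10⁶-quaternion brute-force
rotation search as the superposition oracle.

## Limitations

The package analyzes rigid screw geometry; flexible helix deformation modes
are out of scope. Binary MD formats are not parsed — trajectories enter as
multi-model PDB, conversion being the user's job. The interface-area
defaults (radius table, probe, quadrature) are one published convention
among several, so absolute buried areas are comparable only within a
convention, and reproducing any particular published interface area
additionally requires the original coordinates. Energetic scoring of
interactions, secondary-structure assignment over time and hydration-site
analysis are deliberately not implemented.
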