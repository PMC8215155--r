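---
title: "Methods: coarse-grained nascent folding in rigid exit tunnels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained nascent folding in rigid exit tunnels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ribotunnel simulates the birth of a protein: residues appear one by one at
the peptidyl-transferase centre (PTC) of a ribosome and work their way out
through the exit tunnel, a rough channel some 80--100 Å long whose diameter
varies between roughly 10 and 20 Å and which differs between the domains of
life. The package has three parts: tunnel geometry by grid probing, a
coarse-grained structure-based dynamics engine with sequential growth, and
trajectory analytics including knot detection. This vignette records the
model, the defaults and the design choices a maintainer would want to know.

## Tunnel frame and cylindrical cut-out

All geometry and dynamics live in a PTC-anchored frame: the PTC at the
origin and the tunnel axis along +z. Full ribosomes carry 10^5--10^6 atoms,
so only a cylindrical cut-out of radius `R_R = 70` Å around the axis, in the
half-space `z >= 0` starting at the PTC plane, is kept (`extract_cutout()`).
Boundary atoms are kept with a 1e-6 Å tolerance. The canonical workflow
takes a curated PTC origin and axis from the configuration;
`locate_ptc_hint()` offers a rough starting frame from the L4/L22 protein
chains (the midpoint of their mutually closest atoms, axis pointing away
from the centre of mass toward the emptier half-space) but is advisory
only, because that localisation is qualitative.

## Native models and the overlap criterion

Proteins are reduced to one bead per residue at the Cα position. Native
contacts are assigned by the all-atom overlap criterion: residues `i, j`
with `|i - j| >= 3` are in contact iff any heavy-atom pair overlaps after
the van der Waals spheres are multiplied by 1.24. The radius table is C
1.70, N 1.55, O 1.52, P 1.80, S 1.80 Å (1.70 for anything else); the
enlargement factor, the radii and the minimum sequence separation are all
arguments of `build_native_model()`. Charges are ASP/GLU = -1, LYS/ARG = +1,
histidine neutral. Synthetic traces made by `make_toy_native()` have no
side chains, so they use a Cα-distance cutoff of 7.5 Å instead — a
documented divergence from the production path that only affects fixtures.

## Grid-probe geometry

`rasterize()` lays a grid of default spacing 1 Å over the cut-out and marks
a cell occupied when its centre lies within (atom vdW radius + probe
radius) of a wall atom, i.e. occupancy is pre-inflated by the probe so that
accessibility reduces to cell reachability. The probe radius is 4 Å by
default (large enough not to penetrate the all-atom wall representation)
with 3 Å as the standard comparison value.

`probe_accessibility()` sends rays along all six grid directions from
outside; empty cells swept before the first occupied cell are marked
OUTSIDE. This is repeated for ten orientations (the identity plus nine
seeded uniform random rotations of the cut-out); a cell is finally OUTSIDE
when a majority of orientations marked it so (union and intersection rules
are selectable). The exit tunnel is then the 6-connected flood-fill
component containing the cell nearest the PTC. Per-orientation cavity
volumes are recorded and reported as mean ± standard deviation — the spread
quantifies the discretisation anisotropy, not a statistical error.
The surface is counted as cavity cell faces adjacent to an atom cell or to
an outside cell that itself touches an atom cell; note that voxel surfaces
of smooth shapes exceed the smooth area by up to 4/π, which is fine for the
comparative surface-to-volume ratios the package reports.

`axial_profile()` bins cavity cells along z (2 Å bins) into cross-section
areas and effective radii `r_eff = sqrt(A/π)`; `find_constrictions()`
smooths `r_eff` with a 3-bin moving average and reports strict local minima
ranked by distance from the PTC (CS1, CS2, ...), merging minima closer than
5 Å into the deeper one and discarding minima of prominence below 1 Å
(grid-noise wiggles of the voxelised surface otherwise masquerade as
constrictions). On real ribosomes CS1 sits around 30 Å from the
PTC with CS2 about 20 Å farther; the synthetic-waist fixtures in the test
suite mirror exactly that structure.

## The dynamics engine

Reduced units: the contact depth ε is the energy unit, lengths are in Å,
time in τ (~1 ns), unit bead masses, k_B = 1. The potential is the
standard structure-based (Gō) set:

* harmonic bonds `V = k (r - d0)^2` with `k = 100 ε/Å²`, `d0 = 3.8` Å;
* a chirality penalty `V = κ/2 · C_i²` (κ = 1 ε) applied whenever the local
  backbone chirality `C_i = [(b_{i-1} × b_i) · b_{i+1}]/d0³` has the
  opposite sign to its native value — this supplies backbone stiffness;
* native contacts as 6--12 wells `V = 4ε[(s/r)¹² - (s/r)⁶]` with
  `s = r_nat · 2^{-1/6}`, so the minimum of depth ε sits exactly at the
  native distance; a contact is *formed* when `r < 1.5 s`;
* all other non-bonded pairs, and every bead/wall-atom pair, interact by
  the truncated-shifted repulsion of characteristic length 4 Å (the 6--12
  form with `σ0 = 4·2^{-1/6}` Å cut at its minimum and shifted up by ε, so
  it vanishes smoothly at 4 Å with amplitude ε at contact);
* a bottom plate `V(z) = 332 ε (σ0/z)⁹` acts on every bead, preventing
  backward diffusion below the PTC plane and supplying the outward push on
  newly created beads;
* optional electrostatics-mimicking mouth contacts: ε-deep wells (minimum
  at 5 Å) between charged chain beads and oppositely charged wall residues
  within 10 Å of the tunnel top. They are disabled by default — enabling
  them impedes dissociation from the ribosome — and exist for comparative
  runs.

The walls are rigid: wall atoms never move, so their cell list (4 Å cells)
is built once. Bead-bead pairs are evaluated directly each step; at chain
lengths up to a few hundred beads this costs less than maintaining a
Verlet list and keeps the engine simple.

**Integrator.** BAOAB splitting of Langevin dynamics: half kick, half
drift, an exact Ornstein–Uhlenbeck velocity update with damping γ = 2/τ
and noise variance `T(1 - e^{-2γ dt})`, half drift, half kick, with
`dt = 0.005 τ`. For small γ·dt this reproduces the familiar Gaussian-force
thermostat with variance `2γT·dt`; at γ = 0, T = 0 it reduces exactly to
velocity Verlet, which is what makes the energy-conservation contract in
the tests meaningful. The room-temperature default is `T = 0.35 ε/k_B`.

**Numerical guard rails.** The 6--12 cores and the z^{-9} plate diverge at
the origin, and discrete growth events (a contact becoming eligible, a bead
appearing) can momentarily place pairs deep inside a core. Below a
switching separation (3.0 Å for the σ0 repulsions, 0.84·s for contact
wells, z = 3.5 Å for the plate) the potentials continue linearly with
constant force (C¹-continuous), so such transients relax instead of
blowing up the integrator. The linear region starts where the pair energy
already exceeds hundreds of k_BT, so equilibrium averages are unaffected.
The engine still aborts with a diagnostic if any force component exceeds
10⁶ ε/Å or a bead reaches z ≤ 0.

**Growth.** Residues appear N-terminus first. Residue k is born at the
cumulative schedule time of residues 1..k-1 and released one waiting time
t_w later, so a uniform schedule of N residues at t_w completes synthesis
at exactly N·t_w (56 residues at t_w = 100 τ finish at 5,600 τ). A new
bead appears 5 Å above the PTC plane with a seeded 0.05 Å lateral jitter
(retried with growing jitter, and eventually an error, if the site is
blocked by a wall atom or a non-bonded bead). Its bond to the previous
bead ramps linearly from zero to d0 over t_w — the quasi-continuous
growth — and its contacts become eligible only on release. While a residue
is still emerging it is tethered harmonically to its birth point,
representing the tRNA attachment that keeps the growth point at the PTC;
the tether moves to each new residue and disappears when the last one is
released. The emergence height of 5 Å (rather than directly on the plate)
keeps the plate force finite at birth; the plate energy there (~50 ε)
still accelerates the new bead outward. Velocities of pre-existing beads
are not perturbed at emergence.

## Trajectory analytics

Escape is defined as every bead's axial coordinate passing the mouth plane
(the maximal wall z by default); an N-terminus-only rule can be had by
passing an explicit plane. Outcome classification at `t_check` (default:
the end of the trajectory) labels non-escaped runs by the N-terminus
height relative to CS1 and CS2 — the same binning as the outcome
histograms (0 to CS1, CS1 to CS2, then 10 Å bins to the mouth). Folding
time is the first recorded frame at which every native contact satisfies
`r < 1.5 s`; its resolution is the frame stride, which the caller sets.

**Knots.** Open chains are closed by extending both termini radially from
the centroid to a sphere of three times the maximal extent and joining
them along a great circle — radial closure avoids the spurious knots that
direct end-joining creates in surface-adjacent conformations. The closed
chain is simplified by KMT triangle elimination (a vertex is removed when
its triangle is pierced by no other segment), projected under a seeded
random rotation (re-drawn while the diagram is degenerate), and typed by
the Alexander determinant |Δ(-1)| computed from the crossing diagram: 1 is
the unknot, 3 the trefoil, 5 the figure-eight, reported as
`other(determinant)` beyond the trefoil. At t = -1 each crossing
contributes +2 on its over-arc and -1 on both under-arcs regardless of
sign, which makes the matrix assembly straightforward and
convention-independent. `knot_core()` trims vertices from each terminus
while the sub-chain stays knotted and reports the minimal knotted
sub-chain; for natively knotted proteins such as YibK the native core ends
are the reference points for judging "properly placed" knot ends, a
judgement the package leaves to the user since no tolerance is standard.

## Synthetic fixtures and what they do (and do not) show

`make_toy_tunnel()` builds impermeable cylindrical walls of pseudo-atoms
(vdW 1.7 Å, two shells, lattice spacing ≤ 2 Å, jitter 0.3 Å) realising a
piecewise inner-radius profile with Gaussian waists; walls extend 6 Å past
both ends and can be capped (a closed lumen measures cleanly against the
analytic volume) or left open at the top for escape simulations. A flood
fill at probe radius 3 Å verifies impermeability at generation time.
`make_toy_native()` supplies ideal-geometry helices, β-hairpins and
two-helix bundles; `make_knot_curve()` supplies (2,3)-torus trefoils,
figure-eight curves and helical unknots, opened at their most distal point
with straight tails.

The fixtures reproduce the *structure* of the real problem — constrictions
at controlled positions and radii, growth against rigid walls, knotted
geometry — but not rRNA chemistry, wall roughness statistics, or
real-protein contact topologies. Green tests on fixtures therefore
validate the algorithms and the engine, not biological numbers; runs on
real ribosome structures require the user to supply the PDB/mmCIF files
and a curated PTC frame.

Problem sizes in the shipped tests and the acceptance script were chosen
to make every property visible at desk scale: chains of 10--56 residues,
tunnels of 30--100 Å, ensembles of 5--20 trajectories, 10⁵--4·10⁶ steps
per trajectory. The trapping comparison uses a 20-residue two-helix
bundle grown slowly (t_w = 300 τ) into a 35 Å tunnel with a waist at
z = 25 Å: slow growth lets the emerged chain fold below the waist, which
is precisely the regime where a narrow constriction blocks passage; with
fast growth, or with the waist too close to the PTC, the chain threads
the constriction single-file before folding and a narrow waist can even
*speed up* escape by suppressing lateral wandering — a useful reminder of
what the trapping statistics do and do not measure.
Full-scale counterparts (90--1,000 trajectories, t_E up to 1.5·10⁵ τ on
10⁵-atom cut-outs) use the same code paths with bigger numbers.

## Known limitations

* Walls are rigid by construction; tethered-atom flexibility is out of
  scope here and would likely improve escape rates.
* The Cα resolution cannot capture side-chain packing in the tunnel; an
  all-atom nascent chain would clash with the rigid walls.
* Knot typing is determinant-based: knots sharing |Δ(-1)| (e.g. 4_1 and
  5_1 both give odd determinants distinct from 3, but composite knots can
  collide) are reported by their determinant, not their full type.
* The ± spread on volumes is an anisotropy measure over grid orientations;
  it is not a confidence interval.
* Slipknot analysis is qualitative: per-frame knot status of the full
  chain versus sub-chains; no dedicated slipknot classifier is provided.
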