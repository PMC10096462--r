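---
title: "Modeling spin labels on protein structures with spinlabelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spin labels on protein structures with spinlabelr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Site-directed spin labeling (SDSL) EPR reports on protein structure through
a probe: a paramagnetic side chain (most commonly the nitroxide R1, attached
via cysteine chemistry) introduced at a chosen site. Every observable — a
DEER distance distribution between two labels, a power-saturation membrane
depth, a solvent accessibility — is co-determined by the conformational
ensemble of the label itself, whose unpaired electron sits four to eight
Angstroms away from the backbone on a flexible linker. Quantitative use of
SDSL data therefore requires modeling that ensemble explicitly.

`spinlabelr` does this by *in silico* spin labeling: a **rotamer library**
(a weighted set of discrete side-chain conformations, parameterized by their
mobile dihedral angles over fixed bond lengths and angles) is aligned onto a
backbone site, scored against the surrounding structure, reweighted, and
used to predict observables.

## The model

### Attachment and alignment

A library is aligned to a site by the **bisect** method: rotamers are
translated so their CA coincides with the site CA, then rotated so the
N–CA–C planes and the vectors bisecting the N–CA–C angles coincide. When
library and site have different N–CA–C angles this splits the discrepancy
symmetrically between the N and C sides rather than biasing the side chain
toward one of them. A least-squares (Kabsch) superposition of the N/CA/C
triad is available as the alternative (`alignment = "triad"`); the two are
identical whenever the internal triad geometries agree.

Libraries live in a canonical local frame — CA at the origin, the N–CA–C
bisector along +x, the plane normal along +z — which makes alignment a pure
frame-to-frame map and makes libraries from different sources comparable.

### Three construction modes

* **Rotamer-library (RL) method** (`sample = NULL`, the default): the
  library's discrete rotamers and prior weights are used as-is.
* **Off-rotamer sampling** (`sample = n`): each of n samples picks a parent
  rotamer with probability equal to its weight, then perturbs every mobile
  dihedral by a wrapped normal with per-dihedral width `dihedral_sigmas`
  (the library's own sigmas by default, 35 degrees if it has none — wide
  enough to bridge rotamer wells while staying concentrated near them).
  Sample weights are uniform (1/n): the proposal *is* the target mixture,
  so no importance correction applies; all environment information enters
  through clash reweighting downstream. A dihedral-potential reweighting
  term would be the alternative; we document the simpler choice.
* **Accessible-volume (AV) method** (`sample = n, dihedral_sigmas = Inf`):
  infinite sigma degenerates the wrapped normal to the uniform distribution
  on (−180°, 180°], i.e. unbiased sampling of the sterically accessible
  volume.

### Clash scoring

Rotamer–environment clashes are scored with a flat-top repulsive
Lennard-Jones potential

$$E = \sum_{i,j:\; r_{ij} \le r_\mathrm{cut}} \min\!\Big(E_\mathrm{cap},\;
\varepsilon_{ij}\big(f\, r^\mathrm{min}_{ij}/r_{ij}\big)^{12}\Big)$$

with $r^\mathrm{min}_{ij}$ the sum of the two atoms' rmin/2 radii,
$\varepsilon_{ij}$ the geometric mean of their well depths, a **forgive
factor** $f < 1$ softening contact radii to compensate for the rigid
environment approximation, and a per-pair cap $E_\mathrm{cap}$ (the "flat
top") so that a single deep overlap cannot dominate the score. The
attractive $r^{-6}$ term is omitted by default — without explicit solvent
it biases rotamers toward the protein surface — but a capped 12-6 variant
(`lj_energy_12_6`) and a SASA-augmented score (`sasa_augmented_energy`,
which rewards solvent-exposed rotamers by $-w_\mathrm{sasa}\cdot$SASA as a
proxy for label–solvent van der Waals contacts) are provided. Any function
`(ensemble, environment, params) -> energies` plugs in via `energy_func`.

Posterior weights are Boltzmann: $w_i \propto w^0_i e^{-E_i/kT}$, followed
by **trimming** — the smallest prefix of weight-sorted rotamers whose
cumulative weight reaches $1 - \mathrm{trim\_tol}$ is kept and
renormalized.

Defaults (all recorded in every ensemble's provenance, all overridable):
$f = 0.9$, $E_\mathrm{cap} = 10$ kcal/mol, $r_\mathrm{cut} = 10$ Å,
$kT = 0.593$ kcal/mol (298 K), trim_tol = 0.005. These are physically
conventional choices, declared rather than claimed equivalent to any other
package's. Per-pair (not per-rotamer) capping is likewise a declared choice.

**Clash environment.** The environment is the user's atom subset (default:
the whole structure), always minus waters, and minus the *entire* labeled
residue. Excluding only the native side chain would score the grafted side
chain's own covalent 1-2/1-3 contacts (CB–CA at 1.5 Å, and so on) as
capped clashes on every rotamer, which is chemistry, not sterics. Ligands
and cofactors count as environment unless the user excludes them.

### Observables

Per-rotamer **spin centers** are spin-weight-averaged positions of the
spin-bearing atoms (the N–O midpoint for a nitroxide); the ensemble
**spin centroid** averages those over rotamer weights. The **distance
distribution** between labels collects every rotamer pair's spin-center
distance with weight $w_{Ai} w_{Bj}$, sums over all label pairs when more
than two labels are given, smooths with a Gaussian kernel (default 0.5 Å;
0 gives the raw histogram) and normalizes once at the end — so each pair
contributes equally, a declared resolution of an ambiguity (per-pair
pre-normalization would be the alternative). The default grid is 0–100 Å at
0.5 Å, covering the DEER-relevant range. Distances falling off the grid are
clipped to the edge bins with a warning rather than aborting a screen.

Site-pair screening attaches a label at every residue whose side-chain
solvent-accessible surface area (Shrake–Rupley, probe 1.4 Å, strict
threshold > 50 Ų, glycine excluded) passes in both conformational states,
and ranks pairs by the 1-D earth-mover's (Wasserstein-1) distance between
the two states' predicted distributions, $\int |F_P - F_Q|\,dr$.

### Repacking

`repack` runs Markov-chain Monte Carlo over the label sites plus every
rotatable residue within a radius (default 10 Å) of any label rotamer atom.
Each step picks a region site uniformly, draws a rotamer from that site's
set by prior weight, optionally perturbs its dihedrals (off-rotamer mode),
and accepts by Metropolis–Hastings on the energy change of the moved side
chain against the current environment. Because proposals are drawn from
prior weights, the correct M–H ratio includes the proposal factor
$q(\mathrm{old})/q(\mathrm{new})$; this is the default, with plain
Metropolis available for comparison (`proposal_correction = FALSE`). Before
a site's first accepted move its conformation is not a member of its
discrete rotamer set, so the proposal factor is omitted for that one move.
Energies are reported for **all** steps (relative to the start), coordinate
frames for the initial state and every **accepted** step; site energies are
recomputed in full at every move, so there is no incremental-energy drift
to control. `from_trajectory` rebuilds a standard spin-label ensemble from
the post-burn-in frames (default burn-in 20%), merging frames whose mobile
dihedrals agree within 1e-6 degrees and weighting by frame fraction.

Canonical residues use a small bundled backbone-independent rotamer set:
standard chi quadruplets per residue type with gauche−/trans/gauche+ grids
(chi1 weighted 0.5/0.3/0.2, higher chis uniform). This is a deliberately
minimal, fixture-grade stand-in for a full backbone-dependent library —
redistribution-friendly and self-contained — and external libraries in the
archive format are accepted wherever a label library is.

### Membrane docking

Power-saturation depths (phosphate plane at z = 0, positive z into the
hydrocarbon core) constrain a rigid pose: rotation of the protein about the
centroid of its spin centroids by intrinsic Z–Y–Z Euler angles
$R_z(\alpha) R_y(\beta) R_z(\gamma)$, then translation along z. The fit
minimizes squared differences between transformed spin-centroid
z-coordinates and measured depths, by Nelder–Mead from eight dispersed
starting orientations (derivative-free: the surface is smooth but multimodal
in $\beta$). Planar depth data cannot constrain rotation about the membrane
normal; since the world-frame normal rotation is the *leftmost* factor,
the unconstrained angle is $\alpha$ — reported, but flagged
`alpha_unconstrained` rather than silently fixed. ($\beta$ and $\gamma$ are
both identifiable away from the $\beta \in \{0°, 180°\}$ poles; noise-free
synthetic fits recover them to machine precision.)

## The synthetic world

The test suite runs entirely on generated fixtures, so what a green test
establishes is bounded by what they emulate:

* `make_helix(n)` — ideal poly-alanine α-helix (φ = −57°, ψ = −47°,
  standard bond geometry), axis on z. Real proteins have irregular
  backbones, packed cores and heteroatoms; the helix validates geometry and
  bookkeeping, not force-field realism.
* `make_toy_label_library()` — a 3-rotamer, 9-atom nitroxide-like label
  ("TOY"/"TYL"): a CB–SG–C1–N1–O1 arm with two mobile dihedrals, weights
  (0.5, 0.3, 0.2), spin atoms N1/O1 at half weight each. Its spin centers
  sit 4.9–6.0 Å from CA, in the range of real nitroxide labels, so
  distance-distribution tests are geometrically realistic; its chemistry is
  not real.
* `make_hinge(n, angle)` — two helical arms; state B rotates arm 2 about an
  axis through the spin centroid of the label at a designated arm-2 site
  (computed with clash evaluation, exactly as the screen will see it). By
  construction that site's label barely moves while its CB does — the
  analogue of a site pair with large backbone change but little
  distance-distribution contrast — and pairs spanning the hinge change a
  lot. The screen tests assert exactly these two facts.
* `make_depths` — synthetic depths from a known pose plus Gaussian noise,
  for parameter-recovery tests (noise-free recovery to 0.1 Å in z; mean z
  bias under 1 Å noise below 0.5 Å over 100 replicates).

Statistical tests (χ² on off-rotamer parent frequencies at n = 10⁴,
Kolmogorov–Smirnov uniformity for the accessible-volume limit, two-state
Boltzmann occupancy of the repack chain at 10⁵ steps within three
Monte-Carlo standard errors computed by batch means to honor
autocorrelation) run under fixed seeds.

## Numerical choices

* Dihedrals are wrapped to (−180°, 180°]; wrapped normals are sampled
  unwrapped then wrapped (exact for σ ≪ 360°).
* `set_dihedral` rotates, rigidly, the connected component on the far side
  of the central bond (bond graph inferred geometrically: heavy-heavy
  ≤ 1.9 Å, X–H ≤ 1.2 Å, since conformer PDBs often lack CONECT records);
  bond lengths, angles, and chained dihedrals are preserved to 1e-6.
* Internal-coordinate rebuilds place the fourth atom of each mobile
  dihedral against exactly that dihedral's first three atoms, and define
  sibling atoms sharing the pivot *relative to* the mobile atom so they
  ride with it.
* The rotamer archive is a plain stored ZIP (written in pure R, read by
  R's internal unzip): `manifest.json` plus row-major little-endian
  float64 arrays. Integrity is guarded by per-array CRC-32 checksums in
  the manifest (no cryptographic hash is available in the base stack;
  corruption detection, not tamper-proofing, is the goal). Loading is
  bitwise-faithful: stored arrays are not re-derived.
* Trimming uses a 1e-12 slack on the cumulative-weight comparison so exact
  ties are kept, and always retains at least one rotamer.
* Reweighting shifts energies by their minimum before exponentiating;
  degenerate posteriors (all mass on zero-prior rotamers) raise an error.

## Known limitations

* The bundled LJ table and canonical rotamer grids are fixture-grade, not a
  validated force field or rotamer library; both are swappable.
* No hydrogens are generated; structures are scored as given.
* Insertion codes, mmCIF, and trajectory formats are unsupported.
* The repack energy is a sum of per-site side-chain/environment terms
  evaluated one move at a time; inter-site pair terms are counted from the
  mover's perspective only, as in standard single-move repacking.
* Depth docking assumes a planar membrane and error-free spin centroids;
  per-site uncertainties enter only as optional residual weights.
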