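---
title: "Helical lattice analysis of two-species filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattice analysis of two-species filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixlat)
```

## The model

A 1-start helical filament is generated by a single screw operator: each
subunit is related to the next by an axial **rise** $\Delta z$ (Å) and a
**twist** $\Delta\phi$ (degrees) about the filament axis. Subunit $i$ sits at
azimuth $i\,\Delta\phi \bmod 360$ and height $i\,\Delta z$; the operator for
a neighbour offset $k$ is the $k$-fold composition,
$(k\,\Delta z,\ k\,\Delta\phi)$. Connecting every $k$-th subunit partitions
the filament into the $k$-start strand family: $k$ strands whose step is
$(k\,\Delta z,\ \mathrm{princ}(k\,\Delta\phi))$, where $\mathrm{princ}$ maps
an angle into $(-180, 180]$.

The motivating system is the archaellum, the rotary swimming filament of
archaea. Its lattice, rise 5.57 Å and twist 108°, looks at first like a
one-species helix, but the filament is a heteropolymer of two archaellins
(ArlB1, ArlB2) that alternate along the three left-handed 3-start strands —
with one of the three strands shifted out of register by one subunit. The
package models this as a **register pattern**: $s$ strands, $q$ species, and
a per-strand phase offset in $[0, q)$, inducing the subunit labeling

$$\mathrm{species}(i) = \left(\lfloor i/s \rfloor + \mathrm{off}[i \bmod s]\right) \bmod q .$$

Two consequences of the archaellum register (offsets $(0,0,1)$) carry the
whole analysis:

* the minimal index period after which species labels repeat is **6**, not 2,
  so the true helical symmetry is the 1-start lattice reduced by period 6:
  rise $5.57 \times 6 = 33.42$ Å and twist $\mathrm{princ}(6 \times 108) =
  -72$° (a perfectly in-register alternation would give period 2:
  11.14 Å and raw 216°, which fails against the data);
* contact types split by direction: along the 3-start step ($k = 3$) only
  heterotypic ordered pairs occur, while along the 7-start step ($k = 7$)
  all four ordered species pairs occur, and single-species traces form
  broken "stepped" pseudo-strands with the cyclic gap motif $(1, 1, 4)$.

```{r register}
sym <- helical_symmetry(5.57, 108)
lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
reduced_symmetry_for_labeling(sym, lab)
species_pairs_along(lab, 3)
pseudo_strand_steps(lab, 0)
```

## Conventions and parameters that matter

* **Handedness.** Positive twist is a right-handed rotation about $+z$ when
  advancing along $+z$. Under this convention the 3-start family of the
  archaellum lattice steps by $-36$° (left-handed) and the 7-start family by
  $+36$° (right-handed). The original structural work describes the 7-start
  strands once as right- and once as left-handed; the geometry here is
  purely a consequence of the sign convention, and only the geometry is
  asserted.
* **Angle ranges.** Both the raw twist (reported in $[0, 360)$) and the
  principal twist (in $(-180, 180]$) are stored, because both conventions
  appear in practice (e.g. "216°" vs "$-72$°"); the principal value is the
  default.
* **Tolerances.** Angles are compared at $10^{-6}$ degrees and lengths at
  $10^{-9}$ Å unless overridden. `axial_repeat()` and the handedness
  classification use the angular tolerance to decide "vertical".
* **Indexing.** Subunit 0 sits at the origin and indices increase with
  $+z$; strand indices are likewise 0-based.
* **Refined parameters.** Experimentally refined values such as
  (33.4 Å, $-71.8$°) are treated as empirical inputs; exact lattice
  arithmetic gives (33.42, $-72$) and no attempt is made to derive the
  refined decimals.

## Register inference

`infer_register()` inverts the labeling formula from an observed label
sequence. Species labels in real annotation tasks are symbols, not
integers, so the integer value of each species in the alternation cycle
must be inferred together with the offsets. The global phase is pinned by
assigning value 0 to the first-observed species (which forces strand 0's
offset to 0), and the remaining value assignments are enumerated; the one
that reproduces the observed sequence exactly is returned along with a
`species_map` from values back to the original labels. This is a deliberate
refinement over renaming species purely by order of first appearance: an
arbitrary renaming is not in general a rotation of the alternation cycle,
and only rotations preserve realizability by the formula. If no assignment
works, the error names the first inconsistent subunit index (the
verification window must be at least $2sq$ labels; the formula is exactly
periodic, so a finite window is exhaustive).

## Contact analysis

Contacts are geometric, distance-only tallies:

* **Hydrogen bonds** — donor/acceptor N/O heavy-atom pairs within 3.5 Å,
  with roles taken from a residue chemistry table (backbone N donates,
  backbone O accepts, side chains per standard chemistry).
* **Salt bridges** — Lys NZ / Arg NE,NH1,NH2 / His ND1,NE2 to Asp/Glu
  carboxyl oxygens within 4.0 Å. A charged pair inside both cutoffs counts
  in both tallies.
* **Tail-core contacts** — each subunit's tail centre-line (least-squares
  axis of its tail atoms, clipped to a finite segment) compared by minimal
  segment–segment distance, cutoff 8 Å.

No angle terms are applied and no interface energetics are computed: PISA
dissociation energies reported for the real structure depend on unpublished
criteria and are out of scope, which every contact report states in its
header. Counts on the real deposited structure (13 hydrogen bonds / 3 salt
bridges at one heterodimer interface, 8/2 at the other) are therefore
indicative context, not assertions this package reproduces.

The pair scan uses a cell-list spatial hash with cell size equal to the
cutoff; an $O(N^2)$ all-pairs scan is kept as the test oracle.

## The bend model

Filament flexibility is modelled **forward**: the straight axis is mapped
onto a circular arc of curvature $\kappa$ (1/Å) in a chosen bend plane, and
each subunit rides to its arc station as a rigid body, rotated by the local
tangent angle $\theta = \kappa z$. Arc length along the neutral axis is
preserved, so inter-subunit spacing contracts on the concave side by the
factor $(1 - \kappa r)$ and expands on the convex side by $(1 + \kappa r)$
at radius $r$. The mapping requires $\kappa r_{\max} < 1$ and is the
identity at $\kappa = 0$. An optional hinge swing adds a rigid rotation of
each head domain about its two-residue hinge (the conserved Ser–Gly linker
between tail and head); its default amplitude is 0 because no quantitative
hinge angles are published for the motivating system.

This is a generator of bent conformations with the qualitative properties
observed by 3D variability analysis of real filaments — concave
compression, convex stretch, opposite axial columns sliding in opposite
directions, heads moving as rigid bodies — not a re-analysis of image data.
`motion_report()` mirrors the measurement operations used on such data:
per-subunit displacement vectors, head displacement after tail alignment,
per-domain internal RMSD (exactly 0 here by construction), tail axial slide
and tail rotation about the reference axis; `head_trajectories()` follows
head centroids across a conformational series.

## The synthetic fixture

`make_fixture_filament("mvillosus", n)` builds a straight two-species toy
filament on the (5.57 Å, 108°) lattice with register offsets $(0,0,1)$. Toy
monomers are reduced representations: a 46-residue tail (one CA per
residue, residues 14–59, ideal-helix geometry at 1.5 Å axial spacing per
residue, end-to-end ≈ 69 Å), hinge residues Ser60–Gly61, and a globular
head as a pseudo-atom shell, with a small set of typed polar/charged sites
planted across the 3-start head–head interface and, on species 1, an extra
outward-facing loop (residues 131–137, mirroring the glycosylation loop
that distinguishes the two archaellins).

The tail centre-line runs from radius 4.5 Å at the core to 16 Å with an
80° azimuthal sweep. These constants were calibrated once, by a grid search
over the centre-line geometry, so that the minimal segment–segment
distances to neighbours $k = 1, 3, 4, 7$ fall at 6.4/6.4/2.7/6.3 Å and all
other $|k| \le 12$ stay at 9.4 Å or more — i.e. the tail-contact shell is
exactly $\{\pm1, \pm3, \pm4, \pm7\}$ with ≥ 1.4 Å margin on either side of
the 8 Å cutoff. The constants are fixed in `fixture_config()` and not
fitted at run time.

What the fixture does **not** emulate: real side-chain rotamers and packing
(heads are smooth shells), glycans and metal sites (annotation only),
cryo-EM density or noise, and the absolute contact counts of the deposited
structure. Tests passing on the fixture therefore validate the lattice
algebra, the register logic, the geometric contact machinery and the bend
kinematics — not the energetics or atomic detail of any real filament.

## Numerical choices and degenerate inputs

* Cyclic gap motifs are canonicalized as the lexicographically minimal
  rotation, making `pseudo_strand_steps()` independent of the trace origin.
* `out_of_register_strands()` requires a strict modal offset and raises an
  ambiguous-register error otherwise (e.g. two strands with two distinct
  offsets).
* A constant label sequence presented with $q = 2$ triggers a degenerate
  warning (species unused) and then an inconsistency error, since the
  alternation formula cannot produce it.
* mmCIF is the primary structure format (multi-character chain ids
  `S0001…`); PDB output is limited to 62 chains and fails with a pointer to
  mmCIF beyond that. Coordinates round-trip at $10^{-3}$ Å.
* Degenerate segment fits (single-point tails) fall back to point–segment
  distances.

## Problem sizes

The shipped tests run the property suites at: 1000 random operator
compositions, 200 random register patterns against a brute-force period
oracle, 30–60-subunit fixtures (~100 atoms per subunit) for contact maps
and bend frames, and dense-sampling segment oracles at 400 points per
tail. The full suite completes in well under a minute on a single CPU.

## Known limitations

* Contact counts use distance-only criteria; no donor–acceptor angles, no
  buried surface area, no energetics.
* The bend model is kinematic: it asserts nothing about forces, torques or
  the propensity of a given register to supercoil.
* Register inference assumes every strand alternates with the same period
  $q$; more general colourings (e.g. per-strand species sets) are out of
  scope.
* Species labels are symbolic throughout; nothing is inferred from density
  or sequence.
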