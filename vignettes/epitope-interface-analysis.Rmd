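---
title: "Structure-based epitope interface analysis with epimapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based epitope interface analysis with epimapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

## The scientific problem

Myasthenia gravis autoantibodies bind the main immunogenic region (MIR) of
the muscle nicotinic acetylcholine receptor (nAChR) α1 subunit, cross-link
receptor pentamers and drive receptor internalization.  Given a crystal
structure of an antibody Fab bound to the receptor extracellular domain,
the questions a structural immunologist asks are mechanical and geometric:

* which residues form the interface, and through what chemistry
  (hydrogen bonds, salt bridges, cation-π, π-stacking, water bridges)?
* how much surface is buried, and which residues are the binding
  *hotspots*?
* is the epitope conserved in other subunits and species — will the
  antibody cross-react, and which substitutions break binding?
* can a divalent IgG engage two α1 subunits in one pentamer, or only
  subunits on *different* pentamers (cross-linking)?

`epimapr` implements this analysis pipeline as reusable, tested components
over a plain atom-table structure model.

## Models and procedures

### Contact mapping and interaction typing

Two partner groups (disjoint chain sets) are compared atom-by-atom; every
heavy-atom pair within the contact cutoff (default **4.5 Å**, inclusive,
matching the "within 4.5 Å" convention of interface mapping) is a contact.
Contacts are then typed on heavy-atom geometry only — crystal structures
rarely carry hydrogens, so hydrogen bonds are judged by donor–acceptor
distance (≤ 3.5 Å) plus the antecedent–donor–acceptor angle (≥ 90°), never
by explicit hydrogen positions.  Salt bridges require opposite
formal-charge side-chain atoms (Asp/Glu carboxylate oxygens vs Lys NZ,
Arg NE/NH1/NH2, His ring nitrogens) within 4.0 Å.  Cation-π requires the
cation within 6.0 Å of the aromatic ring centroid and within 45° of the
ring normal; π-stacks require centroids within 5.5 Å.  Tryptophan
contributes its six-membered ring (the dominant π face); histidine rings
are always flagged `tentative` because protonation cannot be read from
heavy atoms.  Water-mediated hydrogen bonds are searched separately: a
water whose oxygen satisfies hydrogen-bond geometry to *both* partners
bridges them, and one record is emitted per bridged residue pair per
water.

Only the 4.5 Å rule comes from the source analysis this package
re-implements; the typing thresholds are standard structural-biology
defaults and every one is exposed in `contact_params()`.

A contacting residue pair that earns no specific type falls back to van
der Waals (`vdw`) records.  The fallback is applied at **residue-pair**
granularity: when two residues already share a salt bridge, their
peripheral atom contacts are regarded as part of that interaction rather
than as an independent vdW category.  This keeps "the set of interaction
types between two residues" meaningful — a designed salt-bridge fixture
classifies as exactly {salt bridge, hydrogen bond}, not {salt bridge,
hydrogen bond, vdw}.

### Contact profiles and hotspots

The per-residue profile counts *distinct partner residues* (not atom
pairs): it is the quantity displayed above epitope sequence alignments.
A hotspot is a residue with at least `hotspot_min_partners` (default
**5**) distinct partners.  "Numerous contacts" is qualitative in the
literature; five distinct partners is the smallest threshold that clearly
separates anchoring residues from peripheral ones, and it is exposed as a
tunable and recorded verbatim in every hotspot call.

### Buried surface area

Solvent-accessible surface area uses the Shrake–Rupley method with a
deterministic golden-section spiral point set (default **960** points per
atom, probe **1.4 Å**, united-atom radii: C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å).  The spiral makes every run bit-reproducible; at 960 points the
relative quadrature error on protein-sized atoms is well under 1% (the
test suite checks an isolated sphere against the closed form and 960- vs
4000-point convergence below 0.5%).

Two conventions for an "interface area" circulate: the total change of
accessible area on complexation, `bsa_total = SASA(A) + SASA(B) −
SASA(A∪B)`, and the per-side average `interface_area = bsa_total / 2`
(the PISA-style figure).  Published values often do not state which
convention was used, so `interface_area()` always reports **both**.
Waters and hydrogens are excluded from the calculation by default; the
same parameter set is used for all three SASA evaluations, so separated
bodies give exactly zero buried area and occlusion is monotone.

### Epitope conservation and cross-reactivity

The receptor-side profile is projected onto a user-supplied multiple
sequence alignment through the reference row (the structure's own
sequence; a 95% identity check guards against misnumbering).  Each target
sequence is scored as the weighted fraction of compatible contacting
positions — identical 1, conservative 0.5 (groups D/E, K/R, N/Q, S/T,
I/L/V/M, F/Y/W), divergent or gap 0 — with the distinct-partner counts as
weights, so hotspot positions dominate and non-contacting positions are
ignored entirely.

The verdict rule is deliberately conservative about what it claims: a
target is `likely_disrupted` when a **hotspot position carries a
charge-reversal substitution** (e.g. D→K, which turns an attractive pair
repulsive) or when the weighted score falls below 0.7; otherwise
`compatible`.  Charge *loss* at a hotspot (e.g. K→N) lowers the score but
does not veto on its own — orthologs carrying neutral replacements at
charged hotspot positions are known to retain antibody binding, and a
loss removes an interaction rather than inverting it.  The scoring makes
no affinity claim; it flags qualitative shape/charge complementarity.

### Rigid-body assembly and divalent feasibility

Grafting places the antibody onto a pentamer subunit by Kabsch
superposition of receptor Cα atoms (paired by residue number; reflections
are never returned — an improper optimum has its smallest singular
direction flipped).  A real receptor domain graft requires at least 50
mappable Cα pairs by default; toy fixtures lower `min_pairs` explicitly.

Divalent binding is reduced to the geometry it actually depends on: each
bound Fab defines a *binding frame* — the paratope anchor point plus the
fixed direction along which the rigid Fab arm extends away from the
epitope (the binding interface is rigid; the orientation of a bound Fab is
not negotiable).  A two-arm antibody can engage two frames when a hinge
position exists at one arm length from both anchors such that

1. each arm direction deviates from its frame axis by at most `elbow_max`
   (default 20°, the declared elbow flexibility),
2. the inter-arm angle lies in the hinge sweep (default 20°–160° in 10°
   steps, giving an achievable tip-span envelope
   `2·L·sin(θ/2)`), and
3. the posed antibody makes no van der Waals clash (overlap > 0.4 Å)
   with the receptor bodies, excluding the paratope-proximal 10 Å of each
   arm, which is *supposed* to touch the antigen.

Candidate hinge positions are sampled on the locus circle (36 samples).
On an upright-binding pentamer the two α-subunit frames point up and
apart, so no hinge position can satisfy the arm-direction constraint —
intra-pentamer binding fails for directional reasons even though the raw
anchor separation lies inside the span envelope.  Two pentamers tilted
toward each other bring the frames into convergence and the same test
succeeds, which is exactly the cross-linking geometry; the angle between
the two five-fold axes of a feasible model (`tilt_analysis()`) is then
the membrane-deformation the cross-link implies (0° would mean both
receptors stand upright on a flat membrane).

The pentamer five-fold axis is computed without symmetry annotations: the
principal axis of the Cα inertia tensor closest to the mean of the
inter-subunit centroid normals.

## The synthetic-structure module

All tests and the acceptance script run without any downloaded
coordinates.  `make_interaction_fixture()` builds minimal two-chain
complexes from idealized residue templates (heavy atoms, near-ideal bond
geometry, regular aromatic rings) in which the designed interaction is the
only specific one present; the designed key distance is realized exactly
and out-of-range requests are refused.  `make_toy_pentamer()` builds C5
rotational copies of a mini-domain about z (chains A–E), so the symmetry
axis and the 72° subunit spacing are known by construction.
`make_igg_dumbbell()` builds a two-arm antibody surrogate whose tip span
is an analytic function of arm length and hinge angle; the arms carry a
rigid zigzag so that superposition onto an arm is rotationally
determinate.

`make_epitope_complex()` is a **synthetic stand-in** for the deposited
antibody–receptor complex, which cannot be redistributed with the
package.  It encodes, from the published residue identities, the
interaction network of the real interface: Asp71 salt-bridged to Arg50
(heavy chain) and hydrogen-bonded to Tyr95 (light chain); the Asn68
side-chain amide making exactly three hydrogen bonds to light-chain
main-chain atoms (Tyr91 carbonyl, Gly94 amide and carbonyl); Arg6
cation-π stacked on Trp52 with a hydrogen bond to Asp54; Lys10
salt-bridged to Asp53; His3 water-bridged to the heavy chain; each of the
four hotspots contacting five distinct partners, the N-terminal helix
touching the heavy chain only and the MIR touching both chains.  What the
stand-in does **not** emulate: the full domain folds, the real packing
density (its buried area is that of the designed epitope patch, not of
the complete deposited interface), crystallographic waters beyond the
designed bridge, and any residue outside the two epitope segments.
Passing tests on the stand-in therefore validate the *pipeline logic*
against a known-answer geometry, not the numerical values of any
deposited entry.

`make_epitope_alignment()` is the matching sequence panel, restricted to
the two epitope segments (positions 1–14 and a 62–79 MIR window).  Only
positions with published identities vary between rows (the α9
replacements K6/D10/D68/Q71, the *Xenopus* α1-b N68D/D71K pair, Asn10 in
*Torpedo*, plus two zero-weight filler differences that exercise
weight-invariance); all other filler positions are identical across rows
and are documented as synthetic, so they can never influence a
compatibility score.

## Numerical choices and degenerate inputs

* Alternate conformations: the highest-occupancy conformer is kept, ties
  resolved toward altloc A, so downstream geometry always sees one
  conformer.
* Author numbering of deposited entries is authoritative; nothing is
  renumbered.
* Waters are residues named `HOH` only; they are excluded from contact
  groups and SASA by default and consulted only by the water-bridge
  search.
* Neighbor search uses an exact cell list with an inclusive boundary
  (`distance ≤ cutoff`); the test suite holds it equal to an all-pairs
  scan on 1000-atom fixtures.
* Sorting of every output table is total (count desc, chain, residue
  number, insertion code, atom serial), so reruns are byte-identical.
* Kabsch superposition requires ≥ 3 non-collinear paired points; empty
  selections, unknown chains, overlapping partner groups, missing ring
  atoms and unknown elements are hard errors that name the offender.
* Problem sizes throughout the examples and tests — a ~235-atom epitope
  complex, 300-atom toy pentamers, 1000-atom neighbor fixtures, 960-point
  SASA spheres — are the smallest at which every property under test is
  non-trivial.

## Known limitations

* SASA is Shrake–Rupley only; no Lee–Richards slices, no solvent-excluded
  surface, no curvature corrections.
* Interaction typing is geometric; there is no energetics, no scoring
  function, and no affinity prediction anywhere in the package.
* The hinge model is a coarse declared sweep (rigid arms pivoting about a
  point); real IgG hinges have anisotropic, subclass-dependent
  flexibility.
* The conservation verdict is a qualitative complementarity flag; a
  `compatible` verdict does not imply measurable binding.
* mmCIF reading is delegated to `bio3d::read.cif()` and inherits its
  dialect coverage.
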