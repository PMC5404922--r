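# epimapr

Structure-based epitope mapping and antibody–receptor interface analysis
in R.

Myasthenia gravis (MG) autoantibodies bind the main immunogenic region
(MIR, residues 67–76) and the N-terminal helix (residues 1–14) of the
muscle nicotinic acetylcholine receptor (nAChR) α1 subunit, and
pathology follows from divalent antibodies cross-linking receptor
pentamers.  Given antibody/receptor coordinates, `epimapr` answers the
questions that analysis turns on:

* **Interface mapping** — all residue contacts under a distance rule
  (default 4.5 Å), typed as hydrogen bonds, salt bridges, cation-π,
  π-stacks, water-mediated bridges or van der Waals contacts, on
  heavy-atom geometry (no hydrogens required).
* **Buried surface** — Shrake–Rupley solvent-accessible surface area with
  a deterministic spiral point set; `ΔSASA = SASA(A) + SASA(B) −
  SASA(A∪B)` reported in both the total and the half (per-side)
  convention.
* **Hotspots** — per-residue profiles of distinct partner counts and a
  threshold hotspot call.
* **Cross-reactivity** — projection of the contact profile onto a
  multiple sequence alignment and a weighted compatibility score
  (identical 1, conservative 0.5, divergent 0), with charge-reversal
  substitutions at hotspots vetoing binding.
* **Divalent feasibility** — rigid-body grafting of the antibody pose
  onto pentamer subunits and a hinge-geometry + clash test of whether one
  IgG can bridge two binding sites within one pentamer or across two.

A synthetic-structure module (`make_interaction_fixture()`,
`make_epitope_complex()`, `make_toy_pentamer()`, `make_igg_dumbbell()`,
`make_epitope_alignment()`) builds every fixture the analyses need, so
the whole package runs and tests itself without downloading coordinates.
The bundled epitope complex is a designed stand-in encoding the published
interaction network, not deposited coordinates — see the vignette.

## Worked example

```r
library(epimapr)

m  <- make_epitope_complex()                 # or read_structure("complex.pdb")
ga <- select_group(m, "R",   label = "receptor")
gb <- select_group(m, "H,L", label = "antibody")

con  <- map_contacts(m, ga, gb)              # 4.5 A rule
prof <- contact_profile(con, side = "a")
call_hotspots(prof)
#> <hotspot_call: 4 residue(s); criterion: distinct contacting partner residues >= 5>
#>   chain resnum icode resname n_partners
#> 1     R      6           ARG          5
#> 2     R     10           LYS          5
#> 3     R     68           ASN          5
#> 4     R     71           ASP          5

interface_area(m, ga, gb)
#> <interface_area receptor | antibody>
#>   bsa_total         725.0 A^2 (buried A 439.3, buried B 285.7)
#>   interface_area    362.5 A^2 (half convention)

ix <- classify_interactions(m, con)
table(ix$kind)
#>           cation_pi               hbond         salt_bridge
#>                   1                   8                   8
#>                 vdw water_mediated_hbond
#>                  48                   2
```

The four hotspots are the receptor residues anchoring the interface
(Arg6 and Lys10 on the N-terminal helix, Asn68 and Asp71 on the MIR);
the interaction table carries, among others, the Asp71–Arg50 salt bridge
and the three hydrogen bonds of the Asn68 side-chain amide to the light
chain.  Projecting the profile onto the bundled epitope-region panel:

```r
aln   <- make_epitope_alignment()
cm    <- map_profile_to_alignment(prof, aln, "human_a1")
panel <- cross_species_panel(cm, aln, setdiff(aln$id, "human_a1"),
                             hotspots = call_hotspots(prof))
panel[, c("target_id", "score", "verdict")]
#>     target_id     score          verdict
#> 1   bovine_a1 1.0000000       compatible
#> 2  chicken_a1 1.0000000       compatible
#> 3    mouse_a1 1.0000000       compatible
#> 4      rat_a1 1.0000000       compatible
#> 5  torpedo_a1 0.7727273       compatible
#> 6 xenopus_a1b 0.5454545 likely_disrupted
#> 7    human_a9 0.2045455 likely_disrupted
```

α9 (which swaps all four hotspot identities) and *Xenopus* α1-b (N68D +
the charge-reversing D71K) are called disrupted; the α1 orthologs are
compatible.  Divalent binding on a toy pentamer:

```r
pent   <- make_toy_pentamer()
igg    <- make_igg_dumbbell(75, 120)
frames <- lapply(c("A", "C"), function(ch) subunit_frame(pent, ch, 15, 0))
divalent_feasibility(frames, igg, obstacles = list(pent),
                     mode = "intra_pentamer")$feasible
#> [1] FALSE
pair <- facing_pentamer_pair(pent, tilt = 30)
inter <- divalent_feasibility(pair$frames, igg, obstacles = pair$pentamers,
                              mode = "inter_pentamer")
inter$feasible; tilt_analysis(inter)
#> [1] TRUE
#> [1] 60
```

One antibody cannot span two upright sites on the same pentamer, but
bridges two tilted pentamers — the cross-linking geometry, with the tilt
angle quantifying the implied membrane deformation.

Pipelines (`run_interface_report()`, `run_crossreactivity()`,
`run_assembly()`) wrap these steps and write TSV/JSON bundles with a
hashed MANIFEST; `inst/exec/epimap.R` exposes them as a small command
line (`contacts`, `crossreact`, `assemble`, `synth`).

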