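# cntglycan

Carboxylated carbon nanotubes (fCNT) are a standard route to making
nanotube surfaces biocompatible, and glycosaminoglycans — hyaluronan
(HA) and chondroitin (Ch), with their monosaccharide building blocks
GlcA, GlcNAc and GalNAc — are natural candidate coating agents.  Whether
and how these sugars adsorb depends on the protonation state of the
surface carboxyl groups, on which molecular face (the H1–H5 side vs the
H2–H4/O4 side) meets the surface, and on how adsorption distorts the
glycosidic backbone.

`cntglycan` is an R package for people who study such systems with
molecular simulation.  It provides:

* **Structure builders** — periodic zigzag (n,0) nanotubes
  (radius $\sqrt{3}\,n\,a_{cc}/2\pi$, period $3a_{cc}$, 4n carbons per
  cell) and finite hydrogen-capped clusters, carboxyl grafting with
  sp²→sp³ rehybridization of the anchor and its neighbor, and exact
  charge bookkeeping: after redistribution the tube carries exactly
  −1 e per carboxylate group.  Idealized ⁴C₁ models of GlcA / GlcNAc /
  GalNAc and HA/Ch decamers with IUPAC atom names and glycosidic
  torsions φ = O5‑C1‑O1‑C′ₙ, ψ = C1‑O1‑C′ₙ‑C′ₙ₋₁.
* **Box assembly** — tube on the box axis, overlap-free glycan copies,
  Na⁺/Cl⁻ at a prescribed ionic strength plus counterions
  (`round(c·N_A·V)` pairs; exactly neutral).
* **A synthetic-trajectory generator** — two-state adsorption kinetics,
  facial orientation with angular noise, wrapped-normal torsion-basin
  sampling — so every analysis is testable without MD.
* **Trajectory analyses** — radial density profiles and 15/20 Å
  monolayer metrics, orientation-side classification, detachment
  events, strict geometric hydrogen-bond counting (d < 3 Å,
  acceptor–donor–H angle < 20°), Lennard-Jones/Coulomb pair energies
  with a 1.2 nm cutoff and minimum image, free-energy maps by Boltzmann
  inversion (F = −k_BT·ln P/P_max at 310 K), RMSF, and Cremer–Pople
  ring-pucker classification.

## Worked example

```r
library(cntglycan)

## the production-size functionalized tube: (17,0), 14 cells, 2% coverage
tube <- build_zigzag_cnt(lattice_spec(17, 14))
fcnt <- redistribute_residual_charge(
  graft_groups(tube, graft_spec("carboxylate",
                                coverage_fraction = 0.02, rng_seed = 1)))
fcnt
#> fcnt_model: 1032 atoms (952 wall C), 1508 bonds, periodic z = 5.9520 nm, groups: 20 carboxylate
#>   net charge -20.000000 e
```

952 wall carbons, 20 carboxylate groups (`ceiling(0.02 * 952)`), a
5.952 nm periodic box edge, and an exactly integral net charge.

```r
## a small demonstration system and synthetic trajectory
small <- redistribute_residual_charge(
  graft_groups(build_zigzag_cnt(lattice_spec(8, 3)),
               graft_spec("carboxylate", n_groups = 4, rng_seed = 1)))
sys <- assemble(small, build_monosaccharide("GlcNAc"), copies = 2, seed = 1)
tr  <- generate_trajectory(sys, adsorption_scenario(facing = "A"),
                           n_frames = 200, seed = 2)

rows <- which(tr$atoms$type == "glycan")
layer_metrics(radial_profile(tr, rows))$fraction
#> r15 r20
#>   1   1
o <- orientation(tr)
sprintf("side A peak %.2f A, side B peak %.2f A -> %s",
        o$side_a_peak, o$side_b_peak, o$label)
#> "side A peak 7.25 A, side B peak 10.25 A -> A(H1-H5)"
mean_pair_energy(tr)
#>    class      E_LJ E_coulomb   E_total        se n_molecules n_frames
#> 1 GlcNAc -15.10809         0 -15.10809 0.5976272           2      200
```

Every glycan atom stays inside the 15 Å monolayer; the H1–H5 face peaks
3 Å closer to the axis than the H2–H4 face, so the classifier recovers
the scripted orientation; and the mean tube–molecule interaction is
reported per single molecule with a block-average standard error.

Decamers, torsion statistics and puckering:

```r
ha <- build_decamer("HA")
ha
#> glycan_chain: 10 residues (GlcA-GlcNAc-...-GlcNAc), 233 atoms, charge -5 e
glycan_torsions(ha)[1:2, ]
#>   linkage type phi  psi
#> 1       1  b13 -70 -110
#> 2       2  b14 -70 -110
```

See `vignette("cntglycan-methods")` for the models, defaults and
numerical choices, and `run_pipeline()` for the one-call
build → assemble → simulate → analyze workflow.

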