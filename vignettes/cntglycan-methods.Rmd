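---
title: "Models and methods behind cntglycan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cntglycan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntglycan)
```

# Scope

`cntglycan` models the adsorption of glycosaminoglycan building blocks
(GlcA, GlcNAc, GalNAc) and of hyaluronan/chondroitin decamers on
carboxyl-functionalized carbon nanotubes (fCNT), and provides the full
trajectory-analysis suite such a study needs: cylindrical radial density
profiles, monolayer metrics, orientation-side classification, detachment
events, geometric hydrogen-bond counting, Lennard-Jones/Coulomb pair
energies, torsional free-energy maps, RMSF and ring puckering.  It does
*not* run molecular dynamics: a seeded synthetic-trajectory generator
with known ground truth stands in for production MD, so every analysis
stage is testable end to end.

# Nanotube construction

A zigzag $(n,0)$ tube is built by rolling graphene: lattice constant
$a = \sqrt{3}\,a_{cc}$, radius $r = \sqrt{3}\,n\,a_{cc}/(2\pi)$,
translational period $T = 3 a_{cc}$ with $4n$ carbons per cell.  All
atoms lie exactly on the ideal cylinder; bonds, angles and dihedrals are
generated from a brute-force neighbor search (1.6 &#8491; cutoff) and
wrap across the periodic z boundary with explicit periodic flags.

The default C&ndash;C distance is $a_{cc} = 0.1417143$ nm.  It was
chosen once so that the 14-cell period of the (17,0) tube equals the
5.952 nm box edge exactly ($3 a_{cc} \cdot 14 = 5.952$ nm); it is within
0.3% of the graphite value and configurable through `lattice_spec()`.

## Carboxyl grafting and charge bookkeeping

Each carboxyl group (protonated COOH or deprotonated COO&#8854;)
rehybridizes its anchor carbon from sp&#178; to sp&#179;; one bonded
neighbor is rehybridized too and receives a hydrogen, conserving
valence.  Anchors are drawn without replacement (seeded), at least 3
bonds apart &mdash; the source of the motif geometry is silent on
adjacent anchors, and fused motifs would break the valence bookkeeping,
so a minimum separation is imposed and configurable.

Motif partial charges are a *configuration block*
(`motif_charge_set()`): the study this package emulates published them
only in a figure, so shipped defaults are plausible values whose group
sums are deliberately non-integral.  `redistribute_residual_charge()`
then spreads the residual uniformly over wall carbons outside the
motifs, making the total exactly $-1\,e$ per carboxylate (0 per acid) to
machine precision.  Spreading over non-motif carbons (rather than all
carbons) preserves the configured motif charges verbatim; the integral
net charge is identical either way.

Finite hydrogen-capped $(10,0)$ clusters (`build_capped_cluster()`)
follow the closed form $2n \cdot \mathrm{rings}$ wall carbons $+ 2n$
capping hydrogens $+$ 4 (carboxylate) or 5 (acid) motif atoms: 164 and
165 atoms for the 7-ring clusters.

# Glycan models

Pyranose rings are ideal $^4C_1$ chairs: six ring atoms (O5, C1..C5) at
60&deg; steps with alternating out-of-plane displacement, giving a
uniform ring bond of 1.50 &#8491; (between the C&ndash;C and C&ndash;O
values; the analyses are insensitive to this idealization).
Substituents sit on ideal tetrahedral directions; axial vs equatorial is
decided geometrically, which is what distinguishes GalNAc (axial O4)
from GlcNAc.  GlcA carries a deprotonated carboxylate ($-0.5\,e$ on each
oxygen, formal charge $-1$).

Decamers alternate GlcA and the hexosamine through
$\beta(1\!\to\!3)$/$\beta(1\!\to\!4)$ linkages.  Each linkage is placed
by natural-extension geometry so that the IUPAC torsions
$\varphi = \mathrm{O5\!-\!C1\!-\!O1\!-\!C'_n}$ and
$\psi = \mathrm{C1\!-\!O1\!-\!C'_n\!-\!C'_{n-1}}$ start at
$(-70&deg;, -110&deg;)$, a syn-region value; the analyses resample the
torsions anyway, so the exact start only needs to be a valid syn
conformation.  The built geometry is an idealized template: local
sterics between bulky substituents of adjacent residues are not relaxed
(there is no force-field minimization in scope).

Each residue exposes two faces used by the orientation analysis: side A
= \{H1, H5\}, side B = \{H2, H4\} (\{H2, O4\} for GalNAc).  The
reported statistic uses exactly these pairs; an extended side-A set
including H3 is available for robustness but is not the default.

# Box assembly

`assemble()` centers the tube on the z axis, places glycan copies at
seeded random poses with no interatomic distance below 2 &#8491;
(minimum image), and inserts $\mathrm{round}(c\,N_A V)$ Na&#8314;/Cl&#8315;
pairs at ionic strength $c$ (default 0.15 mol/L) plus neutralizing
counterions, so the box charge is exactly zero.  Explicit water is never
placed: no analysis in this package touches water coordinates, and the
typical water content of the emulated boxes is recorded as metadata
only.  The number of monosaccharide copies per box is configurable
(default 20 in `study_manifest()`; the emulated study never prints it).

# The synthetic-trajectory generator

The generator defines the study conditions for all tests:

* **Adsorption/desorption** is a two-state Markov chain per molecule
  (per-frame switching probabilities), reflecting the spontaneous
  detachment/re-adsorption events such simulations show.
* **Adsorbed poses** put the molecule's center at
  $r \sim N(r_\mathrm{tube} + 4\,\text{&#8491;}, 0.8\,\text{&#8491;})$,
  truncated so that *every atom* stays inside the 15 &#8491; monolayer
  bound (set `r_max_adsorbed = Inf` to lift this, e.g. for decamers,
  which wrap no surface in this rigid emulation).  The chosen face
  (A, B, or isotropic) points toward the axis with wrapped-Gaussian
  angular noise (default 10&deg;).  Poses are pushed outward if needed
  so no atom penetrates the outermost fCNT atom radius minus contact
  distance &mdash; poses are rigid, not energy-relaxed, and this bound
  keeps steric overlap (hence pair energies) finite and contact-scale.
* **Desorbed poses** place the center uniformly beyond 20 &#8491;.
* **Glycosidic torsions** are resampled every frame (nominally 200 ps
  apart, hence decorrelated) from a wrapped-normal basin mixture
  (`torsion_surface_spec()`), applied exactly by rotating everything
  downstream of each linkage.
* **Thermal noise** is isotropic per-atom Gaussian jitter (default
  0.3 &#8491;; 0.5/0.25 &#8491; in the fluctuation calibrations).

What this emulates well: radial layer statistics, facial orientation
statistics, detachment kinetics, torsion-basin populations, fluctuation
magnitudes.  What it does not: water structure, energy-consistent
sampling, correlated internal dynamics, realistic contact energetics.
Passing tests therefore validate the *analyses* (and the builders'
bookkeeping), not any physical prediction about real adsorption.

# Analyses: numerical choices

* **Radial profiles** are raw counts (not volume-normalized) in
  0.5 &#8491; bins, matching the "number of counts" convention of the
  emulated figures; counts conserve atoms &times; frames.
* **Orientation** takes the first local maximum of each 3-bin-smoothed
  face profile that exceeds 5% of the global maximum; the side with the
  smaller first-peak radius wins, and separations below 1 &#8491; are
  `indeterminate`.
* **Detachment** uses the ring-atom center of geometry, a strict
  20 &#8491; threshold and a 3-frame minimum run length.
* **Pair energies** use Lorentz-Berthelot mixing, a plain 1.2 nm
  cutoff and $f = 138.935458$ kJ mol$^{-1}$ nm e$^{-2}$; there is no
  reciprocal-space term (a deliberate deviation from PME-based engines
  that shifts absolute Coulomb values).  Uncertainties are standard
  errors of 5 block means.  Pairs closer than 0.5 &#8491; are flagged
  but still scored.
* **Hydrogen bonds**: acceptor-donor distance $< 3$ &#8491; *and*
  acceptor-donor-H angle $< 20&deg;$, both strict, with the angle taken
  at the donor heavy atom between D&rarr;A and D&rarr;H &mdash; the
  standard small-angle reading of this criterion.  The carboxylate
  participates as acceptor only; the acid also donates through its O-H.
* **Free-energy maps**: 5&deg; periodic bins,
  $F = -k_BT \ln(P/P_{max})$ at 310 K, empty bins capped at
  $\max F + k_BT$.  Basin gaps are read from 3&times;3 bin windows
  around the basin centers to suppress single-bin shot noise.
* **Conformer windows** (the emulated study names classes without
  windows): syn = $\psi$ within &plusmn;60&deg; of the built canonical
  $-110&deg;$, anti = the same around $+70&deg;$, quasi-trans =
  $180&deg; \pm 30&deg;$ reported separately because it overlaps anti.
* **RMSF** superposes each frame on the mean structure by default
  (two Kabsch passes), removing rigid diffusion; a no-fit mode exists
  because the emulated study does not state whether it fitted.
* **Ring pucker** uses Cremer-Pople $(Q, \theta, \varphi_p)$: chair for
  $\theta < 45&deg;$ or $> 135&deg;$, boat when $\varphi_p$ is within
  15&deg; of a multiple of 60&deg;, skew-boat otherwise, undefined below
  $Q = 0.1$ &#8491;.

# Problem sizes

The shipped tests and the acceptance script run the full-size (17,0)
tube only for construction bookkeeping (it builds in well under a
second) and use an (8,0) three-cell tube with a handful of molecules
for trajectory work; statistical checks use 2,000-10,000 frames and
50,000 torsion samples.  These sizes give standard errors comfortably
below the asserted tolerances while keeping a laptop-scale run time.

# Known limitations

* Glycan templates are idealized: uniform ring bonds, unrelaxed
  inter-residue sterics, no exo-anomeric modeling.
* Pair energies are cutoff-truncated; absolute Coulomb values are not
  comparable to Ewald-based numbers.
* The generator's decamer poses are rigid (principal axis along the
  tube); real decamers wrap the tube.
* Armchair/chiral tubes, multi-walled tubes, sulfated chondroitin and
  alpha anomers are out of scope.
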