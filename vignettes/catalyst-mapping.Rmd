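---
title: "Mapping dirhodium(II) catalyst space from steric and electronic descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dirhodium(II) catalyst space from steric and electronic descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodmap)
```

## The problem and the model

Dirhodium(II) paddlewheel complexes (Rh₂L₄) catalyse carbene-transfer
reactions whose outcome — which C–H bond is functionalised, which of several
cyclisation products forms, and in what yield — depends strongly on the
bridging ligands. Mechanistic prediction is hard because ligand changes can
redirect whole reaction pathways, so `rhodmap` takes the opposite,
mechanism-agnostic approach: describe every catalyst by a fixed panel of
steric and electronic descriptors computed from its own structures, and let
dimensionality reduction reveal the layout of catalyst space. Catalysts that
sit near each other on the map are expected to behave similarly; clusters of
high-performing catalysts in a screen then point at the region worth
exploring.

Each catalyst is represented by two externally optimised structures: the
unbound complex **1** and a carbene complex **2** formed from a symmetric
acceptor–acceptor (malonamide-type) diazo precursor, which acts as a
reporter fragment. The 14 descriptors divide into electronic terms from the
quantum-chemistry sidecar (HOMO, LUMO, their gap, the mean Rh charge, the
mean summed ligand charge), mixed geometric/electronic terms measured off
the structures (Rh–Rh distance in **1** and **2**, mean Rh–Rh–donor angle in
**1** and **2**, mean bite angle in **1**, carbene C–C–C angle in **2**, and
the carbene coordination energy ΔE(coord)), and two purely steric terms
(the distance-weighted volume |wV| and the He₈ probe energy), both computed
on the geometry of **2** with the carbene deleted so they describe the
axial pocket an incoming substrate actually sees.

Descriptor values feed a Pearson correlation map (to expose redundancy: in
real paddlewheel data the Rh–Rh distance and the Rh–Rh–donor angles are
strongly coupled through scaffold rigidity, while |wV| stays nearly
orthogonal to everything) and a PCA. Scores place catalysts on the map;
loadings say which physical quantities each component mixes; explained
variance and the mean squared projection loss say how faithful the
low-dimensional picture is.

## Assumptions

* The inputs are trusted: geometries are optimised minima and the sidecar
  quantities (total energy, orbital energies, partial charges) were computed
  consistently across the whole catalyst set, at one level of theory. The
  package never judges the level of theory, and the charge-partition scheme
  is deliberately unspecified — it is recorded as free-text provenance,
  because mixing schemes across catalysts would silently corrupt the charge
  descriptors.
* The complex actually is an Rh₂L₄ paddlewheel: exactly two Rh atoms, four
  bridging bidentate ligands, at most one axial fragment bound through
  carbon. Everything else is rejected with explicit topology errors rather
  than guessed; a YAML override document covers genuinely unusual ligands
  (e.g. tethered bis-carboxylates that bridge as one connected component —
  chemically one ligand with two donor pairs — which perception reports as
  a bridging-component count of fewer than 4).
* Descriptor comparability across catalysts matters more than absolute
  accuracy of any single descriptor; all derived energies therefore use one
  pinned conversion constant (1 a.u. = 627.5094740631 kcal mol⁻¹) and no
  zero-point or thermal corrections, mirroring how the underlying electronic
  energies are produced.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bond_scale` | 1.2 | – | covalent-radius sum multiplier for bond perception; the standard heuristic. The Rh–Rh bond is asserted regardless, since the scaffold guarantees it. |
| `wv_k`, `wv_l` | 3, 3 | – | exponents of \|wV\| = Σ rᵢᵏ/dᵢˡ; cubic weighting makes both numerator and denominator volume-like, so the sum reads as a distance-damped occupied volume. Bondi van der Waals radii are used. Both exponents are recorded in the descriptor CSV metadata so a database always documents its own convention. |
| `he8_distance` | 1.9 | Å | ring-centre distance from the carbene-binding Rh, on the axial face: just above the region the carbene occupied, where an approaching substrate first meets the ligand shell. |
| `he8_radius` | 2.5 | Å | He-ring radius; places the ring over the ligand walls of the axial pocket rather than on the axis. Configurable and recorded. |
| `pca_components` | 3 | – | retained components for the map; the first two give the main map, the third resolves structure within the two big ligand families. |

The He₈ ring phase (rotation about the axis) is physically irrelevant to a
subsequent single-point energy but matters for byte-reproducible geometry
output, so it is pinned deterministically: He #1 lies along the in-plane
projection of the donor atom nearest the carbene-binding Rh, with exact
symmetry ties broken by atom index (distances are rounded to 10⁻⁶ Å before
ordering so that floating-point noise cannot flip the tie under rigid
motion).

## Numerical and convention choices

* **Q(Rh)** is the *mean* of the two Rh partial charges, not the sum, so the
  value reads as a single-centre charge.
* **∡(Rh–Rh–L)** averages all 8 donor attachments over both metal centres.
* **Bite angle** uses, per ligand, the unique ligand atom bonded to both
  donors (the carboxylate/amidate bridgehead); its absence is a topology
  error, not a silent skip.
* **Donor ambiguity**: an atom within bonding distance of both Rh is
  assigned to the nearer one, ties to the lower index.
* **Standardization before PCA** is per-descriptor z-scoring (n − 1
  denominators). The descriptors mix Å, degrees, a.u., e and kcal mol⁻¹, so
  correlation-matrix PCA is the only defensible default; `pca_fit()` also
  offers a centring-only mode for data already on one scale.
* **PCA sign convention**: each loading column is flipped so its
  largest-magnitude entry is positive; signs are otherwise arbitrary and
  would destroy reproducibility of scores files.
* **Projection loss** is the mean squared reconstruction error on the
  standardized scale — the only scale on which a single unit-free scalar is
  meaningful.
* **Screening-set selection** is greedy maximin in score space (start
  farthest from the centroid, then repeatedly add the point maximizing the
  minimum distance to the chosen set, ties by input order). Greedy maximin
  carries the classical factor-2 guarantee against the optimal spread, is
  deterministic, and — unlike the exact optimum — is practical at any k.
* **Angles** clamp cosines to [−1, 1] before `acos` and refuse zero-length
  vectors rather than returning NaN.
* **Degenerate inputs**: constant descriptor columns are a validation error
  naming the descriptor (a constant cannot be z-scored and carries no
  mapping information); geometries with duplicate atoms (< 0.1 Å) are
  rejected at construction.

## The synthetic data generator

No reference structures ship with the package, so the fixture module
generates them. `build_paddlewheel_fixture()` places an exact D4-symmetric
paddlewheel: two Rh on the z axis at the declared separation, four bridging
ligands at 90° azimuth intervals whose donors sit at a fixed 2.04 Å Rh–donor
distance with a declared tilt out of the perpendicular plane, and a
bridgehead solved from the declared bite angle (the resulting C–O distance,
≈ 1.38 Å, is derived rather than pinned — only declared parameters are ever
asserted). Three ligand scaffolds vary the steric profile: a bare
carboxylate (3 atoms), an N,O-carboxamidate with a methyl substituent, and a
bulky carboxylate carrying a tert-butyl-like cap that intrudes over the
axial face. The optional malonamide-like carbene (9 atoms) is built with a
declared C–C–C angle, its plane set between ligand azimuths and its
amide arms pointing away from the complex; beyond ≈ 160° the carbonyl
oxygens would chelate the metal, so the builder restricts the carbene angle
to [100°, 160°] — the chemically relevant window anyway. The builder
returns its own connectivity and topology as ground truth, which is what
the perception and descriptor tests assert against (recovery to 10⁻⁹ over
randomized rigid transforms).

`synthetic_properties()` adds sidecars that are deliberately *not* physical:
HOMO/LUMO near typical closed-shell values, Rh charges near +0.5 e, overall
neutrality — enough to exercise every code path deterministically from a
seed. `synthetic_aux_energies()` back-solves the He₈ triple and the
ΔE(coord) partners from target interaction energies (repulsive He₈ probe,
exothermic carbene formation), so the assembled descriptors land in
plausible ranges. `simulate_descriptor_table()` generates descriptor
matrices with a *declared* latent covariance (orthonormal loadings, chosen
eigenvalues, isotropic noise) for testing the statistical layer against
analytic expectations.

What passing tests therefore show: the geometry, perception, probe and
assembly machinery is exact on idealized structures, and the statistical
machinery recovers known covariance structure at realistic sample sizes.
What they do not show: behaviour on DFT-quality geometries (symmetry broken,
ligand conformers, secondary interactions), real charge schemes, or real
descriptor distributions — a real application still needs externally
computed structures and sidecars.

## Problem sizes

The test-suite and acceptance computations use: 20 randomized rigid
transforms per geometric-recovery check; 50 random 6×4 matrices for the
PCA-vs-eigendecomposition oracle; n = 5000 samples (20 seeds) for latent
eigenvalue-fraction recovery of the (4, 1) two-variable model, where equal
column variances make the standardized PC1 fraction analytically 0.8;
exhaustive subset enumeration up to 8 points for the maximin guarantee; and
a 48-catalyst synthetic database (two geometries each) for the end-to-end
map, in which the donor tilt is coupled to the Rh–Rh stretch to emulate the
rigid-scaffold correlation seen in real paddlewheel data. These sizes were
chosen so each statistical assertion sits several standard errors inside
its band.

## Known limitations

* Perception covers the Rh₂L₄(+carbene) motif only; axial solvent or
  counterion fragments are rejected, not modelled, and tethered
  bis-carboxylates need a manual topology document.
* The He₈ descriptor requires three external single-point energies; the
  package emits the geometries and decks but does not evaluate energies
  itself (no force field or QM engine inside), so a database build is a
  two-pass workflow.
* The |wV| exponents, radius table, He₈ ring radius and charge scheme are
  conventions, not uniquely determined truths; results are only comparable
  within a database built under one recorded configuration.
* PCA is descriptive, not inferential: component meanings are read from the
  loadings and should not be over-interpreted; the map supports selection
  and visualisation, not yield prediction.
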