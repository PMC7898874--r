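# rhodmap

Descriptor computation and chemical-space mapping for dirhodium(II)
paddlewheel catalysts.

Rh₂L₄ paddlewheel complexes — two rhodium atoms bridged by four bidentate
carboxylate (*O*,*O*) or carboxamidate (*N*,*O*) ligands — catalyse a very
wide range of carbene-transfer chemistry (C–H insertion, cyclopropanation,
ylide formation), and the reaction outcome is often decided by which
catalyst is chosen. `rhodmap` parameterizes these catalysts independently of
any particular reaction mechanism: it computes a set of 14 steric and
electronic descriptors per catalyst from externally optimized 3D structures
and quantum-chemistry property records, assembles them into a descriptor
database, and maps the catalyst space by correlation analysis and principal
component analysis (PCA). The resulting map supports diversity-based
screening-set selection and the visualisation of experimental screening
outcomes (yield, selectivity) in catalyst space. It is aimed at
computational and synthetic chemists who run catalyst screens and want a
data-led way to choose or rationalize them.

## The descriptors

For each catalyst, two structures are used: the unbound complex **1**
(Rh₂L₄) and the corresponding carbene complex **2** (Rh₂L₄=C(R)₂ from a
donor/acceptor-free diazo precursor). The 14 descriptors are:

| descriptor | meaning | units |
|---|---|---|
| `r_rhrh_1`, `r_rhrh_2` | Rh–Rh bond length in **1** and **2** | Å |
| `ang_rhrhl_1`, `ang_rhrhl_2` | mean Rh–Rh–donor angle (all 8 attachments) | ° |
| `bite_angle_1` | mean ligand bite angle ∠(O–C–X) | ° |
| `carbene_angle_2` | carbene ∠(C–C–C) | ° |
| `homo_1`, `lumo_1`, `de_fmo_1` | frontier-orbital energies and gap | a.u. |
| `q_rh_1` | mean partial charge on the Rh atoms | e |
| `q_ligand_mean_1` | mean summed partial charge per ligand | e |
| `wv` | distance-weighted steric volume | – |
| `he8` | interaction energy with an axial ring of 8 He atoms | kcal mol⁻¹ |
| `de_coord` | carbene coordination energy | kcal mol⁻¹ |

The two purely steric descriptors are computed on the carbene-complex
geometry with the carbene removed. The distance-weighted volume sums
van-der-Waals-weighted proximity to the carbene-binding rhodium,

&nbsp;&nbsp;&nbsp;&nbsp;|wV| = Σᵢ rᵢᵏ / dᵢˡ&nbsp;&nbsp;&nbsp;&nbsp;(k = l = 3 by default),

over all ligand atoms (both Rh excluded). The He₈ probe is a ring of eight
helium atoms placed 1.9 Å from the carbene-binding Rh along the Rh–Rh axis
(ring radius 2.5 Å by default); its descriptor is the assembled interaction
energy

&nbsp;&nbsp;&nbsp;&nbsp;He₈ = E(He₈·[Rh–Rh]) − E(He₈) − E([Rh–Rh]),

from three externally computed single points on geometries the package
emits. The carbene coordination energy is

&nbsp;&nbsp;&nbsp;&nbsp;ΔE(coord) = (E(**1**) + E(diazo)) − (E(**2**) + E(N₂)),

converted with 1 a.u. = 627.5094740631 kcal mol⁻¹. Electronic descriptors
(HOMO/LUMO, charges) come from a neutral key–value "sidecar" document per
complex, so any quantum-chemistry package can feed the pipeline.

The package perceives the paddlewheel connectivity automatically (metal
axis, four bridging ligands, donor atoms, axial carbene) from covalent-radius
bond perception, with a YAML override format for unusual ligands such as
tethered bis-carboxylates.

## Worked example

Everything below runs without any quantum-chemistry data, using the built-in
synthetic fixture generator (idealized paddlewheel geometries with declared
parameters plus self-consistent synthetic sidecars):

```r
library(rhodmap)

cat_ <- make_fixture_catalyst("example", seed = 5)
rec <- compute_descriptor_record(cat_$id, cat_$geom1, cat_$props1,
                                 cat_$geom2, cat_$props2, cat_$aux)
print(rec)
#> <descriptor_record> example
#>        r_rhrh_1        r_rhrh_2     ang_rhrhl_1     ang_rhrhl_2    bite_angle_1
#>        2.450000        2.470000       88.000000       87.000000      125.000000
#> carbene_angle_2          homo_1          lumo_1        de_fmo_1          q_rh_1
#>      118.000000       -0.225090       -0.089325        0.135765        0.535796
#> q_ligand_mean_1              wv             he8        de_coord
#>       -0.267898        2.922386        6.772945      -27.107556
```

The geometric entries reproduce the fixture's declared parameters exactly
(Rh–Rh 2.45/2.47 Å; donor tilts of 2°/3° give mean angles 88°/87°; bite
125°; carbene 118°); `de_fmo_1 = lumo_1 − homo_1`; `wv` and `he8` are the
steric terms described above. A small database then maps the catalysts:

```r
lib <- fixture_library(seed = 42)
recs <- lapply(lib, function(x)
  compute_descriptor_record(x$id, x$geom1, x$props1, x$geom2, x$props2, x$aux))
m <- assemble_matrix(unname(recs))
model <- pca_fit(m, n_components = 3)
print(model)
#> <pca_model> 3 components over 14 descriptors, 6 catalysts
#> explained variance: 38.5%, 26.0%, 20.2% (cumulative 84.6%); projection MSE 0.1284

select_screening_set(model, k = 3)
#> [1] "syn-amidate-b" "syn-carbox-a"  "syn-amidate-a"
```

The screening set is a greedy maximin selection in score space: the three
catalysts that best span the mapped diversity. `overlay_outcomes()` then
joins a screening-results table (catalyst, solvent, yield, product ratio)
onto the map, drawing yield as marker size and selectivity as a diverging
colour.

## Command line

The same pipeline is scriptable through `exec/rhodmap`:

```sh
rhodmap fixtures    --out runs/demo
rhodmap descriptors --geometries runs/demo --out runs/demo
rhodmap map         --out runs/demo
rhodmap overlay     --outcomes outcomes.csv --out runs/demo
rhodmap he8-build   --geometries complex2.xyz --out runs/he8
```

Each run persists its resolved configuration and a JSON manifest beside its
outputs. `he8-build` emits the stripped complex, the isolated He₈ ring, and
the composite as XYZ files plus generic single-point input decks, ready for
the external energies the `he8` descriptor needs.

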