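# rnmap

Ramachandran numbers and multi-angle pictures for protein backbones.

A backbone residue's conformation is usually described by its dihedral pair
(φ, ψ).  The **Ramachandran number**

```
R(φ, ψ) = ((φ + ψ) − (φ_min + ψ_min)) / ((φ_max + ψ_max) − (φ_min + ψ_min))
```

collapses the pair onto a single scalar in [0, 1] along the φ + ψ
anti-diagonal of the Ramachandran plot.  The collapse is lossy but
structure-aware: α-helices land near 0.34, β-sheets near 0.52, ppII
helices near 0.60, right-twisting backbones below 0.5 and left-twisting
above.  One number per residue per frame makes it possible to draw an
entire ensemble or trajectory as a single heatmap — residues (or histogram
bins) on one axis, models on the other — with no practical limit on the
number of frames.  A **signed** variant `Rs` (negative for ψ < φ) folds
mirror-image conformations of achiral backbones together while keeping the
twist sense.

The package provides:

* the closed-form, signed, and σ-discretized Ramachandran numbers, plus
  deviation series `D1` (from the first frame) and `Dprev`
  (frame-to-frame);
* a multi-model PDB reader (MODEL/ENDMDL aware, altloc- and
  chain-break-handling) and IUPAC-convention dihedral computation;
* stackable map products: per-residue maps, per-model histogram series,
  deviation maps, and residue-type / neighbor-conditioned histogram
  stacks, all writable as CSV;
* rendering with `SecondaryStructure` and `Chirality` colormaps (PNG/SVG,
  always with a faithful CSV sidecar);
* an ideal-geometry backbone builder (internal → Cartesian), global shape
  descriptors (radius of gyration, end-to-end distance, a handedness
  proxy), binned R-trend sweeps, a PDB writer, and four synthetic
  trajectory archetypes for testing;
* a command-line interface.

## Worked example

```r
library(rnmap)

ramachandran_number(c(-57, -120, -75), c(-47, 135, 145))
#> [1] 0.3555556 0.5208333 0.5972222   # helix, sheet, ppII

# a small synthetic trajectory, written as a multi-model PDB
pdb <- make_test_trajectory("helix-to-sheet", n_res = 6, n_frames = 4, seed = 11)
tab <- read_ensemble(pdb)            # parse + dihedrals + R in one step
head(tab, 8)
#>   model chain resid ins resname   phi   psi Rsigned     R
#> 1     1     A     1         GLY    NA -43.0      NA    NA
#> 2     1     A     2         GLY -56.9 -45.2   0.358 0.358
#> 3     1     A     3         GLY -61.5 -47.1   0.349 0.349
#> 4     1     A     4         GLY -61.1 -50.1   0.346 0.346
#> 5     1     A     5         GLY -53.3 -49.6   0.357 0.357
#> 6     1     A     6         GLY -59.8    NA      NA    NA
#> 7     2     A     1         GLY    NA  11.9      NA    NA
#> 8     2     A     2         GLY -78.8  11.7   0.407 0.407

round(build_residue_map(tab, "A"), 3)   # residues x models
#>       1     2     3     4
#> 1    NA    NA    NA    NA
#> 2 0.358 0.407 0.462 0.524
#> 3 0.349 0.403 0.468 0.522
#> 4 0.346 0.411 0.456 0.518
#> 5 0.357 0.408 0.461 0.505
#> 6    NA    NA    NA    NA
```

Every interior residue migrates from the helical band (~0.35) to the sheet
band (~0.52) across the four frames; termini are `NA` because one of their
dihedrals is undefined.

The one-call pipeline renders the full product set for a PDB file:

```r
f <- tempfile(fileext = ".pdb")
make_test_trajectory("restrained-release", seed = 5, file = f)
out <- run_map_pipeline(f, out_dir = "maps")
basename(sort(out))
#>  [1] "....A.d1.csv"  "....A.d1.png"  "....A.dprev.csv" "....A.dprev.png"
#>  [5] "....A.histogram.csv" "....A.histogram.png"
#>  [7] "....A.map-chirality.csv" "....A.map-chirality.png"
#>  [9] "....A.map-secondarystructure.csv" "....A.map-secondarystructure.png"
```

The same pipeline is available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/rnmap.R", package = "rnmap"))')" \
    -p trajectory.pdb --out maps --signed
```

## Documentation

The methods vignette (`vignettes/ramachandran-number-maps.Rmd`) documents
the model and its assumptions, all numerical conventions (angle wrapping,
rounding, bin edges, torsion sign, the chirality-proxy sign convention),
the generator archetypes and their limitations, and the resolved open
questions.
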