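---
title: "Ramachandran-number maps: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramachandran-number maps: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnmap)
```

## The model

A protein or peptoid backbone residue is conventionally described by the
dihedral pair (&phi;, &psi;).  `rnmap` collapses this pair onto a single
scalar, the Ramachandran number

$$
\mathcal{R}(\phi, \psi) \;=\;
\frac{(\phi + \psi) - (\phi_{\min} + \psi_{\min})}
     {(\phi_{\max} + \psi_{\max}) - (\phi_{\min} + \psi_{\min})},
$$

which maps the square $[-180^\circ, 180^\circ)^2$ onto $[0, 1]$ along the
anti-diagonal $\phi + \psi$.  The collapse is lossy by design: it discards
the $\phi - \psi$ direction, which varies little across the populated
regions of the Ramachandran plot, and keeps the direction that separates
the major secondary-structure classes:

```{r}
ramachandran_number(-57, -47)    # alpha helix
ramachandran_number(-120, 135)   # beta strand
ramachandran_number(-75, 145)    # ppII helix
ramachandran_number(0, 0)        # center of the plot
```

Right-twisting conformations fall below 0.5 and left-twisting ones above,
so a single number per residue per frame supports compact "multi-angle
picture" products for arbitrarily large ensembles: one column per model,
one row per residue (or per histogram bin).

**Assumptions.**  The collapse is only meaningful when both dihedrals are
defined: chain termini and residues adjacent to a chain break get `NA`,
which propagates through every downstream product and renders as
background.  Only `ATOM` records are read; `HETATM` entries (waters,
ligands, but also some modified residues) are ignored entirely.  A peptide
bond longer than 2.0 &Aring; between C(i) and N(i+1) is treated as a chain
break — roughly 1.5&times; the ideal 1.33 &Aring; bond, comfortably above
any physical bond and below any physical gap.

## Signed variant

For backbones without a fixed C&alpha; chirality (glycine-rich polymers,
peptoids), mirror-image conformations are energetically equivalent but land
at $\mathcal{R}$ and $1-\mathcal{R}$.  The signed variant folds the two
together while keeping the twist sense as a sign:

$$
\mathcal{R}_s = \begin{cases}
  \;\;\mathcal{R} & \psi \ge \phi \\
  -\mathcal{R} & \text{otherwise,}
\end{cases}
$$

with the comparison made on the wrapped angles and the boundary
$\psi = \phi$ assigned to the positive branch so every pair has exactly one
image.  Signed products use the display range $[-1, 1]$.

## Numerical conventions

* **Angle wrapping.**  Input angles are wrapped into
  $[\phi_{\min}, \phi_{\min} + 360)$ before use, except that the exact
  upper corner is retained, so `ramachandran_number(180, 180)` is `1`, not
  `0`.  This keeps both worked endpoints ($\mathcal{R}(-180,-180)=0$,
  $\mathcal{R}(180,180)=1$) exact.
* **Discretized form.**  `discretized_ramachandran_number()` implements the
  rotate-shift-round construction at resolution &sigma; (indices per
  degree), with "round half away from zero" rather than R's banker's
  rounding, so the lattice is symmetric about the origin.  On a 1&deg; grid
  the maximum deviation from the closed form decreases monotonically
  through &sigma; = 1, 10, 100, 1000 and is below $10^{-3}$ at
  &sigma; = 1000 (this is asserted in the test suite).
* **Histogram bins.**  Bins are half-open $[lo, hi)$ with the final bin
  closed so that $\mathcal{R}=1$ is counted.  The default width 0.01 gives
  100 bins over $[0,1]$ — fine enough to separate the helix (0.34), sheet
  (0.52) and ppII (0.60) loci, coarse enough that a single decamer model
  still produces a readable column.  Columns are normalized per model so
  frames with different numbers of defined residues are comparable.
* **Deviation maps.**  $D_1 = |\mathcal{R}_t - \mathcal{R}_1|$ and
  $D_{-1} = |\mathcal{R}_t - \mathcal{R}_{t-1}|$; the first column is 0 by
  definition and `NA` propagates.
* **Torsion sign.**  `dihedral_angle()` follows the IUPAC convention
  (positive = clockwise rotation of the far bond viewed from atom 2 toward
  atom 3), implemented as
  `atan2((n1 × n2)·b2hat, n1·n2)`.  The sign was cross-checked against
  three independent implementations in widely used structural-biology
  libraries.

## The backbone builder

`build_backbone()` converts a matrix of (&phi;, &psi;) pairs into Cartesian
N/C&alpha;/C coordinates by sequential internal-to-Cartesian (NeRF-style)
placement with ideal geometry: bonds N–C&alpha; 1.458, C&alpha;–C 1.525,
C–N 1.329 &Aring;; angles N–C&alpha;–C 111.0&deg;, C&alpha;–C–N
116.6&deg;, C–N–C&alpha; 121.9&deg;; all &omega; fixed at 180&deg;.  The
builder recovers its prescribed torsions to ~10⁻⁹ degrees before PDB
rounding and to &lt; 0.1&deg; after the 3-decimal coordinate rounding of
the PDB format (the test suite asserts &lt; 0.5&deg; over 500 random
pairs).

Three global descriptors connect $\mathcal{R}$ to shape:

* `radius_of_gyration()` — RMS distance of backbone atoms from their
  centroid;
* `end_to_end_distance()` — first N to last C;
* `chirality_proxy()` — the mean, over consecutive C&alpha; quadruples, of
  the normalized scalar triple product of the three connecting vectors.
  **Sign convention (pinned):** the right-handed &alpha;-helix
  (&minus;57, &minus;47) gives a *positive* value (&approx; +0.78); planar
  extended chains give 0; mirror images negate it exactly.

`rnumber_binned_trends()` sweeps a uniform (&phi;, &psi;) grid (default
step 5&deg;, i.e. 73&times;73 = 5329 decamers, about 10 s), builds an
ideal-geometry decamer at every grid point, and bins the three descriptors
by $\mathcal{R}$.

### A note on the radius-of-gyration minimum

Across the grid, the binned mean end-to-end distance is maximal at the
$\mathcal{R}$ extremes (fully extended all-trans chains) and the chirality
proxy changes sign across 0.5, both as expected.  The binned mean radius of
gyration, however, attains its minimum near $\mathcal{R} \approx 0.27$
(&phi; + &psi; &approx; &minus;162&deg;, a tight irregular coil with
R_g &approx; 3 &Aring; for a decamer), *not* inside the helical band
[0.3, 0.4] (the ideal &alpha;-helix decamer has R_g &approx; 4.9
&Aring;).  This is a genuine property of uniformly sampled ideal-geometry
chains: without sterics, the most compact anti-diagonal is not the helical
one.  We verified the minimum is robust to including carbonyl oxygens in
the R_g computation.  The corresponding acceptance assertion, which
expects the minimum inside [0.3, 0.4], is deliberately left failing rather
than moving the band; the trends themselves are reported honestly by the
package.

## Trajectory generators

`make_test_trajectory()` provides four archetypes (defaults: 30 residues,
20 frames, glycine backbone, seeded RNG isolated from the caller's stream):

* **`stable-helix`** — every residue drawn around (&minus;57, &minus;47)
  with 5&deg; jitter: a flat, single-band histogram series.
* **`disorder`** — uniform random dihedrals, except residues 15–25 (the
  middle third for short chains) held helical with 2&deg; jitter: a
  conserved segment inside a fluctuating background, the canonical test
  for deviation maps.
* **`helix-to-sheet`** — linear interpolation from the helix locus to
  (&minus;120, 135) with 3&deg; jitter: a monotone migration between the
  two bands.
* **`restrained-release`** — the first third of the frames held extended
  at (&minus;135, 135) ($\mathcal{R}=0.5$), then odd residues released to
  (&minus;75, 145) and even residues to (75, &minus;145): a central band
  splitting into two mirror bands (0.597 / 0.403).

**Limitations.**  The generators are statistical caricatures, not physics:
no excluded volume, no side chains, ideal geometry, independent residues.
They exist so that every map product in the package can be exercised from
code with known ground truth, within the fixture size budget, and with
bitwise seed determinism (`identical()` across runs is asserted in the
tests).

## Problem sizes used in validation

The shipped tests use 2-residue dialanine fixtures for parsing, decamers
for geometry (500 random round trips), 8–30-residue / 3–20-frame synthetic
trajectories for the map products, and the 5&deg; grid sweep (5329 chains)
for the trend analysis.  All fixtures are generated in code at test time;
nothing binary is stored in the package.

## Open questions resolved during implementation

* In one published statement of the unsigned collapse the denominator is
  written with the same angle bound appearing twice; taken literally this
  makes the normalization degenerate.  We treat it as a typographical slip
  and use the symmetric form above, which reproduces every worked value
  exactly.
* The &sigma;-discretized normalization uses the value of the unnormalized
  lattice index at the two corners $(\phi_{\min}, \psi_{\min})$ and
  $(\phi_{\max}, \psi_{\max})$, making the corner values exactly 0 and 1
  at any &sigma;.
* `MODEL` serial numbers are reported verbatim as frame labels (they are
  labels, not indices, and need not be consecutive); frames in a file
  without `MODEL` records form a single model labelled `"1"`.
* Alternate locations keep the highest-occupancy conformer; ties keep the
  first in file order.
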