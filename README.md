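# pnthelix

Steered self-assembly and chirality analysis of diphenylalanine (FF)
peptide nanotubes, in R.

Diphenylalanine dipeptides self-assemble into helical peptide nanotubes
whose screw sense inverts relative to the monomer chirality: L-FF monomers
tend to form right-handed (D) tubes, D-FF monomers left-handed (L) tubes.
`pnthelix` is a desk-scale, fully reproducible replica of the computational
workflow behind that observation, for computational structural biologists
and methods developers who want to study or extend it:

* **Structure builders** — a 43-atom zwitterionic FF unit from an idealized
  internal-coordinate template (L or its exact mirror D), linear chains
  (24 units × 43 atoms = 1032 by default), and parametric helices
  (6 units per turn, tangentially tilted units).
* **MD manipulator** — a reduced-model steered MD engine (Rcpp core):
  velocity-Verlet, harmonic bonds/angles restrained to the template, soft
  non-bonded repulsion, four kinds of staged Hooke-spring scaffolds
  (NH3–CO2 contacts, inner/outer diameter, helix pitch), and a collisional
  thermostat (random elastic collisions with virtual particles, Maxwell at
  300 K, rate λ).  All randomness is counter-based: trajectories are
  bitwise reproducible from the seed, and a mirrored run with mirrored
  collision impulses is the bitwise mirror of the original.
* **Chirality indices** — the Calpha mixed-product index
  `X_total = Σ (V_i, V_{i+1}, V_{i+2})` over support vectors joining
  consecutive alpha carbons, its per-triple normalization `chi_norm`
  (exponent k = 5), and the dipole-moment index
  `c_total = Σ (D_i, D_{i+1}, D_{i+2})` with `c_norm = c_total / D_av^3`,
  where each `D_i` is the unit dipole about its centre of mass.  Sign
  convention: positive = right-handed = D, negative = left-handed = L.
* **Geometry & statistics** — principal-axis fitting, atom-to-axis radial
  statistics, reflection-free pair-fit superposition, cylindrical surface
  maps, windowed chirality profiles, and many-run sign statistics in the
  shape of the published 32-run table (shipped as a checksummed fixture).

See `vignettes/pnthelix-methods.Rmd` for the model, its assumptions, and
the package's deliberate reductions (no full force field, no
quantum-chemical charges).

## Worked example

```r
library(pnthelix)

# a right-handed 24-unit FF helix (4 turns of 6 units)
h <- build_parametric_helix(build_ff_unit("L"), HelixParams(n_units = 24))
calpha_chirality(h, CalphaChiralityParams(window = 12))
#> ChiralityReport
#>   x_total  49.0718
#>   chi_norm 0.0161619
#>   sign     D
#>   profile  37 windows, mixed fraction 0.00 (D)
radial_stats(h)
#> RadialReport: mean 8.723 A (min 0.729, max 16.819, layer 16.090), 1032 atoms
```

`x_total > 0` classifies the helix as right-handed (D); every one of the 37
sliding windows agrees (mixed fraction 0), and the mean atom-to-axis radius
is 8.7 Å for the 9 Å target helix.  Mirroring the structure negates
`x_total` exactly.

Aggregating the packaged transcription of the published 32-run series for
L-FF monomers:

```r
tab <- table1_runs()
stats_table(tab[tab$monomer == "L", ])
#> formula: 6 left (19%), 26 right (81%)
#> expert:  7 left (22%), 25 right (78%)
```

i.e. 26 of 32 runs from L monomers came out right-handed by the sign rule.

A full steered-assembly run (about 100 s for the published 80 ps schedule
plus 30 ps relaxation at 1032 atoms):

```r
chain    <- build_linear_chain("L", 24, 10)          # 1032 atoms
scaffold <- build_scaffold(chain, HelixParams(n_units = 24))
res      <- run_assembly(chain, scaffold, SpringSchedule(),
                         ThermostatParams(seed = 11), IntegratorParams())
calpha_chirality(res$final)$sign_label
```

## Command line

The `exec/pnthelix` script exposes the same workflows:

```sh
pnthelix build chain --chirality L --units 24 --gap 10 --out chain.pdb
pnthelix build helix --handedness right --units 24 --per-turn 6 --out helix.pdb
pnthelix chirality calpha helix.pdb --k 5 --window 12
pnthelix chirality dipole helix.pdb --charges charges.tsv
pnthelix geometry radius helix.pdb
pnthelix geometry map helix.pdb --bins "30 15" --out map.tsv
pnthelix stats table runs.tsv
pnthelix pipeline --runs 8 --base-seed 7 --stage-ps 10 --out-dir out/
```

`pipeline` builds the chain, runs the batch (seeds `base-seed + 0..n-1`, so
realizations differ only in the thermostat's collision sequence), scores
each final structure, and writes per-run PDBs plus a table-shaped summary;
`--mirror` repeats the experiment with D monomers and mirrored impulses,
negating the chirality column exactly.

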