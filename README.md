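# sahdna

Quantitative analysis of DNA-binding single alpha-helix (SAH) domains.

Some proteins bind DNA not through a folded domain but through a long,
solvent-exposed single alpha-helix stabilized by intrahelical i,i+3 / i,i+4
salt bridges. The KER region of chromatin assembly factor 1 (CAF-1) — a
lysine/glutamic-acid/arginine-rich helix of ~90 residues in the yeast Cac1
subunit — is the motivating example: monomers with a ~20 bp footprint add
cooperatively to a DNA fragment, producing EMSA band ladders whose band
count scales with DNA length, and giving CAF-1 its selectivity for
tetrasome-length (≥40 bp) DNA. `sahdna` is for biochemists and structural
biologists who need to turn the raw measurements of such a system — gel band
intensities, CD traces, atomic coordinates, sequences — into the numbers
that characterize it.

## What it computes

* **Cooperative binding fits** (`fraction_bound`, `fit_hill`,
  `aggregate_replicates`): EMSA lane intensities → fraction bound → Hill
  isotherm
  `f([P]) = Bmax·[P]^h / (K_D^h + [P]^h)`
  by bounded Levenberg–Marquardt least squares, with standard errors,
  nested fixed-`h`/fixed-`Bmax` fits and replicate statistics.
* **Competition DNA-ladder selectivity** (`normalize_free_dna`,
  `kdapp_per_fragment`, `c50`, `selectivity_slope`, `compare_constructs`,
  `analyze_ladder`): per-fragment free-DNA depletion → apparent K_D and C50
  with right-censoring of inert fragments, the 40→50 bp selectivity slope
  (nM/bp), and one-way ANOVA comparisons across constructs.
* **Circular dichroism** (`mre`, `fractional_helicity`,
  `subtract_dna_signal`, `fit_melt`, `melt_shift`): mean residue
  ellipticity, helix content by the 222 nm method (coil/helix references
  −3000 / −39000 deg·cm²·dmol⁻¹), DNA-signal subtraction, and two-state
  van't Hoff thermal-melt fits with cooperative vs non-cooperative
  classification.
* **SAH sequence patterns** (`sliding_net_charge`, `predict_ion_pairs`,
  `helical_face_bias`): sliding-window net charge (window 7, assigned to the
  central residue), ion-pair networks, and helical-wheel charge-face bias.
* **Helix geometry** (`read_structure`, `helix_axis`, `measure_geometry`,
  `pairwise_rmsd`): length, turns, per-residue curvature and curved-region
  detection from C-alpha coordinates (PDB/mmCIF), and Kabsch superposition
  RMSD between copies.
* **Synthetic data** (`lattice_config`, `lattice_partition`,
  `simulate_titration`, `render_emsa`, `render_emsa_ladder`, `simulate_cd`,
  `simulate_melt`, `generate_helix`, `generate_sah_sequence`): an exact
  finite-lattice cooperative-binding simulator (non-overlapping 20 bp
  footprints, nearest-neighbor cooperativity ω, transfer-style recursion
  validated against enumeration) plus CD/melt/helix/sequence generators, so
  every stage is testable against known ground truth.

See `vignettes/sah-dna-binding.Rmd` for the models, assumptions, defaults
and numerical choices.

## Worked example

Simulate a 40 bp EMSA titration from the lattice model and fit it:

```r
library(sahdna)

cfg <- lattice_config(L_bp = 40, footprint_bp = 20, K_assoc_per_nM = 1/600,
                      omega = 5, conc_grid_nM = c(0, 5, 10, 20, 40, 80, 160, 320))
lanes <- render_emsa(simulate_titration(cfg), noise_model(cv = 0.05, seed = 42))
head(lanes[, -1], 4)
#>   protein_conc_nM background    free complex1 complex2
#> 1               0          0 1069.61     0.00     0.00
#> 2               5          0  826.09   148.24     0.26
#> 3              10          0  752.60   276.11     0.91
#> 4              20          0  604.41   459.56     3.48

fit <- fit_hill(fraction_bound(lanes, mode = "bound-over-total"))
fit
#> hill_fit: K_D = 30.07 nM (se 2.18), h = 0.939 (se 0.0447), Bmax = 1.03 (se 0.0253)
#>   rss = 0.0007128 over n = 8 points; converged: TRUE
```

The recovered dissociation constant (~30 nM) sits in the range measured for
isolated KER domains; the free band plus two shifted complexes reflect the
two 20 bp footprints a 40 bp fragment can hold.

The competition-ladder analysis on the default generator (10–50 bp fragments
at 1 nM, shared titration, footprint 20 bp):

```r
res <- analyze_ladder(render_emsa_ladder(noise = noise_model(cv = 0.05, seed = 7)))
res$kdapp_summary
#>   construct fragment_bp mean_kdapp_nM sd_kdapp_nM n_censored n
#> 1        wt          10            NA          NA          3 3
#> 2        wt          20     51.576196   3.3977870          0 3
#> 3        wt          30      3.200692   0.6779847          0 3
#> 4        wt          40      2.950781   1.0742983          0 3
#> 5        wt          50      3.500552   0.1074354          0 3
```

The 10 bp fragment cannot accommodate a 20 bp footprint and is censored
(never depleted); the 20 bp fragment holds exactly one monomer and reports
the intrinsic ~50 nM K_D; longer fragments offer many binding registers and
a second site, so their apparent K_D drops sharply — the length-selectivity
signature the ladder assay is designed to read out.

Geometry of an ideal SAH-length helix:

```r
measure_geometry(generate_helix(86))
#> geometry_report [ideal-helix chain A]: 86 residues
#>   end-to-end 127.6 A, axis arc 127.5 A, 23.89 turns (mean twist 100.00 deg/res)
```

A command-line wrapper over the same functions is installed at
`inst/scripts/sah.R` (`Rscript sah.R emsa-fit --lanes lanes.tsv`, `ladder`,
`cd-melt`, `seq-charge`, `geometry`, `sim-*`, ...).

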