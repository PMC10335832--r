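---
title: "Methods: quantifying DNA binding by single alpha-helix domains"
author: "sahdna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DNA binding by single alpha-helix domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahdna)
```

# Scope

`sahdna` implements the quantitative analyses used to characterize a
DNA-binding single alpha-helix (SAH) domain, of which the KER region of the
chromatin assembly factor 1 (CAF-1) large subunit (yeast Cac1, residues
~136–225) is the motivating example: cooperative binding fits of EMSA
titrations, competition DNA-ladder selectivity analysis, circular dichroism
(CD) helicity and thermal-melt analysis, SAH sequence-pattern analysis, and
helix-geometry measurement from atomic coordinates. Because the raw inputs of
such a study are gel images and instrument traces, the package also ships
generators that emulate each data type, so every analysis stage can be
exercised and validated on data whose ground truth is known.

# Cooperative binding model

EMSA titrations are reduced to fraction bound $f$ versus protein
concentration $[P]$ (nM) and fitted with the Hill isotherm

$$ f([P]) \;=\; \frac{B_{max}\,[P]^h}{K_D^{\,h} + [P]^h}, $$

where $K_D$ is the dissociation constant (nM), $h$ the Hill coefficient
(dimensionless, $h>1$ indicating cooperativity) and $B_{max}$ the binding
plateau. At $[P]=K_D$ the model equals $B_{max}/2$ for any $h$, which is also
the internal consistency check used in the tests.

Two fraction-bound definitions are provided because densitometry practice
varies and neither is canonical:

* **bound-over-total** (default for single-fragment EMSAs): the sum of all
  shifted-band intensities over total lane signal. It uses every band and is
  exactly invariant to uniform lane-intensity rescaling (illumination or
  loading differences).
* **free-depletion**: $1 - \mathrm{free}/\mathrm{free}_0$, the definition
  forced on the competition-ladder assay, where only the free band of each
  fragment is resolvable.

Background is a single scalar per lane, subtracted from each band and clamped
at zero; inputs are intensity tables, so no 2-D image background model is
attempted. The zero-protein lane defines fraction bound 0 by construction.

Fitting is Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`)
with data-driven starts: $B_{max}$ at the observed maximum, and $K_D$, $h$
from a log-logit linearization $\log(f/(B-f)) = h\log[P] - h\log K_D$, which
makes convergence reliable even for steep ($h = 4$) or right-shifted curves.
Bounds ($K_D \in [10^{-3}, 10^6]$ nM, $h \in [0.2, 10]$,
$B_{max} \in [0, 1.2]$) exclude biologically implausible excursions without
constraining realistic fits. On failure the fit restarts from five seeded
log-normal perturbations of the starts; if all fail, a coarse grid search
returns best-found parameters flagged `converged = FALSE`. Fits are
unweighted by default; inverse-variance weighting is available when replicate
SDs exist. $B_{max}$ is free by default — published summary tables for this
kind of assay report only $K_D$ and $h$, leaving the constraint unstated — and
`fix_bmax`/`fix_h` give the constrained nested models.

Replicates are averaged per concentration (`aggregate_replicates`) with the
sample SD; a single replicate reports `NA`, not 0, so downstream code cannot
mistake absence of spread for certainty.

# Competition DNA-ladder selectivity

The ladder assay measures DNA-length selectivity under competition:
equimolar labeled fragments (default 10, 20, 30, 40, 50 bp at 1 nM each)
share one protein titration (~37–760 nM), and only the free band per fragment
is quantified. The analysis:

1. normalizes each fragment's free signal to its zero-protein lane
   (`normalize_free_dna`; noise above 1.0 is kept, not clamped);
2. fits the Hill isotherm to $1-\mathrm{normalized\ free}$ per fragment
   independently (`kdapp_per_fragment`), giving the apparent $K_D$
   ($K_{Dapp}$). Fragments never reaching 20% depletion are right-censored
   ($K_{Dapp} >$ max tested concentration) rather than fitted — fitting a
   flat curve yields meaningless boundary estimates. The threshold is
   configurable;
3. computes C50, the concentration at 50% depletion, by inverting the fitted
   curve: $C_{50} = K_D (0.5/(B_{max}-0.5))^{1/h}$, censored when
   $B_{max} \le 0.5$. A monotone linear interpolation of the raw curve is the
   fallback for data without a usable fit. The fit-based route is the default
   because it is smoother on noisy tails. When $h=1$ and $B_{max}=1$, C50 and
   $K_{Dapp}$ coincide exactly;
4. summarizes selectivity as the slope
   $(K_{Dapp}(50) - K_{Dapp}(40))/10$ nM/bp per replicate. The sign
   convention is: positive when $K_{Dapp}$ increases with length; tighter
   binding of the 50 bp fragment gives a negative slope. A censored
   $K_{Dapp}$ at either length leaves the replicate slope undefined and
   flagged;
5. compares constructs by omnibus one-way ANOVA on replicate slopes
   (`compare_constructs`), with per-construct contrasts against a reference
   construct from the linear-model coefficients. No multiplicity correction
   is applied by default (matching the omnibus-stars reporting style of such
   figures); Tukey HSD is available by flag.

Each fragment's depletion curve is fitted independently: no shared
parameters across fragments and no explicit free-protein competition model
linking them. This mirrors how such assays are analyzed in practice and keeps
$K_{Dapp}$ a purely operational quantity.

# Circular dichroism

Observed ellipticity $m^0$ (millidegrees) is converted to mean residue
ellipticity

$$ \mathrm{MRE}(\lambda) = \frac{m^0(\lambda)\cdot MW}{(n-1)\cdot 10\cdot L\cdot C} $$

with molecular weight $MW$ (g/mol), $n$ residues ($n-1$ peptide bonds), path
length $L$ (cm) and concentration $C$ (g/L). Fractional helicity uses the
single-wavelength 222 nm method with reference values $\theta_u = -3000$
(coil) and $\theta_h = -39000$ (full helix) deg·cm²·dmol⁻¹; values outside
$[0,1]$ are reported as-is with a warning flag rather than clipped, since
they are diagnostic of concentration errors. DNA-signal subtraction is a
pointwise millidegree difference (protein metadata retained), with a
linear-interpolation mode for offset wavelength grids.

Thermal denaturation at 222 nm is fitted with the minimal standard model for
a two-state cooperative transition — van't Hoff equilibrium with linear
native and denatured baselines:

$$ S(T) = \frac{b_n(T) + b_d(T)\,K(T)}{1 + K(T)}, \qquad
   K(T) = \exp\!\left[-\frac{\Delta H}{R}\left(\frac1T - \frac1{T_m}\right)\right] $$

(temperatures in kelvin internally; interfaces in °C; $\Delta H$ in kJ/mol).
A curve is classified `non_cooperative` — the expected behavior of an
isolated SAH, which lacks tertiary structure — when any of: the straight-line
model wins on AIC; the fitted $\Delta H$ falls below a 40 kJ/mol floor; the
fitted $T_m$ lies outside the measured range; or the linear model already
explains the data essentially perfectly ($R^2 > 1-10^{-9}$, the degenerate
exact-line case). These thresholds are package decisions: published work
classifies such curves by visual shape, which an automated pipeline must
replace with explicit criteria. DNA-induced stabilization is reported as
$\Delta T_m$ between two fitted curves (`melt_shift`); the fitted-$T_m$ route
is the default over curve-midpoint reading because it uses the whole trace.

# SAH sequence patterns

Charges are $+1$ for Lys/Arg and $-1$ for Asp/Glu. Histidine defaults to 0
(neutral at the pH ~7.4 of typical binding buffers) with `h_charge`
configurable in $[0,1]$, since structure-figure coloring conventions often
count His as basic. Terminal free amine/carboxylate charges are ignored —
the analyses are windowed sums where a terminal correction has no natural
slot.

* `sliding_net_charge`: net charge in a 7-residue window (odd windows only;
  even windows are rejected rather than given an arbitrary center), assigned
  to the window's central (4th) residue and reported in the protein's own
  numbering.
* `predict_ion_pairs`: every $(i, i+3)$ and $(i, i+4)$ pair of
  opposite-charged residues — the intrahelical salt-bridge geometry that
  stabilizes SAH motifs. The pairs are treated as intrahelical (within one
  helix); residues may participate in multiple pairs.
* `helical_face_bias`: residues projected on a helical wheel at 100°/residue
  (ideal 3.6 residues/turn; configurable). Fixed angular bins give a
  partition whose sector charges sum exactly to the total charge; a sliding
  60°-wide sector scan at 1° steps (width configurable) locates the most
  basic face, ties broken toward the smallest start angle. The bias index is
  the max sliding-sector charge minus the mean sector charge. Note that with
  discrete 100° steps residue angles fall on a 20° lattice, so "zero bias by
  symmetry" statements hold exactly only for sector widths commensurate with
  that lattice.

# Helix geometry

From a C-alpha trace (read from PDB/mmCIF via `bio3d`, first alternate
location kept), the local helix axis is built from sliding windows of four
consecutive C-alpha atoms: the second difference
$v_i = P_{i-1} - 2P_i + P_{i+1}$ points from $P_i$ to the local axis;
successive $v$'s give the local twist angle, the local radius
$r = |v|/(2(1-\cos\tau))$, axis points $P_i + r\hat v_i$, and axis directions
$v_i \times v_{i+1}$. A local method was chosen over global cylinder fitting
deliberately: measuring curvature (e.g. a bent region in the middle of a long
helix) requires local axis information.

Reported measures:

* **end-to-end length**: distance between terminal C-alpha atoms;
* **axis arc length**: polyline length of the axis points, extended by the
  mean axis spacing at both ends so it covers all residues. The arc can
  never be shorter than the end-to-end distance beyond numerical tolerance,
  and exceeds it visibly for curved helices;
* **turns**: mean local twist × residue count / 360°. The twist comes from
  the axis construction, not a fixed 100°/residue, so distorted helices
  report their true turns; extrapolating the mean twist across the terminal
  residues (which the 4-C-alpha windows cannot cover) makes an ideal
  86-residue helix report $86/3.6 \approx 23.9$ turns;
* **curvature profile**: angular change of the axis direction per residue
  step, computed after smoothing the axis polyline with a 4-point moving
  average. One helical turn of smoothing cancels the periodic wobble of
  single-window axis points; on generator helices bent to a known radius
  this recovers $1/R$ to well within 2%. The curved region is the longest
  contiguous run above a threshold (default 1.5°/residue);
* **pairwise RMSD**: optimal least-squares rigid superposition (Kabsch, via
  SVD with a reflection guard) on the common residue numbers of each model
  pair, then RMSD. The implementation is validated in the tests against both
  a brute-force rotation-grid minimizer and `bio3d`'s superposition.

Both end-to-end and axis-arc lengths are reported because "helix length" in
descriptive structural work rarely states its definition; for an ideal
86-residue helix (1.5 Å rise) they agree at ~127.5 Å, matching the ~128 Å
length quoted for KER-sized SAH helices.

# Synthetic data generators

The generators emulate the statistical structure of each data type; their
defaults are the study conditions of the motivating system.

**Finite-lattice cooperative binding.** DNA of length $L$ bp is a
one-dimensional lattice on which protein monomers occupy `footprint` = 20 bp
(the estimated KER site size); a fragment carries at most
$\lfloor L/20 \rfloor$ monomers, which is exactly why EMSA band ladders scale
with fragment length and why a 10 bp fragment is inert. Configurations are
weighted $(K_a [P])^k \omega^{a}$ where $k$ is the number of bound monomers,
$a$ the number of abutting (directly adjacent) monomer pairs, and $\omega$
the nearest-neighbor cooperativity — the minimal standard contact-cooperativity
choice. The partition function is computed exactly by a transfer-style
recursion over lattice positions in $O(L \cdot k_{max})$ (validated against
exhaustive enumeration), with log-space accumulation so large $[P]$ or
$\omega$ cannot overflow. With one site ($m = L$, $\omega = 1$) the model
reduces analytically to the Hill curve with $h = 1$, which ties the generator
to the fitting engine in closed form. The phenomenological Hill analysis and
this mechanistic generator are deliberately different models: recovering
sensible Hill parameters from lattice-generated data is evidence the analysis
is robust, not circular. Titration can run in trace-DNA mode (free protein =
total, as in EMSAs with 1–3 nM DNA against ≥9 nM protein) or solve the mass
balance for free protein by bisection. Overlap-exclusion refinements
(McGhee–von Hippel-style non-integer site size) are intentionally out of
scope.

**EMSA rendering.** Band intensity ∝ occupancy probability × DNA amount,
with per-band lognormal noise (CV, default 5%), additive background, an
optional saturation ceiling, and full determinism given a seed. The ladder
renderer shares one titration across fragments (default 10–50 bp, 1 nM each,
37–760 nM protein) and writes exactly the long-format table the selectivity
analysis consumes. Gel migration physics and fluorophore photophysics are
not modeled — bands are read out as exact species proportions plus noise —
so passing tests demonstrate correctness of the analysis pipeline, not
robustness to densitometry artifacts such as smearing, band overlap or
saturation nonlinearity.

**CD and melts.** Spectra are linear mixes of built-in helix/coil basis
curves (190–250 nm, canonical band positions; each rescaled so its 222 nm
value equals the reference $-39000$ or $-3000$ exactly), converted to
millidegrees by inverting the MRE formula, so helicity round-trips exactly at
zero noise. Melts come from the same two-state model the fitter uses — a
self-consistency design, appropriate because the melt fit is validated by
parameter recovery, not model discrimination.

**Helices and sequences.** `generate_helix` places C-alpha atoms on an ideal
helix (rise 1.5 Å, twist 100°, radius 2.3 Å) with optional uniform axis
curvature (axis bent onto a circle, with a parallel-transported local frame).
`generate_sah_sequence` builds E4K4-patterned sequences (every residue in at
least one $i,i+3$/$i,i+4$ pair at full density) with tunable pair density
and a 120°-sector basic stripe, seeded and deterministic.

# Problem sizes and numerical choices

The test and acceptance workloads are sized to run comfortably on one CPU:
parameter recovery uses 200 seeded titrations per condition on 12-point
concentration grids (a $K_D$ grid of 10–300 nM, $h$ of 1–4, noise
$\sigma = 0.03$); melt recovery uses 200 melts across a 35–65 °C $T_m$ grid
at 3% of signal-span noise; enumeration cross-checks cover lattices up to
$L = 60$, footprints up to 25 and $\omega \in \{0.1, 1, 10\}$; ladder nulls
use 4 replicates at 5% CV; geometry oracles use 80–86-residue helices. Seeds
are explicit everywhere; the RNG state of the caller is saved and restored
around every seeded generator.

Tie-breaks and degenerate inputs are fixed deliberately: the face-bias scan
takes the smallest start angle on ties; single-replicate SDs are `NA`;
identical ANOVA groups report $F = 0$, $p = 1$; an all-zero titration is an
error ("no binding detected") rather than a boundary fit; a fragment that
never crosses the censoring threshold reports a censoring bound, never a
number.

# Limitations

* The data-backed validations against the deposited KER crystal structure
  (PDB 8DEI) and published instrument source data require those files to be
  downloaded and placed under `inst/extdata/sourcedata/`; they are not
  distributed with the package, and the corresponding acceptance tests fail
  with an explanatory message when the files are absent.
* $K_{Dapp}$ from the competition ladder is operational, not thermodynamic:
  fragments compete for protein, so per-fragment independent fits fold
  competition effects into the apparent constant. This matches the assay's
  published interpretation but should not be read as a true $K_D$.
* The CD basis curves are idealized two-component references; the package
  deliberately does not attempt CDSSTR/CONTIN-style secondary-structure
  deconvolution.
* Helix geometry assumes a mostly continuous C-alpha trace; chain breaks
  split the axis rather than being bridged.
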