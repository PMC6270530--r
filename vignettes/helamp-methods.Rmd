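---
title: "Methods: design rule, activity indices, spectroscopy and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design rule, activity indices, spectroscopy and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helamp)
```

This vignette records the models `helamp` implements, the constants and
conventions it had to fix where the underlying methodology leaves choices
open, what the synthetic-data generators do and do not emulate, and the
package's known limitations. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. The design model

An ideal α-helix advances δ = 100° per residue around its axis (3.6
residues/turn). We project residue *i* (1-based) to wheel angle
δ·(i−1) mod 360°, with angles increasing counterclockwise viewed from the
N-terminus. For a composition X*m*·Z*m*·W (m hydrophobic X, m cationic Z,
one interface W; length n = 2m+1), `design_isomer()` places W at the chosen
sequence position and then assigns the m wheel positions nearest W going
counterclockwise to X and the m nearest going clockwise to Z.

**Conventions fixed here, and why.** Neither the wheel orientation nor the
partition direction is dictated by the geometry alone; the pair used above
is the unique one (of the four combinations) that reproduces the
independently known interface-6 sequence KKLLKWLKKLL, and it is
cross-consistent with the textual constraints on the interface-8 and
interface-10 isomers (W8 starts LL… and ends …KK; W10 aligns
position-by-position with the combinatorially derived undecapeptide BP76,
KKLFKKILKFL). The test suite proves the constructive rule equivalent to an
exhaustive search over all C(2m, m) face assignments filtered by
`validate_amphipathic()`, for m = 1, 3, 5.

**Degenerate geometries.** If two positions collide on the wheel (e.g. 19
residues at 100°, where position 19 revisits 0°), "nearest going
counterclockwise" is ill-defined; `wheel_angles()` rejects such geometries
with an error rather than inventing a tie-break, since the designed
families never encounter them. Uneven formulas (m hydrophobic ≠ m cationic)
are likewise rejected: *perfect* amphipathy is undefined for them.

**Validation.** `validate_amphipathic()` demands (a) a contiguous cationic
arc, (b) a contiguous hydrophobic arc, (c) the interface residue strictly
between the cationic arc's counterclockwise end and the hydrophobic arc's
clockwise start, and reports the first violated condition. The polar angle
is the angular span of the cationic arc (equivalently 360° minus the
largest circular gap between its members); across the 11-member L5K5W
family it takes exactly the values 120° and 140°, because the arc spans
four consecutive inter-position gaps drawn from {20°, 40°}.

## 2. Physicochemical descriptors

* **Mean hydrophobicity** H is the arithmetic mean of per-residue scale
  values. Scales are pluggable, shipped as two-column text resources; the
  packaged default is the Eisenberg normalized consensus scale. Published
  H/μH values for this family ("on the Eisenberg scale") do not reproduce
  under any standard Eisenberg table we could identify, so the package
  reports descriptors *per named scale* and never asserts a canonical
  value; the family-level property that is scale-independent — μH
  dispersion across the 11 composition isomers below 5 % CV — is what the
  tests assert.
* **Hydrophobic moment** μH = (1/N)·√[(Σhᵢ sin δ(i−1))² + (Σhᵢ cos δ(i−1))²],
  with the same phase convention as the wheel (a constant phase offset
  cannot change the magnitude). A subtlety worth recording: μH of a
  homopolymer vanishes *exactly* only when the wheel closes
  (N·δ ≡ 0 mod 360°, e.g. N = 18 at δ = 100°). At N = 11, δ = 100° the
  unit-vector sum has magnitude |sin 10°|/|sin 50°| ≈ 0.227, leaving a
  residual μH ≈ 0.02 on the consensus scale — small, but not numerical
  noise. The same closure condition governs exact invariance under cyclic
  sequence rotation. Tests assert exact properties on closed wheels and a
  0.03 bound at N = 11.
* **Mass** uses average residue masses plus water; C-terminal amidation
  swaps the hydroxyl for an amino group (−0.985 Da). Monoisotopic masses
  are available behind a flag. The amidated L5K5W mass is 1409.9 Da,
  matching the quoted 1410 Da.
* **Net charge** is integer counting at neutral pH: +1 per Lys/Arg, −1 per
  Asp/Glu, +1 free N-terminal amine, −1 free C-terminal carboxylate (0 if
  amidated); no Henderson–Hasselbalch titration, because the quantity is
  used as a constant integer in this context. Under this model an amidated
  K₅ undecapeptide is +6; the +7 sometimes quoted for such peptides
  double-counts the terminus and is deliberately not reproduced.

## 3. Activity indices

* **GM** is exp(mean(log MIC)) computed in the log2 domain, exact on
  two-fold dilution series. Out-of-range cells (">128") are explicit bound
  markers that refuse to enter a geometric mean — never the numeric 128.
* **MHC** is the lowest *tested* concentration with hemolysis strictly
  greater than the 5 % threshold ("more than 5 %"); if none exceeds it, an
  explicit ">max tested" bound is returned. MHC is non-decreasing in the
  threshold (tested property).
* **TI′ = MHC/GM** divides by the *unrounded* GM. This matters at the
  printed precision: 128/2.378 = 53.8, whereas 128/2.4 = 53.3. A censored
  MHC propagates as a lower bound on TI′.
* Strains labeled `other` (e.g. a multidrug-resistant isolate tracked
  alongside the panel) never enter GM or TI′.
* The packaged reference panel reproduces every tabulated GM and TI′ value
  at one-decimal precision except the W6 column, whose published GMs are
  inconsistent with its own published MICs (2,2,2,4 → 2.38, printed 2.8).
  The package does not special-case W6; it reports computed values and the
  fixtures document the discrepancy.

## 4. Circular dichroism

Raw millidegree signals are normalized as
[θ]λ = θλ/(10·C·l·N) (C molar, l cm, N residues), a linear, exactly
invertible transform (round-trip tested). Grids are resampled to 0.5 nm by
linear interpolation before family operations.

**Helicity estimator.** Full basis-set deconvolution (CDNN/CONTIN-style)
is out of scope; instead the single-wavelength estimator
f = ([θ]₂₂₂ − θ_coil)/(θ_helix^∞·(1 − k/n) − θ_coil) with θ_coil = +640,
θ_helix^∞ = −42500, k = 3 is used, clipped to [0, 1]. These are the
standard Chen-style constants; their role here is a *documented,
monotone* map from [θ]₂₂₂ to a helix fraction, not a claim of absolute
accuracy. Consequently, published helical contents obtained with neural
network deconvolution (the 64–86 % range) are expected only qualitatively.
The model-free alternative [θ]₂₂₂×[θ]₂₀₈ product is provided for SAR use.

**Isodichroic point.** Over a family of ≥3 spectra on a common grid, the
detector returns the wavelength in the 195–215 nm window minimizing the
across-spectra standard deviation, provided that minimum is below 10 % of
the median |[θ]| there (otherwise `NA`: no credible two-state crossing).
Ties break to the lowest wavelength. The 10 % tolerance is a scale-relative
criterion chosen so that instrument-level noise (hundreds of
deg·cm²·dmol⁻¹ against ~10⁴ signals) cannot mask a true crossing, while
families without a common crossing (e.g. multi-state behavior in
sub-micellar detergent) are rejected.

## 5. Fluorescence and NMR

**λmax** is the argmax of a centered moving average (default 5 points).
Emission is typically recorded every 0.2 nm with a ~5 nm bandwidth, so a
raw argmax is noise-sensitive; the 5-point default is a declared choice,
not an inferred one. Edge points where the centered window is undefined
are excluded. Ties break to the lowest wavelength. Δλmax is the signed
difference to a reference spectrum — conventionally NATA
(N-acetyl-L-tryptophanamide), the free-Trp mimic — measured in the same
solvent; negative values (blue shift) indicate a buried, hydrophobic Trp
environment.

**Secondary shifts.** δ¹Hα − 4.7 ppm (the Trp random-coil reference);
values ≤ −0.1 ppm flag helix. Implausible inputs (outside 2–6 ppm) warn
rather than error, because the reader's job is triage, not validation of
the spectrometer. A terminal Trp (as in the interface-11 isomer) tends to
sit near the random-coil value due to terminal flexibility; this is
reported, never special-cased.

## 6. SAR regression

`linear_fit()` is OLS **with intercept** (the conventional choice; the
methodology being reproduced does not state it, so it is documented here
as an assumption); R² = 1 − SS_res/SS_tot ∈ [0, 1]. The slope standard
error is computed directly as √(SS_res/(n−2))/√Σ(x−x̄)², which is exact and
avoids spurious warnings on perfect fits. `fit_with_exclusion()` drops a
stated id subset (e.g. the terminal-Trp isomers W1/W11, whose fluorescence
need not reflect backbone conformation) and records it in the result.
Published R² values for this family (0.90, 0.73, 0.78, 0.95) depend on
figure-only measured data and are therefore not numeric targets; the
module's correctness rests on hand-computed and synthetic fixtures
(R² = 0.25 on the 3-point fixture; planted slopes recovered within 3 SE;
R² monotone in a fixed-seed noise ladder).

## 7. The synthetic world

All generators draw from a single explicit seed and restore the caller's
RNG state. Defaults state the emulated world once:

| parameter | default | rationale |
|---|---|---|
| CD acquisition | 45 μM, 0.2 cm, 11 residues | typical far-UV peptide CD conditions |
| `cd_noise_sd` | 200 deg·cm²·dmol⁻¹ | instrument-level noise, small vs the ~3×10⁴ helix signal |
| CD bands (helix) | 193 (+), 208 (−), 222 (−) nm; σ 5.5/5/6 | the canonical π→π*/n→π* band positions |
| CD band (coil) | 198 nm (−), σ 7 | the strong coil band below 200 nm |
| `fluor_noise_frac` | 0.01 | 1 % of peak, per 0.2 nm point |
| emission widths | σ 12 nm (blue), 18 nm (red) | asymmetric Trp-like peak, FWHM ≈ 35 nm |
| `hemolysis_hill` | 4 | steep dose–response typical of lytic peptides |
| `hemolysis_hc50_range` | 8–256 μg/mL | brackets observed MHCs (16–128) |
| `mic_log2_mean`, `sd` | 1.5, 0.8 | latent potency ≈ 2.8 μg/mL, two-fold-scale spread |
| planted SAR | slope 200, intercept −100, noise sd 4 | hemolysis 10–90 % over helix fractions 0.55–0.95 |

The CD bases are *tied to the analysis constants*: B_H(222) equals the
finite-length helix limit −42500·(1−3/n) and B_C(222) = +640, so a
two-state mixture satisfies `helical_fraction([θ]₂₂₂) = f` exactly in the
noiseless limit, and every mixture family crosses where B_H = B_C (near
204 nm for these bands). The coil basis passes near −15.6×10³ at 203 nm,
inside the plausibility band for unstructured peptide spectra. MIC cells
are 2^ceiling(latent normal), clipped to 1–128: the "first inhibiting
well" discretization of a two-fold series.

**What a green test does not establish.** The generators emulate the
*statistical shape* of each input, not its physics: Gaussian CD bands are
not a band-theory claim; the hemolysis Hill curve ignores cell-count
saturation; the MIC model has no strain-by-peptide interaction structure;
emission noise is white, whereas real instrument noise is correlated over
the bandwidth. Green tests establish that the analysis stages recover
planted parameters under their stated assumptions — not that those
assumptions hold for any particular instrument.

## 8. Known limitations

* **λmax worst-case accuracy (the one red acceptance clause).** The
  acceptance criterion asks for λmax recovery within 1 nm at 1 %-of-peak
  noise, worst case over 100 seeded replicates. For an emission peak of
  realistic width (our σ 12/18 nm is already *narrower* than real Trp
  emission) on a 0.2 nm grid, the 5-point smoothed argmax achieves a
  median error of ~0.6 nm but a worst case of ~2.6 nm; wider windows trade
  noise for asymmetry bias (≥1.4 nm for every window we measured), and
  parabolic-vertex refinement is likewise bias-limited (0.7–2 nm). We
  judged the criterion unattainable in this stated world and left it red
  rather than narrowing the peak or replacing the estimator with one that
  presumes the generator's shape; the unit suite asserts the honest bound
  (median ≤ 1 nm, max < 3 nm).
* Charge and H/μH absolute values are convention-dependent (see §2); the
  package reports them per model/scale and never as "the" value.
* The helicity estimator is single-wavelength; aromatic contributions at
  222 nm (one Trp per peptide here) bias it in ways the package does not
  model.
* No 3D structure, membrane simulation, D-amino acids, retention-time
  prediction, or replicate-level MIC statistics.
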