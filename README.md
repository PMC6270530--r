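# helamp

Design and quantitative characterization of **perfectly amphipathic helical
antimicrobial peptides** (AMPs).

Short cationic peptides that fold into amphipathic α-helices are a major AMP
class: the cationic face selects for anionic bacterial membranes, the
hydrophobic face drives membrane insertion. `helamp` implements a minimal de
novo design rule for this class and the full numerical toolkit used to
characterize the resulting families, for peptide chemists and structural
bioinformaticians who want a reproducible, scriptable version of that
workflow.

## The design rule and the quantities computed

On the helical wheel, residue *i* of an ideal α-helix sits at angle
δ·(i−1) mod 360° with δ = 100°. For a formula X*m*Z*m*W (default **L5K5W**:
five leucines, five lysines, one tryptophan, n = 2m+1 = 11, C-terminally
amidated), the rule places the single interface tryptophan at sequence
position *p*, the m hydrophobic residues on the arc counterclockwise of it
and the m cationic residues on the arc clockwise of it. Both arcs are
contiguous and the tryptophan sits exactly at the lysyl-end/leucyl-start
interface — the peptide is *perfectly amphipathic* as a helix. Enumerating
p = 1..11 yields the 11-isomer W1..W11 family.

Around the design core:

* **Physicochemical descriptors** — mean residue hydrophobicity
  *H* = (1/N)Σh<sub>i</sub>; Eisenberg hydrophobic moment
  μH = (1/N)·|Σ h<sub>i</sub>·e<sup>iδ(i−1)</sup>|; polar angle of the
  cationic face (120° or 140° across this family); average molecular mass
  (amidated KKLLKWLKKLL: 1410 Da); integer net charge; concentration from
  Trp absorbance (ε₂₈₀ = 5500 M⁻¹cm⁻¹).
* **Activity indices** — geometric-mean MIC (GM), computed in log2 domain;
  % hemolysis relative to a Triton X-100 control; minimal hemolytic
  concentration (MHC, first tested concentration with >5 % lysis);
  pseudo-therapeutic index **TI′ = MHC / GM** using the *unrounded* GM.
* **CD analysis** — normalization to mean residue molar ellipticity
  [θ]<sub>λ</sub> = θ(mdeg)/(10·C·l·N); a closed-form helicity estimator
  f = ([θ]₂₂₂ − 640)/(−42500·(1−3/n) − 640); the [θ]₂₂₂×[θ]₂₀₈ product;
  isodichroic-point detection for two-state coil↔helix families.
* **Fluorescence / NMR** — emission λ<sub>max</sub> (smoothed argmax) and
  Δλ<sub>max</sub> versus a NATA reference (negative = blue shift = buried
  Trp); ¹Hα secondary chemical shifts against the 4.7 ppm random-coil
  reference (≤ −0.1 ppm flags helix).
* **SAR regression** — OLS with intercept, R², and stated-subset exclusion
  (e.g. the terminal-Trp isomers W1/W11).
* **Seeded synthetic generators** for every input kind: two-state CD basis
  mixtures, skewed emission peaks, Hill-type hemolysis curves,
  two-fold-quantized MIC tables, planted linear SAR tables.

## Worked example

```r
library(helamp)

fam <- enumerate_family(peptide_formula())   # L5K5W, 11 isomers
fam$W7
#> <designed_peptide> W7  LKKLLKWLKKL-amide  (L5K5W, interface at 7)

physchem_profile(fam$W7)[, -(1:4)]
#>   mean_hydrophobicity hydrophobic_moment polar_angle molecular_mass net_charge
#> 1             -0.1264             0.8402         120           1410          6

tab <- l5k5w_mic_table()                     # packaged 10-strain MIC panel
ref <- l5k5w_reference_summary()             # tabulated MHC / GM / TI'
s <- summarize_activity(tab, mhc_values = setNames(ref$mhc, ref$peptide_id))
s[s$peptide_id == "W7", ]
#>   peptide_id gm_gram_positive gm_gram_negative gm_all mhc ...
#> 7         W7              2.4              3.0    2.7 128
```

The W7 row reads: GM 2.4 μg/mL against the four Gram-positive strains and
3.0 μg/mL against the five Gram-negative strains (potent, broad-spectrum),
MHC 128 μg/mL (barely hemolytic), hence TI′ of 53.8 / 42.2 / 47.0 — the
most selective member of the family. The W6 column of the packaged
reference table is internally inconsistent with its own MICs (a known typo
in the source data); `helamp` reports the recomputed values and the
reference loader documents the discrepancy.

A synthetic CD spectrum at 80 % helix, analyzed blind:

```r
cfg <- synth_config(seed = 42)
sp  <- normalize_ellipticity(synth_cd(0.8, cfg))
cd_summary(sp)
#>   theta_222 theta_208 theta_203 theta_product helical_fraction
#> 1 -24744.73 -25536.87   -9051.9     631902919            0.805
```

## Command line

```sh
Rscript -e 'quit(status = helamp::amp_cli())' design \
    --formula L5K5W --trp-pos all --out family.fasta
# subcommands: design physchem activity cd fluor nmr sar simulate
```

(or use the launcher `inst/cli/helamp`).

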