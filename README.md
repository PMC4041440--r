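# ensdyn

Structural-ensemble comparison and solution-dynamics analysis for small
dimeric proteins, built around the questions raised by a MazF-family
ribonuclease toxin solved both by X-ray crystallography and by NMR: *which
loops really move, and which only look mobile (or rigid) because of crystal
packing or sparse restraints?*

The package is aimed at structural biologists who have (or can simulate)
multiple coordinate models of the same protein plus the usual solution
biophysics, and want the comparisons on a single per-residue axis.

## What it computes

* **Per-residue pairwise RMSD profiles** within and between ensembles:
  every monomer pair is superposed by least squares (Kabsch, proper
  rotations only) on the ordered core (default mask 1–47, 56–112; backbone
  N, CA, C, O), then RMSD is computed residue by residue; unmodelled
  residues contribute a 10 Å placeholder. Also global pairwise RMSD
  matrices and RMSD-to-average with two refinement passes.
* **Crystal-packing burial**: Shrake–Rupley SASA on a deterministic
  golden-spiral lattice, symmetry mates from cell + space group (P1,
  P2₁2₁2₁, C222₁), unique contact interfaces, and per-residue buried
  surface area summed over a chain's lattice contacts.
* **¹⁵N relaxation**: monoexponential R1/R2 fits, duplicate-based hetNOE
  errors, ordered-residue selection, and the isotropic rotational
  correlation time τ_c = √(6⟨R2/R1⟩ − 7)/(4π ν_N).
* **Chemical shift perturbation**: Δδ = √(Δδ_H² + (Δδ_N/6.51)²), windowed
  intensity ratios, hotspot calling.
* **DLS / CD / ESI-MS**: Siegert-relation correlogram fits (1–2
  exponentials, Stokes–Einstein radii, globular R_h→MW calibration), mean
  residue ellipticity conversion, charge-ladder mass deconvolution.
* **SAXS**: iterative Guinier fits, residue-bead Debye curves, χ with
  fitted scale, and an exhaustive Minimal Ensemble Search (≤5 models,
  NNLS weights).
* **Synthetic data**: seeded generators for every input above, with ground
  truth returned alongside, so the full pipeline runs and is tested
  without any downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
dataset; `Rscript analysis/01_simulate.R` writes the fixtures, and the later
stages consume them. Stage 7, for instance:

```sh
$ Rscript analysis/07_saxs_mes.R
Guinier: R_g = 25.82 A, I(0) = 1.29e+04, window q = [0.005, 0.05] (qR_g end 1.29, 46 pts)
Single-model chi values: 2.99 5.76 3.25 2.98 4.79 3.24 4.28 6.02 10.98 16.44
MES: 3 models (of 10) reach chi = 0.93
  selected: 1, 5, 9 | weights: 0.52, 0.29, 0.19
  generator truth: 1, 5, 9 | weights: 0.50, 0.30, 0.20
```

No single conformer explains the mixed curve (best single-model χ ≈ 3);
the search identifies the true three-member mixture and its weights to a
few percent, at χ ≈ 1, i.e. at the noise floor. Stage 4 prints the
relaxation summary:

```
Ordered-region mean R2/R1 = 23.43 over 36 residues
Apparent rotational correlation time tau_c = 15.1 ns
Residues with depressed hetNOE (<0.65), flagging fast motion: 1-3, 12-22, 61-70, 112-114
```

— the correlation time of a well-folded ~30 kDa dimer, with fast motion
confined to the termini and the two designed mobile loops. A minimal
interactive session:

```r
library(ensdyn)
ens <- make_ensemble(synth_spec(seed = 1))$ensemble
prof <- per_residue_profile(ens, mask = default_core_mask())
head(prof[order(-prof$mean), ])   # the mobile-loop residues
tau_c_from_r2_r1(mean_ratio = 23.73, nu_n = nitrogen_frequency(599.78))$tau_c * 1e9
#> [1] 15.23497
mw_from_rh(2.6)$mw_kda_2sf
#> [1] 32
```

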