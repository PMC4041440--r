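---
title: "Methods: comparing structural ensembles and solution dynamics of a dimeric RNase toxin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing structural ensembles and solution dynamics of a dimeric RNase toxin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdyn)
```

# The problem

MazF-family toxins are small dimeric, ribosome-independent mRNA
endoribonucleases whose activity is controlled by an antitoxin (MazE) and,
structurally, by the conformations of three surface loops flanking the RNA
binding groove. When such a protein is solved both by X-ray crystallography
(several crystallographically independent copies) and by NMR (a model
ensemble), the two ensembles rarely agree in exactly those loops: crystal
lattice contacts can pin a mobile loop, while NMR models spread out wherever
restraints are sparse or the backbone genuinely moves. Deciding which loop
variability is functional therefore requires comparing, on the same residue
axis: (i) per-residue coordinate spread within and between ensembles, (ii)
per-residue lattice burial in each crystal, (iii) per-residue ps--ns backbone
dynamics from ¹⁵N relaxation, and (iv) ligand-binding hotspots from chemical
shift mapping. `ensdyn` implements that comparison as a set of small,
separately testable computations plus a seeded generator that produces every
input with known ground truth.

The driver scripts under `analysis/` run the pipeline end to end on the
synthetic dataset; all numerical claims in this vignette are the ones those
scripts and the test suite actually compute.

# Ensemble comparison

Monomers are compared pairwise. Each pair is superposed by least-squares
(Kabsch) on a masked backbone selection; the proper-rotation branch is
enforced (`det R = +1`), so mirror solutions are never returned. The default
atom set is the backbone `N, CA, C, O`, and the default superposition mask is
the ordered core, residues 1--47 and 56--112, excluding the two mobile loops
and the termini: including high-variance loops in the fit would leak their
motion into every residue's apparent RMSD.

The per-residue profile of a pair is the RMSD over the atom set of that
residue after the *global* core superposition. A residue absent from either
member (no modelled atoms) contributes a fixed placeholder of 10 Å to that
pair, a deliberately off-scale value that makes crystallographic disorder
visible as maximal divergence instead of silently shrinking the mean.
Profiles report mean, minimum and maximum across pairs, and the number of
pairs in which the placeholder fired, so plots can distinguish "moves a lot"
from "not modelled".

`rmsd_to_mean()` reports each member's RMSD to the unweighted coordinate
average after two refinement passes (superpose onto the average, re-average).
Residues modelled in fewer than half the members are excluded from the
average structure, which otherwise would be dragged toward whichever few
members model a disordered terminus.

Correctness is anchored two ways: every reported RMSD is reproduced by
brute-force recomputation from the explicitly transformed coordinates
(to 10⁻⁶ Å), and the Kabsch minimum is checked against an independent
nested grid search over SO(3) (to 10⁻³ Å).

# Crystal lattice contacts

Burial is computed PISA-style but deliberately simplified: no thermodynamics,
just geometry. Solvent-accessible surface area uses the Shrake--Rupley
construction with a 1.4 Å probe, Bondi radii, and a *deterministic*
golden-spiral point lattice (default 960 points/atom) instead of random
sphere sampling, so areas are bit-reproducible; halving the point count
changes totals by under 1 % on the fixtures, which bounds the discretisation
error. Symmetry mates are enumerated from hard-coded operator tables for the
space groups that occur here (P1, P2₁2₁2₁, C222₁) over lattice translations
in {−1,0,1}³; a copy is a contact when any heavy-atom pair comes within
5.0 Å, a conventional PISA-like cutoff (the choice only gates which
interfaces are evaluated; burial itself comes from SASA differences).

Per-residue buried area of a chain at one contact is SASA(chain alone) −
SASA(chain in the pair). Two bookkeeping decisions matter:

* A *unique interface* is the unordered chain pair plus the operator class
  modulo lattice translation and inversion, so the A–B interface found from
  A and from B, or the +a and −a images of a self-contact, count once in the
  interface list.
* The per-chain *burial profile* nevertheless sums over all physical
  contacts of that chain (both images of a self-contact bury residues of the
  chain), because that is what a per-residue lattice-burial plot measures.
  The biological dimer interface inside the asymmetric unit is computed too
  but flagged `intra_asu` and excluded from lattice-only profiles by
  default.

# ¹⁵N relaxation and tumbling

R1 and R2 come from per-residue monoexponential fits `I(t) = I₀ e^(−Rt)`
(Levenberg--Marquardt, log-linear start values); the heteronuclear NOE is
the saturated/unsaturated intensity ratio, with the error taken as half the
absolute difference of the duplicate pair when duplicates exist, else from
the fit covariance. Fits that fail or return non-positive rates are flagged
and excluded downstream rather than silently dropped.

The overall rotational correlation time uses the isotropic large-molecule
closed form

$$\tau_c = \frac{\sqrt{6\,\langle R_2/R_1\rangle - 7}}{4\pi\,\nu_N},$$

valid when the spectral density is dominated by overall tumbling, i.e. over
residues without fast internal motion or exchange. "Most ordered" is not a
published rule, so the package makes one and exposes it: drop residues with
hetNOE < 0.65, then drop residues whose R2/R1 deviates more than 1 SD from
the 10 %-trimmed mean, iterated once. ν_N is derived from the spectrometer
proton frequency via the gyromagnetic ratio magnitude 0.101329. A full
anisotropic diffusion-tensor analysis would shift τ_c by a few percent for a
mildly anisotropic dimer; the closed form is the documented scope here, and
at ⟨R2/R1⟩ = 23.73 and 599.78 MHz it evaluates to 15.2 ns.

# Chemical shift mapping

The combined perturbation is Δδ = √(Δδ_H² + (Δδ_N/6.51)²). The nitrogen
weight 6.51 is less common than 5 or 6.5 but is the convention of the source
data for this system, so it is the default and a config value. Intensity
attenuation is summarised with a 5-residue centred sliding mean, truncated at
the chain ends (a constant profile stays constant, including at the edges).
Residues observed in only one spectrum yield missing values, never zeros —
an absent peak is evidence of exchange broadening, not of a zero shift.
Hotspots are residues above mean + k·SD (default k = 1) of either metric.
The titration analysis point is the 1:1 molar-ratio step; later points of
the synthetic series exist but are not aggregated, mirroring practice when
late titration points are compromised (e.g. by aggregation).

# DLS, CD and mass spectrometry

Correlograms are fit with the Siegert relation g₂(τ) = B(1 + β|g₁(τ)|²)
with g₁ a 1- or 2-exponential decay. Amplitudes are parameterised through a
softmax, so aᵢ ≥ 0 and Σaᵢ = 1 hold by construction; rates are fit on a log
scale; three fixed multi-starts on the rates guard against the local minima
that plague sums of exponentials. A component falling below 1 % amplitude
collapses the fit to fewer components, with a note. Each rate converts to
D = Γ/q², with q = 4πn₀ sin(θ/2)/λ (defaults n₀ = 1.331, λ = 632.8 nm,
θ = 90°, the common He–Ne 90° configuration), and to a hydrodynamic radius
via Stokes--Einstein with the Vogel water-viscosity model
η(T) = 2.414·10⁻⁵·10^(247.8/(T−140)) Pa·s; buffers are treated as water.
Whether a published "characteristic time" refers to the g₁ or the g₂ decay
is instrument-software dependent and not always reconcilable with the stated
optics, so the package never round-trips through characteristic times; it
reports Γ, D and R_h directly.

Mass from size uses the empirical globular-protein calibration
R_h(nm) = 0.7429·M(kDa)^0.3599, exposed as two config constants; it
reproduces the reference pairs (2.6 nm, 32 kDa) and (2.5 nm, 29 kDa) at the
2-significant-figure reporting convention, and warns outside 0.5--10 nm.

CD conversion applies [θ] = θ·Mw/(N·c·l) pointwise exactly as stated for
this dataset (θ in degrees from millidegrees, c in g/ml, l in cm). Note
that this convention differs by a constant decimole factor from the also
common [θ] = θ_mdeg·MRW/(10·c_mg/ml·l); the package implements the stated
form and documents the units, since only relative spectral shape is used
downstream.

Electrospray charge ladders are deconvoluted by the adjacent-peak rule
z = round((m₂ − m_p)/(m₁ − m₂)) with m_p = 1.00728 Da; the ladder is
rejected (with the offending pairs listed) unless the implied charges
increase by exactly one and the per-peak masses agree. On noiseless ladders
the recovery is exact to floating-point for any mass in the 5--100 kDa,
z = 5--30 regime, which the tests sample.

# SAXS

Guinier fitting is a weighted linear fit of ln I on q², iterating the window
so that qR_g ≤ 1.3 at the window end until R_g stabilises (<0.5 % change);
a non-negative slope raises a "no Guinier regime" error rather than
returning an imaginary radius. Theoretical curves use a one-bead-per-residue
Debye sum at the CA positions with a uniform form factor — adequate for
*relative* comparisons among conformers of the same protein, but without a
hydration shell or atomic form factors, so absolute χ values against real
data are not comparable to CRYSOL's and are not treated as reference
numbers. χ itself is computed with the scale factor minimised in closed
form.

The minimal ensemble search enumerates every subset of the candidate pool up
to 5 members (pools ≤ 40, so enumeration is exact, with no stochastic
search to tune), fits non-negative weights by NNLS with the global scale
absorbed into the weights, and returns the smallest subset whose χ is within
a factor 1.05 of the global best — "as small as possible without a
meaningful fit penalty". χ of the best subset is non-increasing in subset
size by construction, which the tests assert.

# The synthetic data generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

* **Ensembles** — 20 models (NMR-like) of a 114-residue chain; mobile loops
  12--18, 48--54 and 64--70 at σ = 2.0 Å against a 0.2 Å core; optional
  per-model rigid transforms (so superposition is actually exercised) and
  loop deletions (so the 10 Å placeholder is exercised). The backbone is an
  idealised compact superhelix with 3.8 Å CA spacing and schematic N/C/O
  placement: correct residue-level geometry and compactness, but not
  stereochemically valid — nothing downstream consumes bond geometry.
* **Toy crystal** — a straight-backbone chain whose contact loop (48--54) is
  splayed into a ±x flange; the P1 a-axis is sized by bisection so the
  closest approach to the +a lattice image equals a designed gap (default
  4 Å). A second, flange-free chain in the same cell makes no contacts,
  giving the packed-vs-free contrast on one axis.
* **Relaxation** — monoexponential decays on the standard delay grids
  (R1: 100--1500 ms; R2: 10--210 ms) with 2 % multiplicative noise and
  duplicate NOE pairs; rigid-core truth R1 = 0.9 s⁻¹, R2 = 21 s⁻¹,
  NOE = 0.80 (a ~30 kDa dimer at 600 MHz; R2/R1 = 23.3 implies
  τ_c ≈ 15.2 ns), loops elevated in R1 and depressed in R2/NOE.
* **Titration** — eight steps to a 2:1 ligand:dimer ratio, fast exchange,
  80 % occupancy at the 1:1 analysis point; binding site in loop S1-S2
  (12--18) plus two strand segments (71--77, 83--90); site peaks lose
  intensity to a 0.35 ratio versus 0.85 elsewhere.
* **DLS** — Siegert correlograms on a log grid (10⁻⁷--1 s, 200 points),
  multiplicative noise on g₂ − B; default truth a monodisperse 2.6 nm
  scatterer; a bidisperse 2.6 + 50 nm mixture exercises the two-population
  fit.
* **SAXS** — a 10-conformer pool generated by hinge-bending the template at
  mid-chain (0--150°), mixed with weights 0.5/0.3/0.2 on three
  well-separated conformers, 1 % Gaussian noise with matching error bars.
  Hinge bending matters: conformers must differ in their scattering for
  ensemble selection to be identifiable at all.

All randomness flows from one integer seed through R's Mersenne--Twister
generator, pinned explicitly with inversion sampling for normals, so streams
are reproducible across platforms; each generator offsets the seed by a
fixed constant so the stages are independent. The generators restore the
caller's RNG state on exit.

**What passing tests do and do not show.** The generators emulate the
*statistical structure* the analyses assume: Gaussian coordinate scatter,
ideal monoexponential decays, fast-exchange shifts, exact Siegert behaviour,
residue-bead scattering. Real data add what the generators omit — anisotropic
and correlated coordinate variation, exchange contributions to R2,
intermediate-exchange line broadening, correlogram baselines drifting with
dust and after-pulsing, inter-particle structure factors at finite
concentration, and hydration-layer scattering. Green tests therefore
demonstrate that the estimators are implemented correctly and are unbiased
under their own assumptions, not that those assumptions hold for any given
experiment.

# Numerical choices and degenerate inputs

* Matthews solvent fraction uses 1 − 1.23/V_M (protein partial specific
  volume 0.74 cm³/g). Whether an asymmetric-unit mass includes a cleaved
  initiator methionine moves the result by only a few tenths of a
  percentage point, well inside the ±1 point reporting convention.
* Altloc policy: highest occupancy wins, ties to file order. HETATM and
  non-standard residues are dropped with a message and count.
* Superposition requires ≥3 non-collinear paired atoms; collinear
  selections are rejected (the rotation about the line is undetermined).
* A two-component DLS fit of truly monodisperse data may split its
  amplitude between two nearly identical rates; the intensity-weighted
  radius is invariant, and sub-1 % components trigger the collapse path.
* Exhaustive MES keeps the whole search deterministic; the 1.05 parsimony
  factor is a config value.
* Problem sizes in the tests and drivers — 100-model ensembles for profile
  localisation, 200-replicate rate recovery, 10-member SAXS pools,
  960-point SASA lattices — were chosen as the smallest sizes at which the
  statistical checks are stable, and are stated in the tests themselves.

# Known limitations

* No model-free (Lipari--Szabo) analysis or anisotropic diffusion tensor;
  τ_c is the isotropic estimate.
* The Debye bead model is not a hydrated all-atom predictor; absolute χ
  values are not comparable across software.
* SASA has no cell-list acceleration; it is sized for chains of a few
  hundred residues, not ribosomes.
* The mmCIF reader handles single-model coordinate files as provided by
  `bio3d::read.cif`; multi-model NMR depositions are expected in PDB
  format.
* No CONTIN-style inverse Laplace inversion for DLS and no p(r)/ab-initio
  SAXS reconstruction; both are method families of their own.
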