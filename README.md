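# bsapkit

Trajectory analysis of excipient (buffer) adsorption on protein surfaces and
its effect on aggregation propensity.

Therapeutic antibody formulations commonly use free histidine as a buffer, and
histidine is known empirically to suppress antibody aggregation. The
microscopic picture behind that effect is adsorption: buffer molecules sit on
solvent-exposed hydrophobic patches of the protein surface, shielding them
from water. `bsapkit` provides the analysis toolchain to quantify this from
molecular-dynamics trajectories of a protein in a buffer solution:

- **SAP** — the Spatial Aggregation Propensity of atom *j*,

  SAP(j) = ⟨ Σ_res (SAA_sidechain of res within r of j / SAA_exposed(res)) · R_h(res) ⟩_t

  with neighborhood radius r = 0.5 nm, SAA the Shrake–Rupley
  solvent-accessible area, SAA_exposed the same side chain fully exposed in an
  Ala–X–Ala tripeptide, and R_h the Black & Mould residue hydrophobicity
  shifted so R_h(Gly) = 0. Positive SAP flags aggregation-prone surface.

- **BSAP** — the buffer-aware extension: SAA is recomputed with adsorbed
  buffer molecules as occluders, and every buffer molecule within 0.4 nm of
  atom *j* adds its own hydrophilicity term
  R_h(his) · SAA(molecule)/SAA_exposed(his). The aggregate score
  Σ_j max(value_j, 0) drops when a hydrophilic excipient covers hydrophobic
  patches.

- **BAI** — a contact-based relative free energy of buffer adsorption per
  residue, BAI_i = −k_BT · ln(N_avg_i / N_max), where N_avg_i is the
  frame-averaged number of buffer–residue atomic contacts within 0.4 nm and
  N_max the largest such count across both buffer charge states (shared
  energy reference; the strongest adsorber has BAI = 0).

- **Adsorption kinetics** — per-molecule minimum-distance series d_min(t),
  residence events (maximal runs with d_min ≤ 0.4 nm), the contact survival
  probability S(t), and bounded multi-start fits of the double stretched
  exponential S(t) = A·exp(−(k₁t)^μ₁) + (1−A)·exp(−(k₂t)^μ₂).

- **Excipient-affinity scores** — S_E = Σ_i −E_i · SAA_avg(i)/SAA_exposed(i)
  per interaction type (cation-π, π-π, H-π) plus a hydrogen-bond score using
  −hp(i) in place of −E_i, with the histidine interaction table packaged.

- **Supporting observables** — radius of gyration, four-point hinge angles,
  surface-referenced radial distributions, Green–Kubo viscosity from
  pressure-tensor series, and Henderson–Hasselbalch buffer composition.

Structures are read from PDB/GRO, trajectories from DCD or a plain
XYZ-with-box text dialect; everything needed for testing is generated by the
seeded synthetic-fixture module (`make_toy_protein`,
`make_adsorption_trajectory`, `make_survival_curve`,
`make_ou_pressure_series`), which produces ground-truth event lists alongside
the trajectories.

## Worked example

Score a synthetic protein+buffer trajectory and fit desorption kinetics:

```r
library(bsapkit)

toy <- make_toy_protein(rep(c("LEU", "ALA", "GLY", "ARG"), 3),
                        geometry = "globule", seed = 7)
sys <- add_buffer_molecules(toy$system, n_neutral = 4, n_charged = 4)
gen <- make_adsorption_trajectory(sys, toy$frame, n_frames = 400,
                                  timestep = 10, bound_mean = 120,
                                  unbound_mean = 250, seed = 7)

ref  <- build_exposure_reference(n_points = 480, conformers = 1)
sap  <- sap_index(gen$trajectory, mode = "SAP",  reference = ref, n_points = 240)
bsap <- sap_index(gen$trajectory, mode = "BSAP", reference = ref, n_points = 240)
sap$score   # 5.790
bsap$score  # 5.175
```

The BSAP score is lower than the SAP score: the (hydrophilic) adsorbed buffer
shields exposed hydrophobic area and subtracts its own hydrophilicity term.
Fitting a forward-generated survival curve recovers its parameters:

```r
sc  <- make_survival_curve(0.6, 2, 0.5, 0.5, 0.8, seq(0, 20, 0.05),
                           noise_sd = 0.01, seed = 2)
fit <- fit_desorption(sc)
fit
#> Double stretched-exponential desorption fit
#>   S(t) = A exp(-(k1 t)^mu1) + (1-A) exp(-(k2 t)^mu2)
#>
#>           amplitude     k1    mu1     k2    mu2
#> estimate     0.6891 1.5082 0.4870 0.5575 0.8710
#> std.error    0.3185 0.5662 0.0755 0.1778 0.2493
```

(each estimate within three standard errors of the generating values
0.6, 2, 0.5, 0.5, 0.8). The packaged excipient interaction table rebuilds the
affinity scores of an antibody Fc fragment for neutral histidine:

```r
fc <- fragment_scores("Fc")
round(fc$cation_pi$per_residue, 1)
#>   ARG   LYS
#>  47.6 165.7
sapply(fc, function(x) round(x$total, 1))
#> cation_pi  pi_pi  h_pi  h_bond
#>     213.3   14.9  20.1    27.6
```

A command-line wrapper (`exec/bsapkit`) exposes the same pipeline as
subcommands (`sasa`, `sap`, `bsap`, `escore`, `adsorb`, `props`, `synth`)
driven by a YAML config; see `?run_cli`.

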