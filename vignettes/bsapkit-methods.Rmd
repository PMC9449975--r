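---
title: "Methods: buffer-aware aggregation propensity and adsorption kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: buffer-aware aggregation propensity and adsorption kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsapkit)
```

## The problem

Amino-acid buffers such as free histidine suppress aggregation of
therapeutic antibodies, and the working mechanistic picture is surface
shielding: buffer molecules adsorb onto solvent-exposed hydrophobic patches
and reduce the protein's effective exposed hydrophobicity. `bsapkit`
quantifies this picture from molecular-dynamics trajectories along three
axes: *where* the buffer adsorbs (contact counts, BAI, surface-referenced
distributions), *for how long* (residence events, survival probability,
stretched-exponential desorption fits), and *with what consequence for
aggregation propensity* (SAP versus its buffer-aware extension BSAP).

The package analyses trajectories; it does not run dynamics. All inputs are
either standard structure/trajectory files or the packaged synthetic
generators.

## Accessible areas and the exposure reference

All surface terms rest on Shrake–Rupley accessible areas: test points on a
deterministic Fibonacci lattice are placed on each atom's extended sphere
(van der Waals radius + probe radius) and counted against occlusion by every
other context atom. Defaults: probe 0.14 nm (water), 960 points per atom.
The lattice is seedless, so areas are bit-reproducible; 960 points put the
isolated-sphere error below 0.5% and the point-doubling drift below 1% on
cluster fixtures. Van der Waals radii come from a single packaged
Bondi-style element table, so results are reproducible from the repository
alone. Areas are computed over heavy atoms by default (the synthetic
templates carry no hydrogens); the convention is switchable where it
matters.

Exposure fractions are normalized by the *fully exposed* side-chain area of
each residue type, computed from an extended Ala–X–Ala tripeptide. The
packaged reference is built from idealized template geometry — extended
backbone, side chains grown along an axis with a small zig-zag, averaged
over a few twist conformers about the CA–CB axis — and is therefore a
deterministic *reconstruction*, not an MD ensemble average. Users with
restrained trimer trajectories can average areas over them and pass the
resulting table anywhere a reference is accepted. Glycine has no heavy
side-chain atom; its reference falls back to the accessible area of its CA
in the trimer, which keeps every downstream normalization finite while its
glycine-shifted hydrophobicity of zero annihilates the term anyway.

## SAP and BSAP

For protein atom $j$ in one frame,

$$\mathrm{SAP}(j) \;=\; \sum_{\mathrm{res}} \frac{\mathrm{SAA}^{k\in r}(\mathrm{res})}{\mathrm{SAA_{exposed}}(\mathrm{res})}\; R_h(\mathrm{res}),$$

summing over residues with at least one side-chain atom within
$r = 0.5$ nm of $j$; $\mathrm{SAA}^{k\in r}$ counts only the side-chain
atoms actually inside the neighborhood, and $R_h$ is the Black & Mould
hydrophobicity shifted so glycine is zero (arginine −0.50 is the most
hydrophilic entry, histidine scores −0.34). Values are averaged over frames
first; the aggregate score $\sum_j \max(\mathrm{SAP}_j, 0)$ is then taken on
the time-averaged atomic values, so transient sign flips do not inflate it.

Conventions adopted where the formulation is genuinely open:

- an atom's own residue contributes when its side chain falls within $r$
  (self-inclusive, matching the established SAP formulation); the
  `include_self` switch disables it. A consequence worth knowing: as
  $r \to 0$ a side-chain atom retains exactly its self term, while backbone
  atoms go to zero.
- only protein atoms occlude in SAP; ions and solvent never occlude
  (trajectories analysed here typically omit solvent coordinates).

BSAP modifies this in two separable ways. First, buffer atoms join the
occlusion context globally, so an adsorbed molecule geometrically shields
the surface (this is the $\mathrm{SAP}_b$ term). Second, every buffer
molecule with *any* atom within the 0.4 nm contact cutoff of atom $j$
contributes $R_h(\mathrm{his}) \cdot \mathrm{SAA^{his}} /
\mathrm{SAA_{exposed}^{his}}$, where $\mathrm{SAA^{his}}$ is that molecule's
instantaneous accessible area in the full protein+buffer context and the
denominator is the free molecule in isolation. Occlusion is geometric
(global), membership of the hydrophilicity term is contact-based: the two
ranges deliberately differ. With a hydrophilic excipient the BSAP score can
only fall relative to SAP on fixtures where the buffer adsorbs over
hydrophobic surface, and the suite asserts exactly that.

## Contacts, residence and survival

A buffer molecule is adsorbed while its minimum atomic-pair distance to the
protein, $d_\min$, is at most $r_\mathrm{cut} = 0.4$ nm — a cutoff wide
enough to cover both hydrogen bonds and salt bridges, with the boundary
value counting as adsorbed. Distances are minimum-image under the frame's
box (orthorhombic closed form; triclinic via lattice reduction plus a
27-image scan); a flag disables wrapping for pre-whitened trajectories,
since upstream tools differ in whether they wrapped.

Residence events are maximal runs of consecutive adsorbed frames; a
departure and return is two events. Durations use the convention
$\tau_r = (\text{frames in event}) \times \Delta t$ with 0-based frame
indices, stated here because the trailing-edge choice is arbitrary and must
simply be consistent — the conservation property (total event duration =
adsorbed frames × $\Delta t$) is tested.

The survival probability $S(t)$ is the fraction of buffer–protein contacts
present at a time origin that remain *continuously* intact after lag $t$;
reattachment starts a new event. Multiple time origins are used by default
(a single origin wastes the trajectory), restricted to origins that leave a
full maximum-lag window so the per-lag denominator is constant — that
guarantees monotone $S$ and $S(0) = 1$ exactly, at the price of discarding
tail origins. The maximum lag defaults to half the trajectory.

## The desorption fit

$S(t)$ is fitted to the double stretched exponential

$$S(t) = A\,e^{-(k_1 t)^{\mu_1}} + (1-A)\,e^{-(k_2 t)^{\mu_2}},$$

whose two terms capture the short- and long-time decays; exponents
$\mu < 1$ measure deviation from Markovian desorption. The amplitudes are
parameterized as $A$ and $1-A$ so $S(0)=1$ is structural. Fitting is
bounded Levenberg–Marquardt (`minpack.lm`) with $A \in [0,1]$, $k > 0$,
$\mu \in (0, 1.5]$, started from a deterministic grid (72 points) anchored
on the curve's interpolated $1/e$ crossing; the best converged start by
residual sum of squares wins, and the two terms are reported fast-first
($k_1 \ge k_2$). Weights are uniform by default with an optional
$1/\sqrt{S}$ tail emphasis, because the slow rate is tail-sensitive. A
curve with no decay (min $S > 0.99$) or fewer than 10 lags is rejected
rather than fitted.

Recovery characteristics, measured on forward-generated curves: all five
parameters within 1% noiseless and within three standard errors under
Gaussian noise of 0.01. Two identifiability caveats are inherent to the
model, not the optimizer: a pure single exponential leaves the second term
redundant (only the dominant component's $k$, $\mu$ are meaningful), and
event lists from frame-sampled trajectories carry discretization that the
redundant term absorbs, biasing the dominant $\mu$ upward by roughly 0.1
for a true 0.5. Tests assert accordingly.

## BAI and the excipient-affinity scores

Per-residue contact counts are frame-averaged numbers of buffer–residue
atomic pairs within 0.4 nm, summed over molecules of one charge state. The
Buffer Adsorption Index is $-\ln(N^i_\mathrm{avg}/N_\mathrm{max})$ in
$k_BT$ units, with $N_\mathrm{max}$ shared across charge states so neutral
and protonated buffer sit on one energy reference; the strongest adsorber
is exactly 0 and zero-contact residues report $+\infty$ and are listed
separately rather than plotted.

The affinity scores $S_E = \sum_i -E_i\,\mathrm{SAA_{avg}}(i)/
\mathrm{SAA_{exposed}}(i)$ (and the hydrogen-bond analogue with $-hp_i$)
ship with the histidine interaction table as packaged data: energies in
kcal/mol per interaction type, glycine-shifted hydrophobicities, and the
tabulated fragment-average and fully-exposed areas. The packaged table's
own area columns are printed to 2–3 significant figures; score
reproductions are therefore checked with input-rounding-aware tolerances
(totals to 1%). Signs are chosen so attractive energies and hydrophilic
residues score positively.

## Structural observables

Radius of gyration is mass-weighted by default (element masses from the
packaged table). Hinge angles are defined by four user-declared anchor atom
sets (center-of-mass points, A→B versus C→D): which disulfide pairs anchor
an antibody's Fab–Fc angle is a structure-specific choice the package never
infers. The surface-referenced distribution bins each target atom's minimum
distance to the reference surface and reports frame-averaged counts per bin
width — a gmx-rdf-like convention whose integral is the mean number of
targets in range, *not* a volume-normalized $g(r)$. Green–Kubo viscosity
integrates the off-diagonal pressure autocorrelation (FFT-based, all time
origins, trapezoidal rule) up to `t_max`; with bar, nm³, ps and K in, the
result is in mPa·s. The Henderson–Hasselbalch helper returns the charged
fraction $1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$ — one half at
$\mathrm{pH} = \mathrm{p}K_a$, the operating point of histidine buffers at
pH 6 — and the box-count helper rounds $cVN_A$ to the nearest integer
before splitting by that fraction.

## What the synthetic generators emulate — and what they do not

`make_adsorption_trajectory` drives each buffer molecule through an
alternating bound/unbound telegraph process: bound dwells are exponential
or Weibull (stretched), unbound dwells exponential, and the molecule is
placed so that its drawn distance *is* the minimum protein distance (bound
strictly inside 0.25–0.395 nm, unbound strictly outside 0.6–2 nm, avoiding
boundary ambiguity; a grazing configuration can be built by overriding the
ranges). With `align_grid` the dwells are rounded to frame multiples and
the returned ground-truth event list matches detection exactly, which is
what makes the generator an oracle. Defaults mirror the conditions the
analysis is meant for: 0.4 nm cutoff, ~100 ps dwell scales, 10 ps frames,
tens of buffer molecules split between neutral and charged states as the
Henderson–Hasselbalch fraction dictates at pH 6.

What the generators deliberately do not emulate: force-field energetics,
buffer–buffer interactions, surface diffusion along the protein (a molecule
is either on its anchor site or in solution), solvent, and conformational
change of the protein (frames share one protein geometry). Passing tests
therefore validate the *estimators* — detection, survival, fitting,
scoring — under known kinetics and geometry; they do not validate
force-field realism, and scores on the toy fixtures are not comparable in
magnitude to full-size antibodies, whose surfaces are three orders of
magnitude larger.

Problem sizes used by the test suite were chosen to exercise every code
path at comfortable statistics: 1e6-sample Ornstein–Uhlenbeck series for
the viscosity check (2% agreement with the analytic $(V/k_BT)\sigma^2
\tau_c$, asserted at 5%), 30 molecules × 2000–3000 frames for kinetics
(>10⁴ origin contacts; $S(t)$ within 0.015 of $e^{-k t}$ on exponential
fixtures), 5-atom clusters against a 10⁶-sample Monte-Carlo surface oracle
(2%), and small peptides for the SAP double-loop oracle (1e-9 equality).

## Known limitations

- XTC trajectories are not read; convert to DCD or the plain text dialect.
- The Shrake–Rupley implementation ignores periodic images (proteins are
  assumed whole and compact in the frame).
- The exposure reference is an idealized-geometry reconstruction; absolute
  SAP/BSAP magnitudes shift with the reference, so compare scores computed
  with the same reference only.
- The survival estimator's constant-denominator design discards origins
  near the trajectory end; for very short trajectories use
  `multi_origin = FALSE` and read $S$ as a single-origin step curve.
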