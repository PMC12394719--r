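---
title: "Models and methods behind condage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind condage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condage)
```

condage simulates protein/peptide condensates at residue resolution and
quantifies how inserted peptides change condensate stability and the kinetics
of the liquid-to-solid ("ageing") transition driven by inter-protein
cross-β-sheet formation. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the shipped toy
systems can demonstrate.

## The residue-resolution force field

Each amino acid is one bead carrying a diameter σ (nm), a stickiness
λ ∈ [0, 1], a charge q (e) and a mass (Da); the embedded table is the
published CALVADOS2 parameter set (`calvados_residues()`), with
ε = 0.8368 kJ/mol as the hydrophobic energy scale. Non-bonded interactions
combine:

* an **Ashbaugh–Hatch potential** — a Lennard-Jones core whose attractive
  branch is scaled by λij = (λi + λj)/2: for r ≤ 2^(1/6)σij the energy is
  U_LJ(r) + (1 − λij)ε, beyond it λij·U_LJ(r). The minimum of the attractive
  pair potential sits at 1.122σij, which is why the contact-map threshold
  below uses 1.2σij.
* a **Debye–Hückel potential** for screened electrostatics,
  U = qiqj·B(εr)·exp(−r/λD)/r, with λD computed from the ionic strength
  (0.796 nm at 150 mM NaCl, 300 K, εr = 80). `compute_debye_length(0)`
  returns the unscreened Coulomb limit.

Both terms are truncated and shifted to zero at their cutoffs (defaults
2.0 nm AH, 4.0 nm DH, configurable — toy boxes smaller than twice the cutoff
use shorter ones). Consecutive beads are joined by harmonic bonds
(r0 = 0.38 nm, k = 8033 kJ/mol/nm²). A harmonic angle potential
(θ0 = π, kθ = 50 kJ/mol/rad²) acts **only** along structured LARKS segments;
a fully disordered system has exactly zero angle energy. The angle constant
is our choice: strong enough that structured segments straighten within a few
bond times at 300 K, weak enough to keep the 10 fs timestep stable.

Histidine is neutral at the default pH; an optional Henderson–Hasselbalch
switch (`histidine_ph`) assigns the fractional titration charge with
pKa 6.0. Terminal charges (+1e/−1e) are off by default; they cancel in the
net charge either way.

Units are nm, ps, kJ/mol, Da, e, K with kB = 0.008314463 kJ/mol/K, so
1 Da·nm²/ps² = 1 kJ/mol and no unit conversion appears in the integrator.

## Dynamics

Langevin dynamics uses the BAOAB splitting (friction default 0.01 ps⁻¹,
dt = 10 fs, both configurable). The integrator runs in compiled code but
draws its noise from R's RNG, so `set.seed()` gives bitwise-reproducible
trajectories. At very weak friction the full-step kinetic temperature of any
splitting scheme carries a small O(dt²) bias on steep repulsive walls; runs
that assert temperature accuracy therefore use friction ≥ 0.5 ps⁻¹, where
the thermostat holds the target within a fraction of a percent. Setting
friction to zero disables the O-step entirely and yields an NVE check mode
(energy drift < 10⁻⁴ relative per 10⁴ steps on a bonded dimer at dt = 5 fs).

Bulk NPT runs couple the volume isotropically to a target pressure with a
Berendsen-style weak-coupling rescaling (per-step volume change clamped to
±10% for robustness); slabs are never pressure-coupled. A run whose volume
exceeds 10× its initial value raises the divergence flag. Stability
classification: *condensed* if the mean density over the final quarter stays
at ≥ 50% of the initial density, *diluted* if the volume diverged or density
fell below 10%, *marginal* otherwise; the Tc bracketing protocol counts only
*condensed* runs as stable.

Freshly packed random-walk configurations contain steep overlaps, so
builders run a displacement-capped steepest descent (`minimize_config()`)
before dynamics.

Instead of a neighbour list, the pair kernel evaluates all pairs with an
early cutoff rejection. At the package's intended sizes (10²–10³ beads) this
is faster than maintaining a cell list and removes a whole class of
stale-list bugs; the kernel is O(N²), so scaling to ≥10⁴ beads would warrant
revisiting this choice.

## The ageing engine

LARKS (low-complexity aromatic-rich kinked segments) are annotated per
sequence with 1-based local indices, a disordered per-LARKS binding energy
(informational; the model window is 3–6 kBT) and a structured target
(default window 30–50 kBT; shipped defaults 30 kBT for the FUS LCD LARKS,
40 kBT for TDP-43 LCD — the midpoints of the quoted range). The literature
quotes both 20–45 kBT and 30–50 kBT for structured LARKS; we default to the
latter and expose both ends per annotation.

Every `check_interval` steps (default 5000) the engine:

1. computes the **centre of geometry** of each LARKS segment,
   minimum-image-consistently;
2. finds **nucleation clusters**: connected components of the proximity graph
   over *disordered* centres with edges at distance ≤ cutoff, keeping
   components spanning ≥ 4 pairwise-distinct chains. Event members are one
   LARKS per chain (the one nearest the component centroid), which makes
   detection invariant under chain relabelling;
3. applies **templated growth**: a disordered LARKS within the cutoff of ≥ 2
   structured members of one assembly (on other chains) converts and joins
   that assembly.

The default proximity cutoff is calibrated from the topology as
1.2·σ̄ + b·sqrt((L² − 1)/12): the bead-level contact criterion (just outside
the pair-potential minimum) plus the rod-estimate radius of gyration of an
L-residue segment. The second term matters because two segments whose beads
are in binding contact still have centres separated by roughly the segment
extent; with the bare 1.2·σ̄ the criterion essentially never fires at
segment level.

A transition is irreversible. It rescales the AH energy of inter-chain bead
pairs between member LARKS by a factor solved per member so that the sum of
aligned-pair potential minima against its cluster partners equals its
structured target; freshly co-nucleating pairs use the geometric mean of the
two member scales, which is exact for same-motif LARKS. Intra-chain LARKS
pairs never strengthen. The angle potential activates along the member
segments. The "summed aligned-pair minima" bookkeeping is also the quantity
reported by the disordered baseline (≈ 4–5 kBT for the FUS LCD LARKS against
three clustered partners) and checked post-transition (exactly the target in
homogeneous systems).

`ageing_run()` alternates dynamics chunks with detection sweeps and returns
the structured-fraction time series, the time-stamped event log (JSONL
export), the final ledger and the trajectory.

## Phase behaviour

Two complementary routes, mirroring the two standard protocols:

* **Direct coexistence**: slab configurations (elongated box, dense central
  third), circular-mean-recentred density profiles, and plateau/tail
  averaging — the dense density from the central 50% of the
  above-half-range region, the dilute density from the outermost 25% of the
  box per side, excluding the interfaces. Coexistence points feed
  `fit_critical_point()`, a simultaneous least-squares of the
  critical-exponent width law (ρd − ρl = A(1 − T/Tc)^β, β fixed at 0.325,
  the 3D Ising value) and the law of rectilinear diameters. Given Tc both
  laws are linear in the remaining parameters, so the fit profiles them out
  and optimises Tc in one dimension — no starting guesses, no local minima.
* **NPT bracketing**: a temperature ladder of bulk NPT runs at P = 0; Tc is
  the midpoint between the warmest stable and coolest unstable temperature,
  with the half-interval as the error bar. Default ladder spacing is 5 K for
  production-scale scans.

`reduced_temperature()`/`absolute_temperature()` implement the T/Tc
convention used to place ageing runs at 0.95·Tc, rounding to the nearest
kelvin.

## Ageing kinetics

Raw cross-β counts are normalized by a plateau estimate (mean over the final
10% of the series, capped at 1); a series still rising in that window is
flagged censored. t1/2 is the linear interpolation to the halfway point
between initial value and plateau; the nucleation lag time is the first
event's timestamp; censored trajectories enter box plots at the step budget
and are excluded from kinetic fits.

The secondary-nucleation-dominated model is the standard two-moment system
dP/dt = kn·m^nc + k2·m^n2·M, dM/dt = 2k₊·m·P with m = mtot − M, integrated
with `deSolve::ode` (lsoda). Reaction orders default to nc = n2 = 2. A
single normalized curve constrains only the products kn·k₊ and k2·k₊ — the
classic identifiability limit of this model class — so absolute nucleation
rates are reported after fixing the elongation rate k₊ in `fixed`; with k₊
free, only the products should be interpreted. The fit runs a small
log-space Nelder–Mead multistart seeded by the observed half-time.

Peptide ranking uses the Mann–Whitney U test on replicate half-times
(exact enumeration for n1 + n2 ≤ 20 without ties, tie-corrected normal
approximation otherwise) with 6 replicates per system by default. The lag
times of a nucleation-limited process are memoryless, so
`lag_distribution_test()` fits a one-parameter exponential and reports a
Kolmogorov–Smirnov goodness of fit; describing continuous half-times as
"Poisson" is a common shorthand for exactly this memoryless-arrival picture,
and we implement the exponential reading rather than a discrete Poisson law.
Since the KS test uses an estimated rate its p-value is conservative, which
is acceptable for an accept/reject dispersion check.

## Material properties and structure

* **G(t)** by Green–Kubo: V/(kBT) times the autocorrelation of the
  off-diagonal pressure-tensor components, averaged over the three
  components, with the maximum lag capped at 10% of the series. Maxwell
  modes are fitted by Levenberg–Marquardt with the mode count grown until
  the RMS improves by < 5%; η = ΣGiτi by construction, and the viscosity is
  insensitive to the mode count once the fit has converged.
* **G′/G″** from the Maxwell closed forms; a mode with τ = ∞ is a pure
  elastic plateau. Classification compares the moduli over the lowest
  frequency decade; a permanent plateau mode dominates the ω → 0 limit and
  forces *solid*.
* **Aged-state rheology at toy scale**: the elastic plateau of a cross-linked
  network is Gp = ν·kBT (affine network model) with ν the cross-link number
  density. For an 8-chain toy this is ~1 kJ/mol/nm³, far below the
  statistical noise floor of a short Green–Kubo estimate (±3 in the same
  units), so `network_plateau_mode()` computes the plateau from the ledger
  and appends it to the measured fast modes; the liquid→solid flip is then
  corroborated dynamically by the chain-mobility arrest diagnostic below.
  At production scale (10³+ chains, long runs) the plateau becomes
  measurable directly from the stress autocorrelation.
* **Contact maps**: two residues on different chains are in contact below
  1.2σij; frequencies are percentages over frames × chain pairings, with
  homotypic maps symmetrized (diagonal counted once).
* **Rg and diffusion**: mass-weighted radius of gyration from unwrapped
  chains; chain-centre MSD measured relative to the system centre of mass
  (a Langevin thermostat does not conserve momentum, and for a cross-linked
  cluster the collective drift would otherwise mask the arrest);
  D = slope/6 over the central third of lags, with a log-log exponent < 0.8
  reported as *arrested* instead of a coefficient.

## The screening campaign

`campaign_config()` fixes the study conditions: protein + LARKS annotation,
peptide specs in repeat notation, mass-ratio grid, NPT temperature ladder,
reduced ageing temperature 0.95, six distinct velocity seeds. Peptide copy
numbers come from `resolve_stoichiometry()` (rounded mass ratio; the
realized ratio is reported). `run_phase_scan()` produces Tc brackets and
condensed densities per system; `run_ageing_campaign()` produces replicate
statistics, Mann–Whitney p-values against the pure system, and a rank by
mean t1/2; `screening_summary()` joins the two and flags candidates whose
ΔTc lies in [−5%, −1%] of the pure Tc at a mass ratio ≤ 0.1 — peptides that
mildly destabilize the condensate without dissolving it.

## Toy systems, problem sizes, and what the tests show

The `mini-larks-8` fixture — eight 30-residue aromatic-rich chains with one
central SYSGYS LARKS each, bulk density 700 g/L, short cutoffs (1.2 nm) so
the toy box remains twice the cutoff — is sized so a complete ageing run
(nucleation, growth, plateau) finishes in well under five minutes on one
core. The test suite runs dynamics at 10³–10⁵ steps on 10²-bead systems and
the kinetic/critical fits on synthetic curves of a few hundred points; these
sizes are our choice of a regime where every qualitative property of the
pipeline (monotone irreversible ageing, distinct-chain nucleation, energy
windows, bracket logic, classification flips) is exercised exactly.

What the toys do **not** show: quantitative coexistence densities or Tc of
real LCD sequences (those need 10²-chain slabs and microsecond-scale
sampling), absolute viscosities (no explicit solvent; model units), or the
full ~100× peptide-induced lag-time deceleration, which emerges at
production scale. The production protocol is the same code path at larger
`protein_copies`, `n_steps_npt`, `n_steps_ageing` and replicate counts:
build the FUS LCD or TDP-43 LCD fixture, scan the 13-peptide library over a
0.05–0.1 mg/mg stoichiometry window on a 5 K NPT ladder, then age six
replicates per system at 0.95·Tc.

## Known limitations

* The exact functional form of the local order parameter used in the
  original ageing studies is not public; the centre-distance criterion with
  the calibrated cutoff is the simplest faithful reading, and the cutoff is
  configurable per run.
* Energy rescaling distributes the structured binding uniformly over aligned
  bead pairs; for mixed-motif clusters the geometric-mean coupling makes the
  realized per-LARKS binding approximate (still inside the 30–50 kBT window
  for the shipped annotations).
* Cross-β structures never melt (no thermoresistance modelling), folded
  domains, nucleic acids and explicit solvent are out of scope, and the
  barostat is weak-coupling (no box-shape fluctuations).
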