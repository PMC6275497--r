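---
title: "Modelling cotranslational folding forces with nascentfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cotranslational folding forces with nascentfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nascentfold)
```

## The problem

When a protein domain is synthesized by the ribosome it can begin to fold
while its C-terminus is still held in the exit tunnel. Folding at the tunnel
mouth requires stretching the intervening nascent-chain linker, which puts
the chain under mechanical tension. Arrest peptides (APs) such as SecM act
as force sensors for this tension: the pulling force accelerates escape
from translational arrest, and the fraction of full-length protein
synthesized in a fixed incubation time, `f_FL`, read off a gel, reports the
force. Scanning the linker length `L` between the domain and the arrest
point yields a *force profile* `f_FL(L)` whose peak marks the onset of
cotranslational folding.

`nascentfold` implements the complete computational counterpart of such an
experiment:

1. a coarse-grained, structure-based (Gō-type) model of the domain tethered
   through a repulsive linker to a rigid ribosome scaffold,
2. constrained Langevin dynamics and umbrella sampling along the fraction
   of native contacts `Q`,
3. WHAM reweighting into free-energy profiles `G(Q)`, folded populations
   `P_f(L)`, and state-conditioned mean tether forces `F_u(L)`, `F_f(L)`,
4. a Bell-model arrest-escape kinetic scheme turning those into predicted
   force profiles (both by kinetic Monte Carlo and by a preequilibrium
   closed form), and
5. transition-path statistics (φ-values, conditional contact importance
   `p(TP|q_ij)_nn`) that characterize the folding mechanism on and off the
   ribosome.

## The energy model

Beads: one bead per amino acid at the Cα position, three beads per RNA
nucleotide (P, C4′, N3), with fixed radii 0.45, 0.32, 0.51 and 0.45 nm
(amino acid, phosphate, sugar, base). Internal units are kJ/mol, nm, ps, K;
forces are reported in pN (1 kJ mol⁻¹ nm⁻¹ = 1.66054 pN).

Within the domain a standard structure-based model is used: chain bonds are
constrained to their native lengths; angles are harmonic about native
values (40 kJ mol⁻¹ rad⁻²); dihedrals use the usual
`k[1 − cos(φ−φ₀)] + k/2 [1 − cos 3(φ−φ₀)]` form with the total dihedral
strength set to half of the total native-contact energy (a 2:1
contact-to-dihedral energy share); native contacts are 12–10 wells
`ε_c [5(r₀/r)¹² − 6(r₀/r)¹⁰]`. Native contacts are all residue pairs with
any heavy-atom pair within 0.45 nm at sequence separation ≥ 4 (a Cα
fallback criterion is used, and flagged, for Cα-only inputs). Neither the
contact strength `ε_c` nor the angle/dihedral constants are universal
constants of such models; they are calibration choices, and the values
shipped here are calibrated on the synthetic fixtures (below).

All remaining pairs — nonnative intraprotein pairs, linker against
everything, protein against the ribosome — interact through a soft
excluded-volume potential `V = ε_ij (A r⁻¹² − B r⁻¹⁰ + C r⁻⁶)`. The printed
literature mixing rules for (A, B, C) are typographically corrupted and
dimensionally inconsistent, so the package defines its own default: a pure
`r⁻¹²` repulsion with `A = σ_ij¹²`, `B = C = 0` and
`σ_ij = (σ_i + σ_j)/2`. This choice is strictly positive, monotonically
repulsive, and negligible beyond ~1.5 σ_ij — the three properties the
excluded-volume term actually needs; a 12-10-6 variant
(`A = σ¹², B = 2σ¹⁰, C = σ⁶`) is available via
`cg_params(mixing_rule = "mixed12106")`, differing only by a sub-milli-kT
well just inside σ_ij. Protein–ribosome and linker interactions use
ε = 0.001 kJ/mol (soft steric exclusion); intraprotein nonnative pairs use
ε = 1 kJ/mol (a conventional excluded-volume scale for structure-based
models).

The nascent chain is tethered by its C-terminal bead to the anchor (the
last P atom of the A-site tRNA, or the toy equivalent) with a stiff
harmonic spring, `E = ks(x − x₀)²/2`, `ks = 3000 kJ mol⁻¹ nm⁻²`,
`x₀ = 0.38 nm` — stiff enough that a 500 pN load displaces the bond by less
than 0.1 nm. The instantaneous pulling force is `F = ks(x − x₀)`, positive
under tension. This is the only unconstrained bond.

Optional hydrophobic attractions between selected domain residues and
ribosome-surface residues use a Lennard-Jones 12-6 form with σ = 0.6 nm and
ε = 5 kJ/mol (`add_hydrophobic_surface_attraction()`), and point mutants
are modelled by uniformly weakening all native contacts of the mutated
residue (`weaken_residue_contacts()`, default 40%).

## Dynamics and sampling

Trajectories are propagated with a geodesic BAOAB Langevin integrator at
291 K with friction 0.1 ps⁻¹: velocities are projected onto the constraint
tangent space after every kick and Ornstein-Uhlenbeck stage, and the drift
stage is a RATTLE position update whose constraint corrections act along
the pre-drift constraint gradients. For a linear chain the constraint
coupling matrix is tridiagonal, so both stages are solved directly (Newton
iteration with Thomas solves; the velocity projection is a single exact
solve), reaching the 10⁻⁸ nm bond tolerance in two to four iterations.
This construction is verified by the test suite to conserve the kinetic
energy of a free rigid dimer exactly, to hold NVE energy drift near
10⁻⁶ kJ/mol per step per bead, and to equipartition the thermostatted
constrained system to (3N − n_c)/2 kT within ~1%. Bead masses are uniform;
simulation time is therefore an internal unit, and all rates are later
rescaled to seconds against an experimental anchor, so absolute time
calibration is deliberately not load-bearing. The default step is
0.002 ps. Two conservative safeguards handle pathological geometries: the
dihedral potential is multiplied by smooth masks of the two bending
angles (the torsion is undefined at collinear bends and its torque
diverges there; the mask switches the term off, energy and gradient
together, below sin θ ≈ 0.14), and the excluded-volume pair force is
capped deep inside the core (beyond 10⁴ kJ mol⁻¹ nm⁻¹, a region only
transiently visited during hard collisions).

`Q = (1/N) Σ 1/(1 + exp[γ(r_ij − λ r⁰_ij)])` with γ = 50 nm⁻¹ and λ = 1.2
is both the reaction coordinate and the umbrella-bias variable; the bias
force is propagated through the smooth switching function by the chain
rule, so no auxiliary variable is needed. Umbrella sampling uses 16
windows evenly spaced on [0, 1], visited in ascending order with each
window seeded from the previous one's final configuration. The
production-scale spring constant is 600 kcal/mol; for the ~20-fold smaller
toy systems the per-contact bias forces at that stiffness destabilize the
integrator and the package's toy study conditions use 100 kcal/mol, which
gives the same window occupancy (the bias width scales as √(kT/k_umb) and
window overlap is explicitly checked, with a warning below 2% shared
histogram mass). WHAM solves the self-consistent equations on a 50-bin
grid to 10⁻⁷ kJ/mol in the window free energies and also returns binless
per-sample weights; `Q = 0.5` separates folded from unfolded states.

### Measuring the tether force

The instantaneous observable `ks(x − x₀)` is recorded per frame, but its
state-conditioned *scalar* mean is a biased estimator of chain tension: for
a 3D distance spring the radial shell entropy contributes `≈ 2kT/x₀`
(~21 pN at 291 K) even for a completely slack chain. The package therefore
also records the force *vector* along the tether and
`mean_state_forces()` reports the magnitude of the weighted mean vector:
when the chain is slack the direction decorrelates and the estimator
correctly reads ~0, while under load the direction is pinned and the
estimator equals the mean tension. The toy tunnel additionally encloses
its anchor in a narrow pocket (a "PTC collar"), mimicking the tight
peptidyl-transferase channel, which suppresses the transverse excursions
of the tethered end.

## From equilibrium to f_FL

Escape from arrest is modelled with the Bell expression
`k_e(F) = k₀ exp(β F Δx‡)` with `k₀ = 3.4 × 10⁻⁴ s⁻¹` and `Δx‡ = 0.32 nm`
(soft-validated against the experimentally admissible ranges
0.5–20 × 10⁻⁴ s⁻¹ and 0.1–0.8 nm). The four-state scheme has the arrested
states UA ⇄ FA exchanging with the folding/unfolding rates and escaping to
the absorbing states UR, FR at `k_e(F_u)` and `k_e(F_f)`; `f_FL(t)` is the
absorbed fraction at the incubation time (900 s by default, 1800 s for
30-minute incubations). The scheme is solved by rejection-free kinetic
Monte Carlo (BKL/Gillespie; the waiting time is `−ln u / Σk` — the
dimensionally consistent standard form) and cross-checked in the tests
against a matrix-exponential master-equation oracle. The preequilibrium
closed form `f_FL ≈ 1 − exp(−t[P_u k_e(F_u) + P_f k_e(F_f)])` is computed
alongside, and linker lengths where the two disagree by more than 0.05 are
flagged as violating the separation of timescales.

Simulated rates are much faster than experimental ones. `scale_rates()`
applies one global factor per rate type: unfolding is anchored so that the
scaled `k_u` at the largest L equals the isolated-domain experimental
unfolding rate (4.9 × 10⁻⁴ s⁻¹ by default), and the folding factor either
preserves the simulation model's per-L stability (default) or matches a
supplied experimental folding rate. Within the pipeline, unfolding MFPTs
are measured directly (with the censored maximum-likelihood estimator
`[N_ev t̄ + (N − N_ev) t_sim]/N_ev`) from an equilibrated folded start, and
folding rates follow by detailed balance with the umbrella-sampling
equilibrium constant, `k_f = k_u P_f/P_u`. At desk scale, direct folding
MFPTs are censoring-dominated wherever folding is slow, and the kinetic
scheme must share its equilibrium with the preequilibrium solution; the
detailed-balance construction guarantees both.

## Transition-path analysis

Folding transition paths run from the last frame below `Q = 0.3` to the
first frame above `Q = 0.7` (thresholds mirrored for unfolding harvests).
A contact counts as formed when `r < λ r₀` (strictly), the midpoint of the
smooth switching function. φ-values are per-residue means of the
TP-formation frequencies of that residue's native contacts; residues
without contacts are reported missing, never zero-filled. The fraction of
nonnative frames on TPs is `p(TP)_nn = 2 t_TP/(2 t_TP + t_F^mfpt)` for
folding harvests and `2 t_TP/(2 t_TP + (p_U/p_F) t_U^mfpt)` for unfolding
harvests, and the conditional contact importance follows by Bayes
inversion, `p(TP|q)_nn = p(q|TP) p(TP)_nn / p(q)_nn`, computed over
nonnative frames only (folded frames are excluded; for unfolding harvests
`p(q)_nn` is reconstructed as the `p(TP)_nn`-weighted mixture of TP and
unfolded frequencies). Values are clipped at 1 with a warning when
sampling noise exceeds the bound. Comparisons with reference φ-values
apply a |ΔΔG| > 7 kJ/mol filter before computing a Spearman rank
correlation, which is reported as undefined below 3 surviving pairs.

## The synthetic fixtures and what they do (and do not) show

Every stage is testable offline through three generators.

`make_toy_protein()` builds bead chains with defined native geometry and
contact maps: a compact hairpin (the default; two-state at 291 K with
`ε_c = 1.5` kJ/mol, exchanging many times per 10 ns so folding and
unfolding MFPTs are measurable), a wide hairpin (strand separation 0.8 nm,
used in the tethered family), flat sheets, a β-sandwich, and a helix pair.
A seeded 0.015 nm jitter breaks the planarity of the ideal geometries.

`make_toy_tunnel()` builds a cylindrical wall of immobile beads (open at
the exit, sealed at the buried end) with the anchor inside the PTC-like
pocket described above. Two deliberate departures from literal realism are
made so that a *sparse, single-shell* bead wall behaves like the densely
packed ribosome surface: wall beads repel the folded domain strongly
(ε = 100 kJ/mol) but the threading linker only weakly (ε = 0.02 kJ/mol).
The first makes the exclusion of the compact domain crisp (a soft sparse
wall would let a marginally wider object squeeze through by paying a few
kT); the second keeps the background confinement tension on the threaded
chain at a few pN, as in the much wider real tunnel. These are properties
of the fixture, not of the physical model: real-structure scaffolds use
the printed ε = 0.001 kJ/mol throughout and owe their impenetrability to
bead density.

The toy study conditions (`toy_study_config()`) fix the wide hairpin, a
6 nm × 1.0 nm tunnel, linker lengths 8–28, 250 ps production per umbrella
window, and four 0.6 ns unfolding replicas per L (about ten minutes on one
CPU). Under these conditions the family reproduces the qualitative
cotranslational mechanism: `P_f(L)` rises from ~10⁻¹⁹ to ~0.97, `F_f(L)`
falls from ~100 pN at the folding onset to ~22 pN at the longest linker,
and `f_FL(L)` has a single interior maximum near L = 20, where
substantial folded population coincides with a still-high folded-state
force. Passing these tests
shows that the machinery — sampling, reweighting, force estimation,
kinetics — composes correctly; it does not show that any particular real
protein folds at a particular linker length, which requires the
real-structure pipeline with experimental structures (hours to days of
CPU) and is out of desk-scale scope.

`make_synthetic_tp_ensemble()` emits labelled frame ensembles with exactly
known per-contact formation probabilities, so every transition-path
estimator can be checked against analytic ground truth (the `truth`
element) at 10⁵ frames.

## Numerical choices and degenerate inputs

* WHAM tolerance 10⁻⁷ kJ/mol, 50 bins; non-overlapping windows abort with
  per-window diagnostics. A single unbiased window degenerates to
  `−kT log(histogram)` exactly.
* An umbrella window that never reaches its target Q simply contributes
  zero weight there; a state with no reweighted samples yields `NA` forces
  with a warning and must enter the kinetics with population weight ~0.
* `mfpt_censored()` with zero events returns the censoring lower bound
  `N t_sim` flagged `censored_bound = TRUE`.
* Contact ties: a pair exactly at `λ r₀` is *not* formed; ranking ties in
  the mechanism report are broken lexicographically by (i, j).
* Trajectory divergence (non-finite energy or runaway coordinates) aborts
  with the step number rather than returning silently corrupted output.
* Seeds: every stochastic function takes an explicit integer seed and is
  bit-reproducible given it; the pipeline derives per-stage streams from
  one master seed.

## Known limitations

* The ribosome scaffold is rigid; induced-fit effects (e.g. displacement
  of ribosomal-protein loops by the folding domain) are outside the model.
* Escape kinetics are entirely phenomenological (Bell); arrest-peptide
  sequence identity enters only through `k₀` and `Δx‡`.
* The toy family's absolute force scale depends on its fixture parameters;
  only trends and mechanism structure are meaningful at desk scale.
* Post-release folding/unfolding before quantification is not modelled
  (the released states are absorbing).
* Electrostatics, solvent, and chemical detail of the tRNA linkage are out
  of scope.
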