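---
title: "A bottom-up kinetic model of rod phototransduction recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bottom-up kinetic model of rod phototransduction recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rodcascade)
```

# The model

`rodcascade` simulates the phototransduction cascade of a vertebrate rod
photoreceptor as a deterministic mass-action reaction network in a
well-stirred 1 pL outer-segment volume. Each elementary reaction contributes
its rate with stoichiometric signs to a system of ordinary differential
equations; species are tracked as molecule counts, except the two diffusible
second messengers (cGMP and free Ca²⁺), which are tracked in micromolar
concentration with explicit conversion (1 µM ≙ 6.02214×10⁵ molecules per pL)
wherever a reaction couples the two representations.

The network has four tiers:

1. **Receptor front end.** Photoisomerized rhodopsin (R\*) activates
   transducin (Gt). A fraction of Gt is precoupled to dark rhodopsin, and the
   affinity of R\* for Gt decays exponentially with the number of attached
   phosphates, kG1(n) = kG1₀·exp(−ω·n). GDP release, GTP uptake and
   Gα/Gβγ dissociation are lumped into a single exchange step.
2. **Receptor shutdown.** Rhodopsin kinase (RK) binds R\* with an affinity
   that *declines linearly* with phosphorylation and is extinguished at five
   phosphates (slope kRK1₀/5); arrestin (Arr) binds with an affinity that
   *rises linearly* over the first four phosphates and then plateaus.
   Arr binding quenches R\*; the complex releases Arr slowly after receptor
   deactivation. RK binding itself does not block transducin activation
   (the kinase engages the phosphorylated C-terminus, not the G-protein
   interface), so kinase-complexed R\* keeps signaling at its
   phosphorylation-indexed rate.
3. **Effector shutdown.** Gα·GTP activates the two catalytic subunits of PDE6
   sequentially. RGS binding (kRGS1) followed by fast GAP-accelerated
   hydrolysis terminates each active subunit; a slow spontaneous shutoff
   (kPDE_shutoff) runs in parallel. This tier is rate-limiting for recovery,
   which is why the dominant time constant τ_D tracks RGS expression.
4. **Second-messenger back end.** Active PDE hydrolyzes cGMP; synthesis is
   Ca²⁺-inhibited through an implicit-GCAP Hill term; the CNG current follows
   (cGMP/cGMP_dark)³, and Ca²⁺ enters through the channels, is extruded by an
   exchanger and buffered by an anonymous buffer pool plus, explicitly,
   recoverin.

Two mechanisms receive an explicit elementary treatment:

* **Ca²⁺/recoverin feedback on RK.** Tense recoverin binds one free Ca²⁺ ion
  and relaxes (kRec1 = 0.011 µM⁻¹s⁻¹, kRec2 = 0.05 s⁻¹); relaxed recoverin
  sequesters RK (kRec3 = 9.69 µM⁻¹s⁻¹ converted to per-molecule units at
  1 pL, kRec4 = 0.61 s⁻¹). Because recoverin now buffers Ca²⁺ explicitly, the
  anonymous buffer capacity eT is reduced by the total recoverin
  concentration (33.1 µM), which keeps the dark free-Ca²⁺ balance unchanged.
  One Ca²⁺ per recoverin is used, exactly as the rate law is written, even
  though two ions bind biologically.
* **Arrestin storage oligomers.** Two monomers form a dimer and two dimers a
  tetramer, both steps with kA4 = 1.787×10⁻⁸ (per molecule·s) forward and
  kA5 = 0.646 s⁻¹ reverse, encoding the imposed 60 µM dissociation constant
  in a 1 pL compartment. At 3×10⁸ total molecules the dark split is ≈13%
  monomeric, 27% in dimers, 60% in tetramers. An optional variant multiplies
  kA4 by exp(ω_Arr·(Ca/Ca_dark − 1)); the printed description of this
  exponent is ambiguous, so the package uses this normalized form, keeps the
  mechanism off by default (ω_Arr = 0), and treats the exact form as
  unresolved.

# The backbone constant table

The backbone tiers (1, 3, 4) descend from an earlier comprehensive amphibian
rod model whose full supplementary constant table is not reprinted in the
source for the present mechanisms. `BASE_PARAMS_v1` is therefore a
**synthetic reconstruction**, built and frozen as follows:

* every constant that *is* printed for the present model is used verbatim
  (kG1₀, kRK1₀, m_RK = kRK1₀/5, kArr, m_Arr, kA2, kA3, kA4, kA5, kRGS1,
  kPDE_shutoff, kRec1–kRec4);
* total pools that follow from printed dark steady states are used directly
  (3×10⁸ Arr; 2.0×10⁷ Rec = 33.1 µM; 4.07×10⁶ RK from the printed
  RecR_Ca·RK pool plus the free-RK value implied by the kRec3/kRec4
  equilibrium);
* dark free Ca²⁺ is 0.6 µM, the top of the physiological dark range and the
  value implied by the printed recoverin pools through the reaction-1
  equilibrium (kRec2·RecR_Ca/(kRec1·RecT) ≈ 0.603 µM);
* the remaining backbone constants (pool sizes of the front end, the RK
  catalytic cycle, the Gt exchange step, the cGMP/Ca²⁺ back end) were set to
  canonical amphibian-rod magnitudes and then calibrated once against the
  model's printed wild-type recovery characteristics and dosage-response
  patterns (wild-type dominant time constant, the RGS and RK
  expression-series patterns, and response saturation near ~200 R\* per
  flash). They are literature-scale constants chosen by the package, not a
  transcription, and the file documents each entry.

Printed bimolecular constants carry s⁻¹ units although they multiply pairs of
molecule counts; the package interprets them as per-molecule-per-second
constants acting on counts. This convention is validated by the kA5/kA4
ratio, which reproduces the 60 µM dissociation constant only on the count
scale.

A note on one printed inconsistency: the source's dark-state table lists
8×10³ free RK molecules, but the printed kRec3/kRec4 equilibrium together
with the printed RecR_Ca and RecR_Ca·RK pools implies ≈8.1×10⁴. The package
solves the dark state from the rate constants rather than forcing the printed
row, and treats the free-RK row as unreliable.

# Numerical contract

* Stiff adaptive integration (LSODA) with rtol 10⁻⁸ and atol 10⁻¹² on the
  molecule-count scale; the derivative function is evaluated in C from a
  packed network description, with a pure-R implementation kept as a
  reference (the two agree to ~10⁻¹⁵ along trajectories).
* Stimuli are time-gated first-order photoactivation terms applied to both
  free and precoupled rhodopsin; a flash is a constant R\*-production window
  of 24 ms, not a delta function. Trajectories are integrated piecewise
  between gate discontinuities with the solver restarted at each boundary
  (`tcrit` prevents stepping across a gate).
* Dark states are computed analytically tier by tier (precoupling quadratic,
  coupled Rec/RK root, oligomer closure root, buffer and cyclase balances)
  and verified as fixed points (scaled residual < 10⁻⁷).
* Output is resampled to a fixed grid: 1 ms by default, 2–5 ms in the
  long batch sweeps; descriptor values interpolate linearly between samples,
  so the coarser grids change T_sat by well under 1 ms.
* Conservation of every protein pool (weighted by subunit multiplicity) is
  monitored; residuals stay below 10⁻⁶ relative on all shipped protocols.

# Descriptors and the standardized Pepperberg procedure

* **T_sat** — the length of the contiguous interval with ΔJ/J_dark ≥ 0.9,
  crossings linearly interpolated. Traces that never reach 0.9 are reported
  as "not saturating" (NA), never as zero.
* **τ_rec** — least-squares single-exponential time constant over the window
  from 50% to 99% recovery of the peak; this operationalizes "the second
  half of the recovery phase", which has no printed numerical definition.
* **τ_D** — ordinary least-squares slope of T_sat against the *natural*
  logarithm of flash strength over the first four saturating points of a
  standardized half-log ladder (10^2.5 … 10^6 R\*/flash, identical for every
  genotype). Normalized values divide by the wild-type slope measured
  identically, so the wild-type entry is 1 by construction.

The mutant engine scales total protein pools (never individual dark
sub-pools), applies mechanism switches, and re-solves the dark steady state
before any stimulus, so all dark pools of a scaled protein re-partition
through the equilibria. The anonymous-buffer reduction for explicit
recoverin buffering is kept at its wild-type value under mutants: the engine
scales proteins, not the buffer bookkeeping. Disabling oligomerization sets
kA4 = 0 *and* places the whole arrestin complement in the monomer pool at
dark, the interpretation consistent with the large non-recovering monomer
reservoir the disabled-oligomerization simulations display.

# Problem sizes

The shipped analyses use: 56 species and ~130 reactions; flash horizons of
10–60 s (extended automatically until saturating responses recover below 10%
suppression); ladders of up to eight half-log flash strengths per genotype
with early exit after the fourth saturating point; and a 13-genotype sweep
for the expression-series table. A single 30-second flash response takes
well under a second; the full sweep takes a few minutes.

# What the simulations do and do not show

The simulated-experiment recipes reproduce *model-to-model* quantities:
steady states, descriptor tables and dosage patterns. They are not fits to
digitized electrophysiological recordings, and species differences (the
backbone is amphibian-parameterized, many reference experiments are murine)
are handled only by the crude convention of doubling mouse-derived stimulus
intensities. Within that scope, the package reproduces the dark arrestin
statistics analytically, the RGS dosage series, the recoverin
knockout/overexpression pattern, arrestin dosage insensitivity, and the
oligomerization-dependent capping dynamics.

Known limitations, deliberately not patched:

* The reported small *increase* of τ_D under 2–3× RK overexpression is
  attributed by the source to monomeric-arrestin availability. At the
  printed pool sizes the monomer pool (3.8×10⁷) exceeds even the brightest
  stimulus's arrestin demand (1.2×10⁵) by ~300-fold, so capping never
  becomes storage-limited in this implementation and the overexpression rows
  come out just below, rather than just above, wild type (within ±12%).
  For the same reason the 3×RK/0.2×RGS double mutant lands ~15–18% below its
  reported normalized value: with the printed kRGS1 and kPDE_shutoff, the
  ratio of effector shutoff rates between wild type and 0.2× RGS is bounded
  by (a + kPDE_shutoff)/(0.2a + kPDE_shutoff) < 5 at a = kRGS1·RGS_total,
  i.e. ≈4.5 under this parameterization, and only fit-window curvature can
  exceed it.
* Under a steady non-saturating background, the model reproduces reduced
  incremental sensitivity but not the shortening of T_sat for a
  superimposed saturating flash: the background's standing effector
  activity raises the effector level below which the current recovers above
  the saturation criterion, and in this backbone that bookkeeping effect
  slightly outweighs the recoverin-mediated acceleration of receptor
  shutdown. The adaptation behavior of T_sat therefore should not be
  trusted quantitatively.
* Light-dependent translocation of Arr/Rec/Gt, phosducin, calmodulin,
  explicit GCAP binding, opsin regeneration and spatial structure are out of
  scope, as in the source model.
* The Ca²⁺-dependent oligomerization variant is implemented in a normalized
  exponential form because the printed formula cannot be recovered
  unambiguously; it is off by default and shipped only as a switch.
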