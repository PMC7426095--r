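---
title: "A mass-action model of post-synaptic plasticity in a cortical spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of post-synaptic plasticity in a cortical spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spinedyn` simulates the biochemistry of a single well-mixed dendritic
spine head (0.5 µm³) as a deterministic mass-action reaction network of
185 species and 207 elementary reactions, grouped in a 140-row reaction
table. Three kinase pathways connect the model's four external inputs —
Ca²⁺, β-adrenergic ligand (`L`), glutamate (`Glu`) and acetylcholine
(`ACh`), all delivered as particle fluxes — to the phosphorylation and
trafficking of AMPA-receptor subunits:

* **CaMKII pathway.** Ca²⁺ loads calmodulin in three steps (2 + 1 + 1
  ions); CaMCa₄ activates CaMKII subunits, which pair and
  trans-autophosphorylate, yielding an autonomous kinase that
  phosphorylates GluR1 at S831 (raising the single-channel conductance of
  GluR1 homomers).
* **PKA pathway.** The β-adrenergic receptor activates Gs; Gs-coupled
  adenylyl cyclases (AC1, requiring CaMCa₄; AC8) produce cAMP; four cAMP
  release the catalytic PKA subunit, which phosphorylates GluR1 at S845
  and thereby switches GluR1 to a fast membrane-insertion regime
  (membrane fraction 1/5 without S845 phosphorylation, ~4/5 with it).
  Negative feedback runs through receptor phosphorylation (ultimately
  coupling to Gi), PDE4 phosphorylation, and CaM-activated PDE1.
* **PKC pathway.** Glutamate-bound mGluR and ACh-bound M1 receptors
  activate Gq; Ca- and Gq-bound PLC hydrolyses PIP₂ into DAG and IP₃;
  Ca + DAG transiently activate PKC, and arachidonic acid (from
  Ca-activated PLA2) converts it to a persistently active form. Active
  PKC phosphorylates membrane GluR2 at S880, which switches GluR2 to a
  fast-endocytosis regime; internalised S880-GluR2 is dephosphorylated by
  PP2A and recycled.

Phosphatases PP1 and PP2B (calcineurin, activated by Ca-loaded CaM)
reverse the GluR1 phosphorylations; inhibitor-1 couples the PKA and PP1
arms.

Concentrations are held in nM and time in ms throughout; user-facing
protocol constructors accept seconds where their arguments are naturally
protocol-scale. Particle fluxes convert to concentration rates by
1 particle ≈ 3.32 nM in 0.5 µm³.

## The synaptic conductance model

Receptor tetramers are not tracked kinetically — with 28 subunit states
the combinatorics are prohibitive, and tetramer assembly kinetics are
deliberately out of scope. Instead a statistical model maps the
membrane-bound subunit pools (N₁ GluR1 subunits, N₁,ₚ of them
S831-phosphorylated, N₂ GluR2 subunits) to expected tetramer-class
counts. Under the random-assembly rule the probability of a
non-phosphorylated GluR1 homomer is (N₁−N₁,ₚ)⁴/(N₁+N₂)⁴, of a
phosphorylated GluR1 homomer (N₁⁴−(N₁−N₁,ₚ)⁴)/(N₁+N₂)⁴, of a GluR2
homomer N₂⁴/(N₁+N₂)⁴, and heteromers take the rest. The power form
approximates a four-subunit draw without replacement; `spinedyn`'s test
suite checks it against exhaustive hypergeometric enumeration and its
convergence as N₁+N₂ grows. The total maximal synaptic conductance is

g_syn = (N₁+N₂)/4 · (12.4 pS·p_hom1 + 18.9 pS·p_hom1,phos + 2.2 pS·p_hom2 + 2.5 pS·p_het),

with the tetramer count left real-valued (a floored variant is available
behind a flag). An alternative dimer-of-like-dimers rule — subunits
dimerise at random and tetramers form only from like dimer pairs,
renormalised over the three like-pair events, which forbids 1:3 and 3:1
heterotetramers — is provided for sensitivity analyses; with a 35:65
GluR1:GluR2 balance it reproduces the same qualitative plasticity. The
"phosphorylated homomer" share under this rule applies the quartic
phosphorylated-fraction split within the GluR1 homomer class; exact
supplementary formulas for this rule were not available, so this
renormalisation is a declared package decision validated qualitatively.

Enzyme-bound membrane receptors count as membrane subunits (the subunit
remains in the membrane while a kinase or phosphatase is attached).

## Model definition, groups, and provenance

The reaction table ships in `inst/extdata/` as three TSV files: the
species inventory with initial concentrations, the 140-row grouped
reaction table, and the group-membership table that expands placeholder
rows (e.g. one row for "PP1 binds S845-phosphorylated GluR1" expands to
the four membrane/internal × singly/doubly-phosphorylated variants).
`load_model()` expands, validates and checks the result against a frozen
manifest (species/reaction counts and an MD5 fingerprint); expansion is
idempotent and byte-reproducible.

Where the published grouped table leaves memberships implicit, this
package's memberships were reconstructed from the pathway mechanisms.
The choices that matter most, made once and documented here:

* S845 phosphorylation by PKAc acts on internal GluR1 (insertion then
  carries the subunit to the membrane); S831 phosphorylation by
  CaMKII/PKC acts on membrane GluR1; PP1/PP2B dephosphorylate GluR1 in
  **both** pools (they are cytosolic enzymes and internal S845
  phosphorylation would otherwise be unopposed).
* PKC phosphorylates membrane GluR2; PP2A dephosphorylates internalised
  S880-GluR2 only (the classic phosphorylate → endocytose →
  dephosphorylate → recycle loop).
* The receptor-desensitisation ladder phosphorylates both free and
  ligand-bound β-receptors with the printed rate accelerations, and the
  Gq GTPase acts on both Ca-bound and Ca-free PLC–Gq complexes.
* The PKA dissociation reaction's backward rate law is proportional to
  [PKAr]·[PKAc] (not [PKAc]²) while still returning two catalytic
  subunits per event, per the published footnote.

Every closed molecular family (34 of them: receptor totals, G-protein
subunits, kinases, phosphatases, buffers, adenine nucleotides, GluR1/2
subunits, ...) is verified symbolically at load time
(w·S = 0 against the stoichiometric matrix) and numerically along
trajectories (relative drift < 10⁻⁶ over a stimulated run).

## Stimulation protocols

All induction protocols deliver 3-ms Ca pulses of 1900 particles/ms,
each accompanied by 3-ms pulses of β-ligand (10), glutamate (20) and
acetylcholine (20 particles/ms): HFS (100 pulses at 100 Hz), 4xHFS (four
HFS trains separated by 3 s), LFS (900 pulses at 5 Hz), LFS-1Hz (1800
pulses at 1 Hz) and 6xHFSt (six theta-burst trains of 10 × 4 pulses).
Square-pulse experiments apply 5-min constant fluxes; the neuromodulator
amplitudes of the square-pulse experiments are not fully pinned down by
the source material, so the pulse-train values (10/20/20) are the
defaults and all are arguments. Bath application injects a ligand at
50 particles/s for 10 min starting 8 min before a protocol.

Spike-timing protocols tile a per-pairing Ca flux waveform at 1 Hz for
2 min. Waveforms can be imported from two-column text files (ms,
particles/ms) — the intended quantitative route, fed by a biophysical
neuron model — or generated by `synth_nmdar_trace()`, an explicitly
synthetic stand-in: a double-exponential NMDAR-like conductance whose
Mg-gate is relieved during the post-synaptic burst window (ramping up
over the ~30 ms spike burst), with a saturation cap so that
near-coincident pairings clip in peak while still differing in integral.
Its defaults (peak 3000 particles/ms — the scale of a few-pA NMDAR
current with a ~10% Ca fraction — rise 15 ms reflecting receptor
occupancy build-up, decay 50 ms, 60-ms post window, cap 2500) make a
coincident 2-min pairing train deliver a total Ca load of the same order
as the induction protocols, while an anti-causal pairing delivers far
less; they are parameters, not calibrated quantities, and conclusions
drawn from the synthetic sweep are qualitative (orderings), never
quantitative.

## Numerics

The stiff ODE system (rate constants span 1.6·10⁻¹⁵ to 20 ms⁻¹) is
integrated with `deSolve` using an analytic Jacobian assembled from the
mass-action rate laws. The default method is adaptive per segment: the
implicit BDF solver (`vode`) for short, event-dense pulse segments, where
its cheap restarts dominate, and `lsoda` (automatic stiff/non-stiff
switching) for long smooth stretches — equilibration, bath phases,
post-stimulus tails — where it is roughly an order of magnitude faster
and more robust on strongly rescaled networks. Pulse edges are hard discontinuities:
the integrator restarts at every edge rather than relying on step
rejection, so a 900-pulse LFS cannot silently step over 3-ms pulses.
Default tolerances are rtol = 10⁻⁶, atol = 10⁻⁶ nM; the suite checks
that halving rtol moves post-protocol states of all species above
10⁻³ nM by < 0.1%. Tiny negative excursions (< 0.1 nM) from the
implicit steps are clamped to zero silently, larger ones warn, and
excursions beyond 1 nM abort the run. Equilibration integrates 4040 s
without inputs on a logarithmic output grid and reports the residual
|d[X]/dt| as a flatness diagnostic; the resulting state is a fixed point
to solver tolerance.

A stochastic simulation mode is deliberately not provided: the
deterministic trajectories are the package's acceptance surface, and
mesoscopic stochastic reproduction is a non-goal.

## Experiments, classification, scans

`run_plasticity_experiment()` equilibrates, stimulates and reports
g_syn(t)/g_syn(rest) at requested minutes after protocol onset, plus
membrane GluR1/GluR2 levels, the S880-phosphorylated GluR2 fraction and
the peak free Ca. Plasticity curves evaluate 5-min square pulses at 0,
50, 150 and 250 particles/ms and classify the 250-response into 16
classes of width 0.36 starting at 0.16 (the observed response range
0.16–5.92); class 6 is therefore [1.96, 2.32). (The printed verbal gloss
"132–168% LTP" for class 6 is arithmetically inconsistent with these bin
parameters and the reported subclass centre 2.24; the bin formula is
authoritative here.) A BCM-type curve is one whose 50- or
150-particles/ms response is depressing while the 250 response
potentiates. Parameter scans draw GluR1 ratio ~ U(0,1) and NCX/PKA/PKC
factors ~ U(0,2) (plain uniform sampling under a caller-supplied seed;
the sampling scheme was an open choice) and exclude samples whose free
Ca exceeds 2 µM. The robustness scan perturbs each of the 47 nonzero
initial concentrations and each nonzero rate of the grouped table
(perturbing a grouped rate moves all expanded members together) by ±10%
and flags parameters that change the LTP/LTD amplitude |g_rel − 1| by
more than 15% of its default value; at full scale (two protocols, ~270
parameters, ~1100 simulations) this is an overnight job, and the test
suite exercises it on small parameter subsets.

Measurement times follow the conventions of the underlying experiments:
15 min after onset for plasticity curves, 16 min for robustness/STDP
outcomes, and LFS checkpoints 15 min after the end of the 180-s
protocol; all are explicit arguments.

## Fitting

`nsga2_fit()` fits per-pulse input amplitudes (Ca, β-ligand, glutamate —
ACh follows the glutamate amplitude) and the concentration scalers to
the packaged table of cortical LTP/LTD measurements (11 datasets:
entorhinal, prefrontal, barrel, anterior cingulate, visual, auditory
cortex; targets at 10/15/20 min with a pooled SD; burst notations
parsed as trains of 100-Hz pulses at the base frequency, and the
visual-cortex LFS rows using the reduced 180 × 15 ms @ 1 Hz
substitution). One objective per experiment (mean absolute target error
over available times, missing 10-min targets simply omitted) plus a
penalty objective for free-Ca transients above 2 µM. The optimiser is a
self-contained NSGA-II (fast non-dominated sort, crowding distance,
binary tournament, SBX crossover η=15, polynomial mutation η=20),
reproducible from its seed; "acceptable" parameter sets fit every
experiment within one SD on average. Desk-scale defaults are population
64 × 5 generations; the full-scale setting (1000 × 20) is configuration
only, and the published acceptance percentages at that budget are not
asserted anywhere in the package. The objective takes a pluggable
predictor, which the test suite uses to run optimiser-behaviour and
parameter-recovery checks against fast surrogates while the
simulation-backed path shares all remaining code.

## What the tests do and do not show

The test suite verifies the resting-state calibration (baseline
conductance ≈ 33 pS from the trafficking equilibria; 45% membrane GluR2),
the Ca-binding kinetics (buffers/pumps saturate in under 2 s, CaM in
tens of seconds), the BCM-shaped square-pulse triple, LFS-induced
depression with S880 phosphorylation and 4xHFS-induced potentiation, the
knockout/blockade directions (no LTP without GluR1, Ca or β-input; no
LTD without GluR2; PKC blockade weakens LTD and trims LTP via the
GluR1-homomer effect), and the spike-timing property that outcomes track
the total rather than the peak Ca input. Simulated protocols are the
real ones; where a test is labelled desk-scale (scans, fitting budgets,
shortened pairing trains) it checks machinery and directions, not
published magnitudes. Synthetic Ca traces do not emulate dendritic
nonlinearities, SK-channel feedback, or stochastic vesicle release, so
quantitative spike-timing magnitudes are outside what passing tests
demonstrate.

Known limitations: the group memberships of the published reaction table
had to be reconstructed from mechanism (see above); the persistent-PKC
tone after pulsed protocols, and with it the S880 level measured 15 min
after LFS and the exact square-pulse responses at 150–250 particles/ms,
are sensitive to those choices and sit below/above their published
values respectively (the package reports what it computes); plasticity
does not feed back onto the Ca²⁺ inputs; and the spine is a single
well-mixed compartment with no diffusion.
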