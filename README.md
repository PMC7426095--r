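# spinedyn

Biochemically detailed modelling of post-synaptic plasticity in a
cortical dendritic spine.

`spinedyn` is for computational neuroscientists and systems biologists
who want to ask *mechanistic* questions about cortical LTP and LTD: which
kinase pathway carries a given induction protocol, what happens to the
synapse when a protein is over- or under-expressed or pharmacologically
blocked, and how the balance of GluR1 and GluR2 AMPA-receptor subunits
shapes the sign and size of plasticity.

The core of the package is a deterministic mass-action reaction network
of a single 0.5 µm³ spine head — 185 species, 207 elementary reactions
from a 140-row grouped table — coupling four external inputs (Ca²⁺,
β-adrenergic ligand, glutamate, acetylcholine; particle fluxes) to three
signalling pathways:

* **CaMKII**: Ca²⁺ → calmodulin (three-step loading) → CaMKII
  autophosphorylation → GluR1-S831 phosphorylation (higher GluR1-homomer
  conductance);
* **PKA**: β-receptor → Gs → AC1/AC8 → cAMP → PKA → GluR1-S845
  phosphorylation (fast membrane insertion of GluR1);
* **PKC**: mGluR/M1R → Gq → PLC → DAG (+ arachidonic acid →
  persistent PKC) → GluR2-S880 phosphorylation (fast endocytosis of
  GluR2).

A statistical AMPAR-tetramer model turns the membrane-bound subunit
pools into a total maximal synaptic conductance: with N₁ membrane GluR1
subunits (N₁,ₚ S831-phosphorylated) and N₂ membrane GluR2 subunits,
tetramer-class probabilities are the quartic forms
p₁ = (N₁−N₁,ₚ)⁴/(N₁+N₂)⁴, p₁ₚ = (N₁⁴−(N₁−N₁,ₚ)⁴)/(N₁+N₂)⁴,
p₂ = N₂⁴/(N₁+N₂)⁴, p_het = 1 − N₁⁴/(N₁+N₂)⁴ − N₂⁴/(N₁+N₂)⁴, and

    gsyn = (N1+N2)/4 * (12.4 p1 + 18.9 p1p + 2.2 p2 + 2.5 p_het) pS.

On top of the simulator the package provides the standard induction
protocols (HFS, 4xHFS, LFS, theta-burst, square pulses, bath
application, spike-timing pairings driven by imported or synthetic Ca
traces), named manipulation presets (pathway blockades,
phosphorylation-site-deficient receptors, subunit knockouts),
plasticity-curve classification, ±10% robustness scans, and
multi-objective (NSGA-II) fitting of concentration scalers to a packaged
table of cortical LTP/LTD measurements.

## Worked example

```r
library(spinedyn)

net  <- load_model()          # packaged network, validated + fingerprinted
rest <- equilibrate(net)      # 4040 s without inputs

gsyn_from_state(rest, net)
#> [1] 33.46077                # resting synaptic conductance, pS

sum(rest[grep("^GluR2_memb", names(rest))])
#> [1] 121.4963                # membrane GluR2 at rest, nM (45% of 270)

# low-frequency stimulation: 900 Ca pulses at 5 Hz -> depression
lfs <- run_plasticity_experiment(net, make_lfs(),
                                 measure_times_min = 18, eq_state = rest)
lfs
#> <plasticity_outcome> baseline 33.46 pS; relative conductance: 18 min: 0.879

# 4xHFS: four 100-Hz trains -> potentiation via GluR1 insertion
hfs <- run_plasticity_experiment(net, make_4xhfs(),
                                 measure_times_min = 16, eq_state = rest)
hfs
#> <plasticity_outcome> baseline 33.46 pS; relative conductance: 16 min: 2.832
```

The LFS run depresses the synapse (relative conductance 0.879: GluR2
subunits are S880-phosphorylated and endocytosed while GluR1 is
untouched), and 4xHFS potentiates it strongly (2.83×: S845-driven GluR1
insertion plus GluR2 endocytosis shift the membrane toward
high-conductance GluR1 homomers). Blocking the β-adrenergic input
(`apply_manipulation(net, "no_beta")`) abolishes the LTP but not the
GluR2 endocytosis; a GluR1-free synapse
(`apply_scalers(net, concentration_scalers(glur1_ratio = 0))`) cannot
potentiate at all.

## Package layout

* `inst/extdata/` — the model definition (species, grouped reactions,
  group memberships) plus frozen manifest, and the cortical LTP/LTD
  fitting table.
* `R/` — network loading/validation, the stiff ODE engine, protocols,
  the tetramer conductance model, experiment drivers, scans, NSGA-II
  fitting, serialisation.
* `vignettes/spine-plasticity-model.Rmd` — the model, its assumptions,
  numerical choices, and known limitations.
* `inst/scripts/run_protocol.R` — thin command-line wrapper to simulate
  one protocol and export a tidy trajectory.
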