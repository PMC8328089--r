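---
title: "acrodyn: model, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{acrodyn: model, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrodyn)
```

## The model

`acrodyn` models the signaling network of the human sperm acrosome reaction
(AR) as a multi-valued logical network under synchronous, deterministic
update. The network state at time $t$ is $X(t) = (x_1(t), \dots, x_N(t))$,
each node taking integer levels $0 \dots M_x$ (most nodes are binary; the
membrane potential `Em` has four levels, and `CatSper`, `Ca_i` and `pH_i`
three). Every non-input node carries a complete truth table $F_i$ over its
regulators and all nodes update simultaneously:

$$x_i(t+1) = F_i\big(x_{i_1}(t), \dots, x_{i_k}(t)\big).$$

Input nodes (the external stimuli `A23187`, `Pg`, `Ca_o`, `HCO3_o`) hold
their value. Because the dynamics are deterministic on a finite space,
every trajectory enters an attractor — a fixed point or a limit cycle —
and state space partitions exactly into basins of attraction.

Three functional classes summarize what an attractor means for a cell
(computed with the progesterone input off): **Spontaneous** attractors
contain a fusion state (`Fusion = 1`); **Inducible** attractors reach
fusion only after the `Pg` input is switched on; **Negative** attractors
never fuse. This classification, together with clamping experiments
(holding a node fixed during all updates, the in-silico analog of a
pharmacological block) and transient perturbations (a one-time edit of one
node's level), is the package's analysis vocabulary.

## The bundled AR network is a reconstruction

The bundled model (`ar_network()`) has the published structure — 38 nodes,
87 signed interactions, four inputs, the `Fusion` reporter, the exact
multi-level node semantics — but its truth tables are **reconstructed**
from the narrative description of the pathway (bicarbonate uptake and sAC
activation, sNHE/Hv pH regulation, the acidic acrosomal lumen maintained by
a V-ATPase against a proton leak, CatSper's pH- and voltage-dependence,
store-operated calcium entry downstream of STIM, the biphasic IP3
receptors, the cAMP/EPAC/Rap/Rab3A branch of the fusion machinery, and the
SNARE/synaptotagmin fusion core). The original supplementary truth tables
were not available in machine-readable form. Every function in
`inst/extdata/ar_network.json` is therefore marked
`provenance = "reconstructed"`, and the file is data: corrections are
edits to the JSON, never code changes.

Calibration policy: during development the tables were exercised against
the *directions* of the 26 published experimental comparisons and the
qualitative clamping claims. No quantity was ever tuned against a printed
number. The consequences are visible in the acceptance tests:

* Structural facts, the absence of fixed points, the clamp class
  structure, and the basal-level exactness of Inducible attractors hold.
* Attractor *counts* (the published 36 at `Pg = 0`, 8 and 10 under the two
  `pH_a` clamps) are properties of the original tables; the reconstruction
  yields different counts (around 90, 22 and 2 respectively) and the
  corresponding test is expected to fail until the original tables can be
  transcribed into the network file.
* Of the 26 battery rows, 23 agree in direction here. The two acrosomal-pH
  rows with printed effects of a few percent (`Capacitation` and `DIDS`)
  read as "no change" because the reconstructed `pH_a` homeostat has a
  condition-independent duty cycle; and the xestospongin-C + progesterone
  row *agrees* with experiment here whereas the published model famously
  failed it — our single pooled `Ca_i` node cannot separate flagellar from
  head calcium, which is the mechanism the published failure hinges on.

## Why there are no fixed points

The acrosomal pH block is wired as a pump/leak homeostat: the V-ATPase
engages one step after the lumen alkalinizes, the proton leak one step
after it acidifies, and the lumen responds to both with a one-step lag.
Under synchronous update this two-node negative loop has no stable state —
a fixed point would need the pump simultaneously on and off — so *every*
attractor of the full network is a limit cycle, reproducing the model
family's signature behavior. The homeostat also provides the time base
against which "sustained" acrosomal alkalinization is defined (below).

## Key design decisions

**Irreversible fusion.** `Swell` and `Fusion` latch (their truth tables
contain a self-term): exocytosis and acrosomal swelling are morphologically
irreversible. Two consequences follow. First, attractor discovery restricts
its random restart states to `Fusion = Swell = SNARE = 0` (the
`constraints` argument, overridable): states born fused are biologically
unreasonable and would flood the landscape with trivially fused attractors.
The same restriction defines the population ensembles. Second, Spontaneous
attractors survive acidic `pH_a` clamping of their own states — fusion that
has happened stays happened — which is exactly the published behavior of
the milder, attractor-state clamping experiment.

**Sustained vs oscillatory alkalinization.** Weak-base-type calcium release
from the acrosome should fire when the lumen is *held* alkaline (a clamp,
a V-ATPase block), not on every alkaline phase of the free-running
homeostat. The release term `pH_a == 1 & HLeak_a == 0` implements this:
the leak is off one step after an alkaline phase, so the conjunction means
"alkaline now and one step ago". Free-running dips of the store last a
single step and are refilled by the compensating ACA pump before the
store-depletion detector (`STIM` high and store still empty, again a
two-step conjunction) can open the store-operated channels.

**Capacitation as a bistable latch.** The cAMP → sNHE → pH_i → sAC → cAMP
positive loop has two stable regimes under capacitating medium: an acidic,
cAMP-free, hyperpolarized quiescent state (the uncapacitated lock, which
progesterone cannot move because CatSper requires an alkaline cytosol) and
an alkaline, cAMP-high state from which progesterone triggers fusion. This
bistability, together with the filled/depleted states of the two calcium
stores and phase relations between the oscillating subsystems, generates
the attractor multiplicity and the three functional classes.

**Classification across phases.** When a non-fusing attractor is tested
for inducibility, the progesterone input is switched on from *every* phase
of the cycle; the attractor is Inducible if any phase reaches fusion, and
phase disagreement is recorded in the landscape's `class_log` rather than
hidden. The attractor-state clamping experiment likewise runs from every
phase, reports the canonical phase's fate and logs the rest.

**Persistent attractor-state clamps.** `clamp_attractor_states()` holds
the clamp from the moment of application onward (a sustained change of
condition once the cell has settled), because the class conversions the
experiment is about require the acrosomal pH to stay where it was put. A
`one_shot` variant (edit once, relax freely) exists for sensitivity
analysis.

**Stratification weights.** The observed AR proportions quoted for
spontaneous/inducible/negative sperm are 15, 30 and 65% — which sum to
110%. The default normalizes them to fractions (0.136/0.273/0.591); mode
`"rescale_negative"` instead keeps 15/30 exact and lowers the negative
share to 55%. Every population records which mode produced it. Stratified
sampling is by rejection against the basin class of each candidate state —
basins cannot be enumerated at $1.9\times10^{12}$ states — which by
construction cancels any effect of relative basin sizes.

**Response metric.** The battery metric is the difference, in percentage
points, of population mean activation of the readout node over attractor
states, condition minus baseline. Activation of node $x$ means
$x > M_x/2$. A dead band of ±0.5 points reads as "no change"; printed
comparisons like "NNC vs Ionomycin" are condition-vs-condition deltas. The
pharmacology-to-node mapping (DCCD → V-ATPase off, DIDS → SLC off, NNC →
`pH_a` alkaline, XC → both IP3R pools off, thapsigargin → ACA off, cAMP
analog / 8-pCPT / Rab3A → the respective node held active) is bundled as
editable JSON, since it is the largest unstated degree of freedom in this
kind of comparison.

## Numerical and engineering choices

* States pack into mixed-radix integers (declared node order, first node
  most significant); the packed key of the canonical (smallest-key-first)
  rotation of a cycle is the attractor's identity. State spaces are
  validated below $2^{53}$ so keys are exact doubles.
* Cycle detection uses a visited-state hash record, which yields the
  transient length for free; `max_steps = 10000` is orders of magnitude
  above observed transients and failing it raises an error rather than
  looping.
* Discovery stops after `n_confirm = 1e5` consecutive non-novel restarts
  (cheap, since trajectories are short) and flags — never hides —
  non-convergence.
* The exhaustive oracle (`brute_force_landscape()`) enumerates successor
  arrays with memoized attractor labels, bounded by a $2^{20}$-state
  budget, and is the reference the sampling machinery is tested against on
  random fixtures (attractor sets and basin partitions must match exactly
  under full-coverage restarts).
* The engine inner loops are C++ (Rcpp); all randomness flows through R's
  RNG, so a seed fixes every result bit-for-bit.

## What the synthetic fixtures do and do not establish

`random_network()` generates uniform-random, monotone-random (quantized
weighted-threshold, used to exercise the edge-sign validator) and constant
table schemes. Green oracle-equivalence tests establish that discovery,
basin assignment and statistics are *exact algorithms* on any model the
engine accepts; they say nothing about whether the bundled truth tables
are the published ones — that conditionality is carried by the
reconstruction notes above.

## Known limitations

* Synchronous, deterministic updating is inherited from the model family
  it implements; asynchronous or stochastic schemes are out of scope.
* Ordinal levels are not physical units: `Em` levels are not millivolts
  and pH levels are not pH units.
* The single pooled cytosolic calcium node cannot represent
  flagellum-to-head signal propagation; see the battery discussion above.
* Actin dynamics, capacitation upstream of the modeled nodes, and calcium
  oscillation waveforms are not modeled.
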