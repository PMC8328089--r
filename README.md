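# acrodyn

Discrete logical dynamics of the human sperm acrosome reaction (AR).

The AR is the exocytotic event that lets a spermatozoon fuse with the egg:
the acrosomal vesicle swells, its outer membrane docks onto the plasma
membrane and the two fuse, releasing the acrosomal content. Which cells in a
sperm population can do this — spontaneously, only after a progesterone
stimulus, or not at all — depends on a signaling network coupling
bicarbonate/cAMP signaling, cytosolic and acrosomal pH, membrane potential,
and calcium handling across the cytosol, the acrosome and the neck store.

`acrodyn` implements this system as a multi-valued, synchronous,
deterministic logical network and provides the full analysis battery such a
model needs:

* a generic engine for multi-valued logical networks: every node *x* takes
  levels `0..M_x`, and updates as
  `x_i(t+1) = F_i(x_i1(t), ..., x_ik(t))`
  with complete truth tables `F_i`; all nodes update simultaneously, so
  every trajectory ends in a fixed point or a limit cycle (an *attractor*),
  and every state belongs to exactly one *basin of attraction*;
* a bundled 38-node, 87-edge AR network (4 input stimuli: ionophore
  `A23187`, progesterone `Pg`, external `Ca_o` and `HCO3_o`; reporter
  `Fusion`; multi-level nodes `Em` 0–3, `CatSper`, `Ca_i`, `pH_i` 0–2),
  in an editable JSON format with a structural validator;
* attractor discovery by random restart with convergence detection, and
  functional classification of progesterone-free attractors into
  **Spontaneous** (fusion without Pg), **Inducible** (fusion only after
  switching Pg on) and **Negative** (no fusion either way);
* heterogeneity-aware initial-state ensembles: uniform constrained sampling
  and stratified sampling at observed AR proportions (15/30/65 for
  spontaneous/inducible/negative, normalized), with per-node activation
  statistics `P(x) = P(x > M_x/2)`;
* in-silico experiments: global and attractor-state clamping of the
  acrosomal pH node (`pH_a`), single-node transient perturbation screens,
  truth-table row perturbations, and a 26-row literature battery mapping
  pharmacological conditions (DCCD, DIDS, NNC, xestospongin C, thapsigargin,
  cAMP analogs, ionophore, progesterone, capacitation) to node clamps;
* random-network fixtures plus an exhaustive brute-force oracle that
  enumerates entire state spaces, used to prove the sampling machinery
  exact on small models.

The engine core is C++ (via Rcpp); a full discovery run on the
1.9 × 10¹² state AR model takes seconds.

**Provenance note.** The regulatory truth tables of the bundled AR network
are *reconstructed* from the published mechanistic description of the
pathway and calibrated only against published response *directions*; the
original supplementary tables were not available. Structural and engine
properties are exact; attractor *counts* and printed magnitudes are
properties of the original tables and differ here (see the methods
vignette for the full discussion).

## Worked example

```r
library(acrodyn)

ar <- ar_network()
ar
#> <acrodyn_network> ar_human_sperm: 38 nodes, 87 edges
#>   inputs: A23187, Pg, Ca_o, HCO3_o
#>   multi-level: pH_i (0..2), Em (0..3), CatSper (0..2), Ca_i (0..2)
#>   state space: 1.855e+12 states

# discover and classify the progesterone-free attractor landscape
ls <- classify_landscape(ar, discover_attractors(ar, ar_protocol(Pg = 0),
                                                 n_samples = 1e6,
                                                 n_confirm = 1e5, seed = 1))
ls
#> <acrodyn_landscape> ar_human_sperm [Pg=0]: 91 attractors (converged, 289,561 samples)
#> Spontaneous   Inducible    Negative
#>          18          19          54
```

Every attractor is a limit cycle (the acrosomal pump/leak homeostat never
settles); 18 of them fuse spontaneously, 19 fuse only after the Pg input is
switched on, 54 never fuse.

Clamping the acrosomal pH node alkaline during all dynamics deletes the
Negative class — acrosomal alkalinization by itself commits the network to
fusion:

```r
clamp_global(ar, "pH_a", 1, n_samples = 5e5, n_confirm = 1e5, seed = 1)
#> <clamp experiment> global_state_space, pH_a = 1: 2 attractors
#> Spontaneous   Inducible    Negative
#>           2           0           0
```

A stratified population at the observed AR proportions feeds per-class
node statistics and the literature battery:

```r
pop <- sample_stratified(ar, ls, n = 2e4, seed = 1)
head(class_stats_table(ar, ls, pop, scope = "attractor_states")[
  c("node", "class", "P", "SE")], 4)
#>     node       class          P         SE
#> 1    NBC Spontaneous 1.00000000 0.00000000
#> 2    SLC Spontaneous 0.04166667 0.02354976
#> 3 HCO3_i Spontaneous 0.95833333 0.02354976
#> 4    sAC Spontaneous 0.48611111 0.05890283

rep <- run_battery(ar, pop, seed = 1)
rep$rows[rep$rows$condition == "NNC" & rep$rows$readout == "Fusion",
         c("condition", "readout", "reported", "delta", "agreement")]
#>    condition readout reported  delta agreement
#> 25       NNC  Fusion       up 86.365      TRUE
#> 26       NNC  Fusion       up 55.040      TRUE
```

The first row says: clamping `pH_a` alkaline (the weak-base agent NNC)
raises the population fusion readout by 86 percentage points over the
untreated capacitated control — acrosomal alkalinization triggering the AR
on its own, in the direction the experiments report.

## Command line

A thin CLI ships under `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "acrodyn", package = "acrodyn"))')
Rscript $CLI validate                  # structural report, exit 0 on pass
Rscript $CLI attractors --pg 0 --seed 1 --out landscape.json
Rscript $CLI clamp --node pH_a --level 1 --mode global
Rscript $CLI battery --n 20000 --out battery.csv
Rscript $CLI fixtures --seed 3        # 100-fixture oracle self-test
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
against the installed package — landscape discovery and classification,
both pH_a clamping experiments, the stratified ensemble and the full
battery — and writes its result object to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/`, `src/` — engine (`step`, `run_to_attractor`, `canonicalize`,
  pack/unpack), network I/O (JSON dialect, SBML-qual/DOT/GraphML export),
  landscape, population, perturbation, experiments, fixtures modules
* `inst/extdata/ar_network.json` — the bundled AR model (data, not code)
* `inst/extdata/ar_battery.json` — the condition → clamp mapping and the
  26 literature comparisons (editable data)
* `vignettes/acrodyn-methods.Rmd` — the model, its assumptions, parameter
  choices, and known limitations
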