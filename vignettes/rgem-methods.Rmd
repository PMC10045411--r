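---
title: "Methods: context-specific metabolic models from multi-omic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific metabolic models from multi-omic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`rgem` implements a constraint-based workflow for asking how the loss of a
membrane transporter reshapes tissue metabolism when the evidence consists
of (i) present/absent transcript calls per condition and (ii) plasma
metabolite fold changes between knockout (KO) and wildtype (WT) animals.
The workflow builds a context-specific metabolic model per condition,
constrains exchange fluxes with the metabolomic data, compares the two
models' reaction content and sampled flux states, and ranks metabolites by
stoichiometric connectivity within the reactions that distinguish the
conditions. All linear programming runs on a solver built into the package
(a dense two-phase simplex with variable upper bounds), so results are
deterministic and reproducible to the reported tolerances on any machine.

# The flux model

A metabolic network with $m$ metabolites and $n$ reactions is encoded by
its stoichiometric matrix $S \in \mathbb{R}^{m\times n}$. A flux state
$v \in \mathbb{R}^n$ (mmol/gDW/h) is feasible when it satisfies
steady-state mass balance $S\,v = 0$ and the bounds
$v_l \le v \le v_u$. Flux balance analysis (FBA) maximizes the flux of a
designated objective reaction over this polytope; flux variability
analysis (FVA) reports, per reaction, the attainable flux range, optionally
subject to the objective reaching a fraction of its optimum. Exchange
reactions are single-metabolite boundary reactions written `met ->`, with
positive flux meaning secretion and negative flux uptake. Non-finite
bounds are capped at $\pm 1000$, the conventional "unlimited" flux value,
which keeps every linear program bounded.

# GIMME: context-specific extraction

Expression data enter as reaction weights. Each gene is called present
when it is present in at least 2 of 3 replicates; reaction presence
follows from the gene-protein-reaction rule (OR = any subunit present,
AND = all present; reactions without a rule are never penalized, since
absence of evidence is not evidence of absence). Presence is encoded as a
binary expression level $x_j \in \{0,1\}$ against a cutoff
$x_{\mathrm{cutoff}} = 0.5$, giving weights
$c_j = \max(x_{\mathrm{cutoff}} - x_j,\, 0)$ — a constant $0.5$ for
below-cutoff (absent) reactions and $0$ otherwise. With binary calls any
positive constant yields the same minimizer and active set.

The extraction solves

$$\min_v \; \sum_j c_j\,|v_j| \quad \text{s.t.}\quad S v = 0,\;
v_l \le v \le v_u,\; v_{\mathrm{obj}} \ge f \cdot v_{\mathrm{obj}}^{\max},$$

linearized by the split $v = v^+ - v^-$ with $0 \le v^+ \le v_u$ and
$0 \le v^- \le -v_l$, so that $|v_j| = v^+_j + v^-_j$ at any optimum. The
optimal value is the inconsistency score: zero means the expression calls
and the required functionality are perfectly compatible. The objective is
the standard weighted $\ell_1$ penalty $\min c^\top |v|$ of the GIMME
literature.

The active subnetwork is the set of unpenalized reactions plus any
penalized reaction carrying flux above $10^{-6}$ (above solver tolerance,
below meaningful flux). Tissue ATP demand is the default objective, with
the required fraction $f = 0.9$ of the unconstrained optimum; $f$ is a
configuration knob, since reasonable analyses range it between 0.5 and 1.

Reaction order can tip the solver between equally scoring subnetworks, so
context models are built as a 10-run ensemble over seeded random reaction
permutations, and only reactions active in all 10 runs are reported (a
strict intersection). Symmetric alternatives therefore drop out of the
consensus, which the test suite checks on a constructed degenerate
fixture.

# Metabolomic constraints

Exchanges of measured metabolites are first classified by FVA (at
objective fraction 0, i.e. pure feasibility, since classification precedes
the imposition of any objective) into secretion-only, uptake-only,
bidirectional, or blocked. For metabolites passing the significance filter
(two-way ANOVA on log intensities, genotype + batch, $p < 0.05$), one of
four rules fires on the KO model:

| rule | condition | action |
|------|-----------|--------|
| R1 | KO/WT > 1, secretion-only | force secretion: lb := 10% of max secretion |
| R2 | KO/WT > 1, uptake-only | restrict uptake: lb := 10% of max uptake |
| R3 | KO/WT < 1, secretion-only | restrict secretion: ub := 10% of max secretion |
| R4 | KO/WT < 1, uptake-only | force uptake: ub := 90% of max uptake |

The R1 (10%) and R4 (90%) fractions are the protocol's fixed values; for
R2 and R3, where only the direction of the inequality is essential, this
package uses the symmetric 10% mark (configurable). Bidirectional and blocked
exchanges are logged untouched. Every bound change lands in a constraint
ledger (reaction, rule, old and new bounds), and the constrained model's
feasibility is re-verified; conflicting rules raise an error rather than
being silently relaxed. Substrate exchanges of mapped metabolites receive
a reference uptake of 0.25 mmol/gDW/h (the unit is read as mmol, the
standard flux unit), and the conventional free species — oxygen, sodium,
potassium, iron, magnesium, bicarbonate, protons, water — get
$\pm 1000$ bounds. The metabolite-to-exchange mapping is an explicit
user-supplied table; there is no fuzzy name matching.

The fold-change constraints describe the KO plasma state relative to WT,
so they are applied to the KO model only; the WT model carries just the
reference bounds. This is a deliberate design decision of the package.

# Sampling, differential reactions, co-sets

The feasible flux polytope of each context model is characterized with
artificial-centering hit-and-run sampling: directions are drawn through
the FVA extreme points (the warmup set), and $2n$ points are kept for
$n$ reactions. Consecutive kept points are separated by
$\max(100,\,25n)$ chain steps: the mixing time of hit-and-run grows
with the polytope dimension (free transport loops with $\pm 1000$ bounds
stretch the polytope enormously along a few directions), and a fixed
short thinning leaves chain-level autocorrelation that a two-sample test
downstream would mistake for signal. The package's null-calibration
tests pin this down: at the dimension-scaled thinning, wildtype-versus-
wildtype sampling shows a Kolmogorov-Smirnov false-positive fraction
within the nominal level.
Because directions are differences of feasible points, iterates remain in
the affine space $\{Sv=0\}$ to solver precision without reprojection; the
suite asserts $\lVert S v\rVert_\infty \le 10^{-6}$ on every kept point.
A numerically flat polytope (all FVA widths below $10^{-9}$) returns the
single feasible point with a warning.

Sampled states are normalized per sample by total absolute flux (L1),
making WT/KO comparisons scale-free; the normalization method is
configurable (`none`, per-reaction z-score); L1 is the default because it
is the simplest scale-free choice. Differentially active reactions
are detected per shared reaction with the two-sample Kolmogorov-Smirnov
test at $p < 0.001$ and no multiple-testing correction, mirroring the
stated fixed threshold. Co-sets (correlated reaction sets) are the
connected components of the graph joining reactions with
$|r| \ge 0.95$ (Pearson, over samples), after excluding constant-flux
reactions; single-linkage components are the default grouping, maximal
cliques are available for diagnostics.

# Comparison and connectivity

The WT and KO consensus active sets are partitioned into shared and
condition-unique reactions; induced metabolite sets give per-compartment
counts and KO/WT ratios (0/0 counts as 1, $x$/0 is flagged infinite).
Subsystem breakdown reports, per subsystem, the count of unique reactions
and the affected fraction of the subsystem, which counters the bias of
large subsystems dominating raw counts.

Metabolite connectivity restricts the binarized stoichiometric matrix
$S_b$ ($[S_b]_{ij} = 1$ iff $|S_{ij}| > 10^{-12}$) to the columns of a
reaction subset — typically the KO-unique reactions — and computes
$c_m = \mathrm{diag}(S_b S_b^\top)$: for each metabolite, the number of
subset reactions involving it. Ranking ties break lexicographically by
metabolite id so reports are deterministic.

# The synthetic study system

Genome-scale reconstructions and animal multi-omics are rarely available
in a form a test suite can depend on, so the package ships a designed ~70-reaction
kidney-redox toy network on which every stage is testable end to end:

* a glucose- and pyruvate-fed backbone (glycolysis, TCA, oxidative
  phosphorylation) with ATP demand as objective;
* an obligatory superoxide leak at complex I (2% of electron pairs), so
  respiration at 90% of optimal ATP forces a superoxide disposal flux;
* urate scavenging as the wildtype's free disposal route, fed by a
  reabsorption-style urate uptake (the "Urat1-like" exchange);
* a capacity-limited enzymatic branch — superoxide dismutase isoforms in
  five compartments, the ascorbate cycle with NADPH- and
  glutathione-dependent regeneration, glutathione/thioredoxin peroxide
  routes, and transhydrogenase-backed NADPH supply — whose genes are
  planted absent (hence penalized) in both conditions.

Blocking the urate uptake removes the free route, so the knockout's LP is
forced through every capacity-limited penalized reaction; the KO-unique
consensus set is then exactly the redox branch, the ROS-detoxification
subsystem has the highest affected fraction, and the connectivity ranking
of the KO-unique reactions is headed by redox species (hydrogen peroxide,
NADP(H), protons). The per-isoform and per-route capacities were sized at
design time so that every branch member saturates at the 90% ATP
constraint — the point of the fixture is that the designed signal is
unambiguous, not that the capacities are physiological. All non-boundary
reactions are exactly mass- and charge-balanced with real elemental
formulas; one invented species (an oxidized-urate adduct closing the
scavenging route) is documented as synthetic.

The omics generators emulate: 3 present/absent replicates per condition,
with planted-absent genes called absent at rate 0.9 per replicate (so the
2-of-3 consensus is absent with probability 0.972) and a 2% dropout on
expressed genes; and 6 plasma samples per condition with log-normal noise
(sigma 0.25 on the log scale), a balanced two-batch structure with a 0.10
log-scale batch offset, 6 metabolites planted up at fold 2.0, 2 down at
0.5, and 4 unchanged — a realistic plasma panel in which a minority of
metabolites move, most of them upward. Planted-absent redox genes are
encoded as
two-subunit AND rules, which makes a spurious consensus-present call on a
penalized reaction quadratically unlikely and keeps the planted signal
stable across seeds.

What the generators do **not** emulate: probe-level microarray artifacts,
peak identification and drift in mass spectrometry, correlated gene
expression, compartment-specific proteome constraints, or any kinetic
regulation. Passing tests therefore demonstrate that the pipeline's
logic, numerics and statistics behave as specified on data with the
assumed structure — not that the biological conclusions transfer to any
particular real dataset.

# Numerical choices

* Zero tolerance $10^{-12}$ for stoichiometric coefficients and
  binarization (below LP precision).
* Simplex feasibility/optimality tolerances $10^{-9}$; Dantzig pricing
  with a switch to Bland's rule after $5(n+m)$ iterations guarantees
  termination on degenerate flux LPs; solutions are vertices, so objective
  values are deterministic even when flux vectors are degenerate (tests
  assert objective values and ranges, never a particular alternate
  optimum).
* Active-set flux threshold $10^{-6}$.
* Sampling uses R's RNG, so a seed makes sample sets bit-identical;
  every stochastic stage of the pipeline derives its own seed from the
  master seed.
* Reaction permutations in the ensemble affect LP column order only; this
  is the package's stand-in for the order sensitivity of greedy/context
  extraction noted in practice.

# Problem sizes in the test suite

The suite exercises: brute-force polytope-vertex oracles on 50+ random
networks of up to 8 reactions (orthant enumeration makes the weighted
$\ell_1$ objective exactly verifiable); 200 random incidence structures
for the connectivity identity; 10,000 draws for the 2-of-3 consensus
arithmetic; 1,000-point uniformity checks and 200 null replicate pairs
for sampler calibration; and 20 seeded end-to-end runs for planted-signal
recovery. These sizes keep the default suite in the minutes range while
holding each statistical assertion to a three-sigma (or stated) band.

# Known limitations

* The LP engine is dense and targets networks up to a few hundred
  reactions; genome-scale reconstructions (thousands of reactions) would
  need a sparse factorized solver behind the same interface.
* GIMME is the only extraction method implemented; the reorder-ensemble
  idea is borrowed as a robustness device, not as a second method.
* The KS screen is run per reaction without multiplicity correction by
  design; interpret counts, not individual p-values.
* SBML support covers Level 3 + fbc version 2 (bounds as parameters,
  gene-product associations, one active linear objective), which is what
  current genome-scale models use; older SBML dialects are out of scope.
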