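---
title: "Qualitative networks, stability analysis, and in-silico inhibitor screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative networks, stability analysis, and in-silico inhibitor screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnscreen)
```

## The formalism

A qualitative network (QN) generalizes Boolean networks: each node $v$ holds a
bounded integer activity level $s_v \in \{r^{min}_v, \dots, r^{max}_v\}$
(default granularity 0..4) and is assigned a *target function* $T_v(s)$, a
real-valued formula over the levels of its regulators. The synchronous update
moves every node one step toward its target simultaneously:

$$ s'_v = \mathrm{clamp}\big(s_v + \mathrm{sign}(T_v(s) - s_v)\big), $$

where the sign is zero when $T_v(s) = s_v$ exactly. The dynamics are
deterministic over a finite state space, so every trajectory closes a cycle —
an *attractor*; a period-1 attractor is a stable state.

**Default target function.** Unless a mechanism demands otherwise, a node uses
`avg(pos) − avg(neg)`: the mean level of its activating inputs minus the mean
level of its inhibiting inputs. Two conventions complete the rule:

* an empty input set contributes 0, so a node with only activators uses
  `avg(pos)` alone;
* a node with *no activators* is assumed constitutively active: its target is
  a per-node constitutive constant (default: the node's maximum, i.e. fully ON
  unless repressed) minus `avg(neg)`. The constant is a modeling degree of
  freedom and is serialized with the model.

When an input's range differs from its consumer's, the input level is first
rescaled linearly onto the consumer's range; with the uniform 0..4 ranges of
the shipped model this is the identity.

**Real-valued targets and oscillation.** Targets stay real; the step rule
compares a real target against an integer level. A fractional target such as
2.5 therefore forces a period-2 oscillation between levels 2 and 3. This
choice (rather than rounding targets before comparison) was made because it
reproduces the documented behavior that a node may "oscillate between two
levels", which is then summarized by the mean of its minimum and maximum —
here $2.5$ — the *mean-of-min-and-max convention* used for every non-point
node summary in the package.

Explicit formulas use a small grammar (`var`, decimal constants, `avg`, `min`,
`max`, `ceil`, `floor`, `+ − * /`, parentheses; case-insensitive function
names, standard precedence). Division by a zero divisor is a hard error naming
the offending node, never a silent clamp.

## Stability analysis

`narrow_intervals()` maintains a per-node interval box and iterates, round-robin
over nodes in declaration order, the update

$$ [l_v, h_v] \leftarrow [l_v,h_v] \cap
   \big[\lfloor \min T_v(B) \rfloor,\ \lceil \max T_v(B) \rceil\big], $$

until a full pass changes nothing. For default (linear, monotone) targets the
exact range over the box is attained at interval endpoints; for explicit
formulas the range is found by enumerating the level combinations of the
formula's support nodes (budget $10^5$ combinations), falling back to
conservative, monotonicity-aware interval arithmetic above the budget
(widening for products; an error when a divisor interval straddles zero).
Iteration order affects only speed, not the fixpoint (asserted by test on
permuted models). Intersecting with the current interval is what makes the
iteration monotone, hence terminating; the soundness argument is inductive:
recurrent states lie in the current box, so their next levels lie within one
step of the target range over that box.

The contract is *soundness*: every state of every attractor reachable from the
initial box lies inside the final box, and an all-point box is a proven unique
stable state. The converse does not hold — a wide box may still harbor a
unique attractor. `qn_stabilize()` therefore refines non-point boxes by
simulating from a deterministic sample of initial states inside the box: the
all-low corner, the all-high corner, the rounded midpoint, and 32 seeded
uniform draws (the seed is an argument and is recorded in the result). Nodes
are summarized over the union of all attractor states found; the summary
`midpoint` is the mean of the node's minimum and maximum. The sample is a
heuristic: in a model with very many attractors it can miss basins, which is
why the engine's guarantees are stated for the box, and why the sampled
summary is cross-checked against exhaustive enumeration on the synthetic
battery (below).

`enumerate_attractors()` is the brute-force oracle: it computes the successor
of *every* state (refusing state spaces above $10^6$ states) and extracts all
cycles of the functional graph, so its output is exact. Simulation budgets
default to $10\times$ the sum of range sizes; exceeding a budget is an
explicit error, never a truncation.

A property worth knowing about synchronous semantics: a two-node
mutual-inhibition toggle (both constitutively ON) has, besides the five
antidiagonal fixed points $(0,4)\dots(4,0)$, four period-2 "checkerboard"
cycles in which both nodes step past each other in lockstep — e.g.
$(2,1) \leftrightarrow (3,2)$. These are genuine attractors of the
simultaneous update (asynchronous semantics, a non-goal here, would dissolve
them) and are asserted as such in the fixture suite.

## The synthetic-model battery

`random_qn()` draws seeded signed Erdős–Rényi digraphs (no self-loops, default
target functions); `qn_fixtures()` ships four hand-built models whose exact
attractor sets are frozen from the enumeration oracle (constant chain,
fractional oscillator, toggle, three-node negative-feedback ring). The engine
battery — 200 models, 4 nodes, levels 0..2, seeds 0..199 — keeps each state
space at $3^4 = 81$ states so exhaustive enumeration stays instant, and
asserts on every model that the narrowed box contains all recurrent states and
that point boxes coincide with a unique fixed point. The battery emulates
topology and sign structure only; it does not emulate the degree distribution,
pathway modularity, or curated formulas of real signaling networks, so passing
it certifies the *engine*, not any biological claim.

## The breast-tumor model

The shipped network (`build_breast_model()`, ~32 nodes, all ranges 0..4) is a
literature-constrained reconstruction of Myc/Ras/p53/Wnt/HIF cross talk in
Wnt-driven, estrogen-receptor-negative mammary tumor cells, organized in
pathway modules (microenvironment, Wnt, EGFR/HER2, Ras/MAPK, p53,
HIF/hypoxia, phenotypes). The `in_vitro` variant carries HER2 between EGFR
and Ras; the `in_vivo` variant (the screened one) removes HER2 and adds
VEGF-driven angiogenesis as a third phenotype. Because the original curated
node/edge tables are not redistributable, fidelity is defined behaviorally: a
shipped table of qualitative claims (`breast_expectations()`) over stable-state
summaries must pass in full, and the model was iteratively refined against
that table — the same build-test-refine loop used to produce the original.

Mechanistic choices that required explicit formulas (each also commented in
the source):

* **Wnt–Myc mutualism.** Myc represses the cell's own `Wnt1`; reception
  integrates autocrine and paracrine (`Wnt1_env`) ligand through redundant
  Frizzled/LRP6 co-receptors; β-catenin quenches the `p19ARF` apoptotic
  trigger. A pure Myc-high clone therefore starves itself of survival
  signaling, while a paracrine Wnt source (Myc-low neighbors) restores it.
* **p53 spine.** `Mdm2 = 1 + ERK/2 − p19ARF/2`: basal Mdm2 expression (the
  p53→Mdm2 transcriptional feedback folded into the basal term, which avoids
  spurious limit cycles at integer granularity), enhanced by ERK and opposed
  by ARF sequestration; `p53 = 4 − Mdm2`.
* **Myc priming.** `PUMA`/`NOXA` follow `min(p53, Myc + 1)`: the apoptotic
  (rather than arrest) arm of the p53 response requires Myc drive, with a
  basal offset; `p21 = p53 − Myc` implements Myc/Miz1 repression of CDKN1A,
  so Myc-forced clones resist arrest.
* **Serial HIF degradation.** `HIF1a = 4 − min(PHD2, VHL)`: hydroxylation and
  ubiquitination act in series, so losing either step stabilizes HIF1α
  regardless of oxygen; HIF1α induces BNIP3 (hypoxic death) and VEGF.
* **Phenotypes.** Proliferation follows the strongest mitogenic driver
  (`max(Myc, avg(ERK, bCatenin)) − p21`: deregulated Myc is sufficient on its
  own); apoptosis balances BH3 pressure against the ERK- and COX2-driven
  survival inputs, with BNIP3 as a bypass:
  `max(avg(PUMA, NOXA) − avg(ERK, COX2), BNIP3)`.

**Clones are pure node settings** on the shared model (`clone_configs()`):
`healthy` fixes nothing (physiological Wnt tone 2, normoxia); `myc_low` fixes
the paracrine Wnt source at 4 and hypoxia at 1 (indolent, hypovascular pure
tumors); `myc_low_mixed` is the same clone normoxic (angiogenic Myc-high
neighbors); `myc_high_pure` forces Myc to 4 with the Wnt source lowered to 0;
`myc_high_mixed` forces Myc to 4 with the Wnt source raised to 4. The
environment levels are the one place where inter-clonal cooperation enters;
the model deliberately does not track clonal population dynamics during
treatment, so predictions are per-clone snapshots at fixed microenvironments.

## The inhibitor screen

Drug inhibition is binary: the treated node's target function is replaced by
zero (`pert_inhibit()`), on top of the clone's fixings; treating a clone-fixed
node is a conflict error and treatments are sets (no same-node pairs). For M
candidate targets, `run_screen()` evaluates all $M + M(M-1)/2$ mono and pair
treatments per clone plus the untreated baselines, reading the `Proliferation`
and `Apoptosis` midpoints. Candidate targets default to the druggable
annotation — a static snapshot of drug–gene interactions shipped with the
model (`node_annotations()`), never a live database query.

Downstream analysis mirrors the published presentation rules:

* **Healthy toxicity:** any treatment whose healthy-clone apoptosis midpoint
  strictly exceeds 3 is masked (reason-coded, never deleted). The mutual
  PHD2+VHL pair is exempt by the same presentation rule that removed those
  rows before clustering in the original figures; a `drop_phd2_vhl` flag
  additionally hides their rows/columns for display.
* **Effective monotherapies:** a target is row-eligible when its monotherapy
  improves the metric (apoptosis up / proliferation down) versus baseline by
  more than ε in at least one tumor clone; ε defaults to 0 (strict
  improvement) and is exposed because the original effectiveness criterion is
  unstated.
* **Delta matrices:** `delta[a, b]` is the metric change when b is added to
  monotherapy a, averaged over the two *mixed* clones — the mixed tumor is
  the clinically relevant context, and pure clones are reported separately
  (`resilience_report()`); a flag could average pure clones instead, which was
  the main open reading of "both clones".
* **Outcome label:** a condition is `net_apoptosis` when apoptosis midpoint
  exceeds proliferation midpoint by more than 0.5, `net_proliferation` when
  the reverse holds, otherwise `balanced`; the dichotomy is named but not
  quantified in the source material, so the half-level margin is this
  package's rule.

On the shipped in-vivo model the screen recovers the qualitative predictions
asserted by the test suite: mixed clones are at least as resilient as pure
clones under every single inhibitor; MEK inhibition adds more apoptosis in
Myc-high than Myc-low cells; MEK+COX2 exceeds both monotherapies in the
Myc-low clone; and the maximal mean apoptosis-gain cell of the druggable delta
matrix is the MEK+COX2 combination.

## Numerical choices and problem sizes

* Stabilization sampling: 3 deterministic starts + 32 seeded draws; seeds are
  plumbed through every command and recorded in provenance records, so reruns
  are byte-identical.
* Budgets: simulation $10\times\sum_v |range_v|$ steps; enumeration $10^6$
  states; formula-support enumeration $10^5$ combinations. All overruns are
  errors.
* Floating point: target ranges are rounded at $10^{-9}$ before floor/ceil in
  the narrowing step; step comparisons use the same tolerance.
* Study sizes: the engine battery uses 200 four-node networks (81 states
  each); the expectation suite evaluates 15 claims over ~20 clone/treatment
  conditions; the druggable screen covers 12 targets → 78 treatments × 3
  clones. These sizes make the full validation-plus-screen workflow a
  sub-minute computation on one core while keeping the brute-force oracle
  exact.

## Known limitations

Inhibition is all-or-none (no dose–response); triple combinations are out of
scope; clonal composition is static during treatment, so therapy-induced loss
of the Wnt-supplying clone — and the consequent collapse of Myc-high
survival — is not modeled; the network is a reconstruction whose guarantee is
the behavioral claim suite, not edge-list identity with the original curated
tables (users with access to those tables can substitute their JSON and keep
the expectation suite as a regression harness); and attractor sampling inside
non-point boxes is heuristic, certified only against the exhaustive oracle at
battery scale.
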