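# qnscreen

Executable, qualitative-network (QN) modeling of oncogenic signaling with
stable-state analysis and an exhaustive in-silico inhibitor screen — built
around the biology of *biclonal* Wnt-driven breast tumors in which Myc-high
and Myc-low tumor-cell clones depend on each other.

## The problem and who this is for

Breast tumors commonly contain intermixed clones expressing high and low
levels of Myc. Myc-high cells proliferate aggressively and instruct an
angiogenic stroma but are primed for p53-dependent apoptosis and — because
high Myc represses *Wnt1* — starve themselves of an essential autocrine
survival signal; Myc-low cells supply paracrine Wnt1 that quenches the
p19^ARF^→p53→PUMA/NOXA apoptotic axis of their aggressive neighbors. The two
clones are obligate mutualists, and that mutualism is a therapeutic target.
This package is for systems/computational biologists who want to (i) simulate
and analyze such signaling logic as executable models, and (ii) screen single
and pairwise node inhibitions across cell contexts for combinations that kill
both clones while sparing healthy cells.

## The formalism

A QN is a signed digraph over nodes with bounded integer activity levels
(here 0..4). Each node moves one level per synchronous step toward a
real-valued target function, by default

```
T_v(s) = avg(activators) − avg(inhibitors)
```

(with a constitutive constant when a node has no activators). Deterministic
dynamics over a finite state space always close a cycle; the package finds
stable behavior two ways:

* **Interval narrowing** (`narrow_intervals`): iteratively shrinks per-node
  `[lo, hi]` bounds using the exact target range over the current box — a
  *sound* over-approximation of all long-run behavior; all-point intervals
  prove a unique stable state.
* **Exhaustive enumeration** (`enumerate_attractors`): the brute-force oracle
  for small state spaces, used to certify the narrowing on batteries of
  seeded random networks.

Nodes that oscillate are summarized by the mean of their minimum and maximum
level (`midpoint`). Drug inhibition fixes a node's target at zero; clone
identities (Myc forced to maximum, paracrine Wnt1 raised or lost, hypoxia)
are pure node-level settings on one shared model.

## Worked example

```r
library(qnscreen)

m  <- build_breast_model("in_vivo")   # curated Myc/Ras/p53/Wnt/HIF network
m
#> Qualitative network 'breast_in_vivo': 32 variables, 48 relationships
#>   target functions: 26 default, 6 explicit

cl <- clone_configs(m)

# A pure Myc-high tumor: Wnt signaling collapses, the ARF->p53 axis engages
st <- qn_stabilize(m, cl$myc_high_pure$perturbations, seed = 1)
subset(st$summary, variable %in% c("Wnt1", "bCatenin", "p19ARF", "p53",
                                   "Proliferation", "Apoptosis"))
#>       variable lo hi min max midpoint
#>           Wnt1  0  0   0   0        0
#>       bCatenin  0  0   0   0        0
#>         p19ARF  4  4   4   4        4
#>            p53  4  4   4   4        4
#>  Proliferation  4  4   4   4        4
#>      Apoptosis  2  2   2   2        2
```

Every node collapsed to a point, so this is a proven stable state: the clone
proliferates maximally (midpoint 4) but sits under strong apoptotic pressure
(2 vs. ~0 in Myc-low clones). Giving the same clone a paracrine Wnt1 source
(`myc_high_mixed`) restores β-catenin to 2, halves p19^ARF^, and drops
apoptosis to 1 while proliferation stays at 4 — the in-silico restatement of
clonal mutualism.

Screening treatments across clones:

```r
sc <- run_screen(m, cl[c("healthy", "myc_high_mixed", "myc_low_mixed")],
                 targets = c("MEK", "COX2"), seed = 1)
sc[, c("clone", "treatment", "proliferation", "apoptosis", "outcome")]
#>           clone treatment proliferation apoptosis           outcome
#>         healthy       MEK           0.5       2.0     net_apoptosis
#>         healthy      COX2           2.0       1.5          balanced
#>         healthy  COX2+MEK           0.5       2.5     net_apoptosis
#>  myc_high_mixed       MEK           4.0       3.5          balanced
#>  myc_high_mixed      COX2           4.0       2.0 net_proliferation
#>  myc_high_mixed  COX2+MEK           4.0       4.0          balanced
#>   myc_low_mixed       MEK           0.5       2.0     net_apoptosis
#>   myc_low_mixed      COX2           2.0       1.5          balanced
#>   myc_low_mixed  COX2+MEK           0.5       2.5     net_apoptosis
```

MEK inhibition alone is strongly apoptotic for Myc-high cells (3.5) and
antiproliferative for Myc-low cells (0.5); adding COX2 inhibition pushes
apoptosis to the ceiling in Myc-high (4.0) and past either monotherapy in
Myc-low (2.5 vs 2.0/1.5), while healthy-cell apoptosis stays at or below the
toxicity bound of 3. Over the full druggable panel,
`delta_matrix(run_screen(...), "apoptosis")` builds the
add-a-second-inhibitor matrix (same-node and healthy-toxic cells masked, the
PHD2+VHL mutual pair exempt), and `top_delta_cell()` identifies MEK+COX2 as
the best apoptosis-gain combination.

The full workflow — expectation validation, druggable screen, CSV/heatmap/
provenance exports — is one call (`qn_cmd_reproduce("out")`) or one shell
command (`Rscript inst/cli/clonalqn.R reproduce --out out`).

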