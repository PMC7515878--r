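---
title: "Network Hamiltonian models of fibril self-assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Hamiltonian models of fibril self-assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilnet)
```

## The model

`fibrilnet` treats an aggregating protein system as an *aggregation graph*:
one vertex per monomer, one edge per non-covalent inter-monomer contact.
The energetics of an aggregation state are summarised by a coarse-grained
network Hamiltonian over nine topological motif counts
$t(g) = (t_e, t_{2s}, t_{NSP1}, t_{NSP2}, t_{ESP0}, t_{ESP1}, t_{C5},
t_{C6}, t_{C7})$:

$$
\mathcal{H}(g) = (\phi_e + k_B T)\, t_e + \phi_{2s} t_{2s}
 + \phi_{NSP1} t_{NSP1} + \phi_{NSP2} t_{NSP2}
 + \phi_{ESP0} t_{ESP0} + \phi_{ESP1} t_{ESP1}
 + \phi_{C5} t_{C5} + \phi_{C6} t_{C6} + \phi_{C7} t_{C7}.
$$

The motifs are: edges; two-stars (a monomer bound to two partners, the
first-order cost of additional bonds at an occupied interface); null
shared-partner counts NSP1/NSP2 (unbound pairs with exactly one or two
common partners — local deformability of chain and sheet-like regions);
edgewise shared-partner counts ESP0/ESP1 (bound pairs with zero or one
common partner — triadic closure); and the numbers of simple cycles of
length five to seven (higher-order rigidity). Each cycle subgraph is
counted once, irrespective of traversal direction or starting point, which
is the usual subgraph-census convention and the one our enumeration oracle
uses in the tests.

In equilibrium the state follows the Boltzmann / exponential-family random
graph (ERGM) distribution

$$
\Pr(G = g) \propto \exp\!\big(-\mathcal{H}(g)/(k_B T)\big)\, h(g),
$$

with $h$ a reference measure accounting for hidden degrees of freedom. The
package implements the counting measure ($\log h \equiv 0$), the stated
default of the modelling framework; `brute_force_distribution()` exposes a
`log_h` hook should an alternative be needed. Note one convention choice:
because the edge coefficient of the Hamiltonian is $\phi_e + k_B T$ (not
$\phi_e$ alone), the natural parameter vector returned by `theta()` is
$-(\text{coefficients})/(k_B T)$ including that offset, so that
$\theta^\top t(g) = -\mathcal{H}(g)/(k_B T)$ holds identically.

All equilibrium and kinetic computations go through *change statistics*
(`change_stats()`): the exact difference $t(g \oplus \{u,v\}) - t(g)$ for a
single-bond toggle, computed locally. The shared-partner deltas only touch
the neighbourhoods of the toggled endpoints, and the cycle deltas equal the
number of simple paths of length 4–6 between the endpoints (every affected
cycle passes through the toggled bond), found by a depth-bounded search.
These kernels are compiled (Rcpp), as is usual for ERGM software.

## Kinetics

The kinetic extension makes the model dynamical. States one bond apart
(one Hamming step) interconvert with conditional rate

$$
r_{ij} = \frac{A}{1 + \exp\!\big(\beta\,\Delta^{\mathcal H}_{ij}
 - \Delta^{S}_{ij}\big)},
$$

where $A$ is a collision frequency, $\beta = 1/(k_B T)$, and
$\Delta^{S}$ vanishes under the counting measure. Strongly uphill moves
reduce to the Arrhenius form $A e^{-\beta E_a}$ (verified to 1% for
$\beta\Delta\mathcal{H} \ge 7$ in the tests); strongly downhill moves
saturate at the collision frequency, which is how spatial/dynamical
limitations enter this non-spatial model. The ratio
$r_{ij}/r_{ji} = e^{-\beta \Delta \mathcal{H}}$ gives detailed balance
with respect to the equilibrium distribution; we verify this both
algebraically (to 1e-12) and empirically (time-weighted occupancy of the
three-monomer chain against exact enumeration, total variation < 0.03).

`simulate_fibrillization()` runs the resulting continuous-time Markov
chain from the empty graph: waiting times are exponential with rate equal
to the exit rate $R_{i+} = \sum_j r_{ij}$, and the realised toggle is
drawn with probability $r_{ij}/R_{i+}$. Times are reported in units of
inverse collision rate ($A = 1$ by default); rescaling $A$ is a pure
relabelling of the time axis. The waiting time is always drawn before the
neighbour choice from a single seeded generator, making runs
bit-reproducible.

Recomputing every dyad rate after each event costs $O(n^2)$ change-stat
evaluations; instead the simulator re-evaluates only dyads whose change
statistics the toggle of $\{u,v\}$ can have altered: every dyad incident
to $u$ or $v$ (degree terms), plus dyads $(a,b)$ with
$d(a,\{u,v\}) + d(b,\{u,v\}) \le 5$, the reach of the shared-partner and
seven-cycle terms. Distances to the *set* $\{u,v\}$ are unchanged by the
toggle itself, which makes the rule exact rather than heuristic; the test
suite confirms bit-identical event streams against full recomputation.
(A radius-3 "both endpoints" rule would miss both the degree effect on
dyads with one distant endpoint and the longest cycle paths.)

## Fibril topologies and induced fibrillar components

The five topology classes covering fibril structures resolved to date are
shipped as declarative periodic templates (`fibril_classes()`): a minimal
repeating subunit with intra-subunit, consecutive-subunit and (for the
"1,2" classes) next-nearest-subunit bond patterns. The exact edge patterns
of the 1,2 and double 1,2 2-ribbons follow the natural reading of the
class names — every monomer bonds its first and second axial neighbour on
its own strand, the double variant laterally pairs two such ribbons — and
because templates are data, they can be amended without touching any
machinery.

A monomer is *locally fibrillar* (`is_locally_fibrillar()`) when its
closed 1-neighbourhood embeds, induced and anchored, into the
neighbourhood of some position of the ideal fibril — interior or terminal.
Extra bonds disqualify: a monomer with five partners can never sit in a
1-ribbon, whose positions have at most two. Terminal positions are
included so that growth faces count as fibrillar.

`induced_fibrillar_components()` then extracts maximal connected sets of
fibrillar monomers, with three refinements that we consider the central
design decisions of the package:

1. **Segment verification.** Each candidate component must be isomorphic
   to a contiguous, possibly end-truncated segment of its ideal fibril.
   Closed rings of path-like monomers, for instance, are not fibrils.
2. **Bridge splitting.** A connected fibrillar set that fails
   verification is split at its first bridge bond (deterministic order)
   and the parts re-examined. A single spurious bond joining two fibrils
   is always such a bridge (every bond of a multi-stranded fibril is
   cycle-protected), so joined-but-distinct fibrils resolve into their
   parts with the joining bond left for the defect census. For the
   1-ribbon, where a terminal-terminal bond genuinely merges two fibrils
   into one, the merged path passes verification directly and no split
   occurs — joining two 10-mers yields one 20-mer component, halving the
   component count.
3. **Rescue pass.** Strict local embedding would declare a fibril
   interior monomer non-fibrillar the moment a defect bonds to it, which
   would make defect-to-fibril-centre contacts unrepresentable. After the
   strict pass and extraction, a monomer outside every retained component
   is rescued if its bonds *to retained-component monomers* form a valid
   template neighbourhood; its remaining bonds are defect bonds. Because
   the rescue is anchored to already-verified components, disordered
   condensates (where the strict pass retains nothing) are not rescued
   into fibrils, and the fibril fraction correctly stays near zero during
   condensation.

Components below the nucleation threshold — two full minimal repeating
subunits, i.e. `2 * subunit_size`, raised to four for the single-monomer
subunit of the 1-ribbon so that bonded pairs do not count as fibrils — are
discarded.

## Metrics, epochs, defects

`graph_metrics()` reports, per frame: average component size $n/\#$
components (free monomers are singleton components, so every run starts
at exactly 1); maximum induced fibril component size; induced fibril
component count; fibril fraction (fibrillar monomers over $n$); and the
oligomer count. Oligomers are connected components of fewer than eight
monomers; we additionally require at least two monomers so that free
monomers are not counted as oligomers — an interpretive choice, flagged
as such, since oligomers are conventionally distinct species from free
monomer.

`segment_epochs()` places the five-epoch boundaries on the smoothed
series (centered moving average, default window 1% of frames, at least
3): Condensation ends at the first maximum of average component size;
Nucleation starts when the maximum fibril size first reaches the
nucleation threshold (Local Ordering is the interval between — the text
defining these phases implies Local Ordering ends exactly where
Nucleation begins, and we implement it that way); Fibril Growth starts at
the first maximum of the fibril component count; Maturation starts at the
earliest frame from which both the fibril fraction and the maximum fibril
size fluctuate by at most `conv_tol` (default 5% relative) through the
end of the series, with the candidate start capped at 90% of the frames
so convergence is always judged on a meaningful trailing window.
"First occurrence" resolves all argmax ties, making segmentation
deterministic; boundaries out of order raise a structured error rather
than a silent reordering. Boundaries depend only on frame order and
values, so uniform rescaling of the time axis rescales the segmentation.
The two 1-ribbon pathway schemes (condensate annealing, dendrite
consolidation) are label sets over the same machinery, prefixed by a
Dimerization epoch that ends when average component size first reaches 2;
their boundary rules are explicit approximations, as the narrative
descriptions of these pathways do not pin down quantitative markers.

For the defect analysis, `vertex_roles()` labels monomers as fibril ends
(terminal-subunit positions of a verified component), centers (other
component members), defects (non-fibrillar monomers in an aggregate that
contains fibrillar structure) or free. `motif_census()` classifies every
bond not internal to a single fibrillar component by its endpoint role
pair — the closed set over \{end, center, defect\} plus free-monomer
attachment, which partitions all such bonds by construction.
`detect_breakage_events()` counts deletions incident to a defect that
disconnect their aggregate (i.e. bridge deletions); whether
non-disconnecting deletions should also count is ambiguous in the source
description, and we adopt the stricter reading.

## The synthetic generators and what the tests do (and do not) show

Fixture generators (`make_fixture()`) build ideal fibrils, joined-fibril
and defect-decorated variants, deterministic growth trajectories and
metric curves with planted landmarks. The planted curves are designed so
that each epoch boundary is known by construction; they validate the
boundary machinery exactly, but say nothing about whether simulated
trajectories of any particular parameter set exhibit those epochs.

The calibrated coefficient sets for the five topology classes are
configuration input to this package (they accompany the original study's
supplementary material and are not redistributed here). The bundled
parameter files are **hand-tuned placeholders**, named accordingly, chosen
to demonstrate the mechanism classes at small system size:

* `params_1ribbon_dendrite_consolidation_placeholder.yaml` — bonds deep
  enough to hold chains ($\phi_e = -7.5$ with $k_BT = 1$), a convex
  two-star penalty ($\phi_{2s} = 5$) against an NSP1 reward
  ($\phi_{NSP1} = -1.5$) so that junction bonds cost
  $\phi_{2s} + \phi_{NSP1} = 3.5$ more than chain extension: sparse
  growth to high 1-ribbon fraction (≈0.9 at $n = 40$ within $10^4$
  events).
* `params_1ribbon_condensate_annealing_placeholder.yaml` — the same
  architecture with the junction surcharge reduced to 1: monomers gel
  into a long-lived disordered aggregate from which chain order anneals
  only on time scales beyond routine simulation length.
* `params_2ribbon_placeholder.yaml` — a chordless-square reward
  ($\phi_{NSP2} = -5$) against the two-star penalty, with a six-cycle
  penalty that excludes closed square-rich polyhedra (hypercubes are the
  failure mode of an unconstrained square reward). This set nucleates
  ladder segments out of a chain condensate but, at the system sizes we
  simulate ($n \le 100$), fibril fraction fluctuates in the 0.2–0.8 range
  rather than converging: the Maturation epoch is typically not reached,
  and the corresponding check is reported rather than gated.

Problem sizes in the test suite ($n \le 40$ for behavioural tests, $n =
60$ with $1.5\times 10^4$ events for the reported higher-order run,
$n \le 7$ for oracle enumeration, $10^6$ Metropolis steps and
$\ge 10^5$ kinetic events on three monomers for distributional checks)
were chosen as the smallest systems for which the checked quantities are
statistically meaningful. What the passing suite shows: the statistics,
dynamics and analysis layers are exact or statistically consistent on
systems where exact answers exist. What it does not show: that any
placeholder parameter set reproduces the kinetic phenomenology of a
calibrated model at thousands of monomers — that requires the calibrated
coefficients as input.

## Numerical choices and degenerate inputs

* Reduced units $k_B = T = A = 1$ by default; parameter files may
  override all three.
* Exact integer motif counts are carried in doubles; all counts involved
  are far below the 2^53 integer-exactness limit.
* The cumulative-scan draw of the realised transition uses a fixed dyad
  order (lexicographic $(u,v)$, $u < v$), and the exit rate is re-summed
  in full each event in both update modes, so incremental and naive modes
  are bit-identical, not merely statistically equivalent.
* Empty graphs are valid everywhere: all statistics zero, Hamiltonian
  zero, average component size 1, no fibrillar components. Enumeration
  (`brute_force_distribution()`) refuses $n > 5$; the kinetic simulator
  refuses $n < 2$ (no dyads).
* Tie-breaks: argmax ties in epoch detection take the first frame;
  `classify_topology()` reports *all* matching classes with a warning on
  ambiguity rather than picking one.
* A vertex may belong to at most one fibrillar component (components are
  disjoint by construction); overlapping alternative segmentations are
  not enumerated.

## Known limitations

* The bridge-splitting recursion picks the first bridge in label order;
  for pathological tangles of many cross-linked fibrils the decomposition
  is deterministic but not guaranteed to maximise retained fibril
  content.
* The rescue pass is a single round anchored on strictly verified
  components; chains of mutually dependent rescues (two defect-decorated
  interior monomers adjacent to each other, each needing the other
  removed first) can leave a component split one monomer short.
* Local fibrillarity inspects 1-neighbourhoods only; structures that are
  locally template-consistent but globally wrong are caught at the
  component level, at the cost of discarding (not trimming) bridgeless
  offenders such as closed rings.
* `run_cli()` reads whole trajectories into memory; at the $10^6$-event
  scale use `frame_interval`/`stride` to keep the metric layer cheap.
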