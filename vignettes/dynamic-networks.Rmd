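---
title: "Dynamic residue networks, allosteric pathways and the ensemble allosteric model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic residue networks, allosteric pathways and the ensemble allosteric model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The problem

When a protein is mutated at a site far from its functional surface, the
structural consequences are often not local: perturbations propagate along
networks of dynamically coupled residues, and the regions that deform are
the regions those networks cover.  `allonet` implements, as one tested
pipeline, the computational machinery used to locate such networks from a
conformational trajectory and from a thermodynamic ensemble model, to trace
candidate allosteric pathways from a mutation site to its responding
regions, and to quantify how well networks found by different methods
agree.

The pipeline has four analytical stages, each usable on its own:

1. **Cross-correlation analysis** of residue fluctuations (DCCM),
2. a **correlation-weighted, contact-filtered residue graph** with
   shortest-path allosteric pathway search,
3. **betweenness-centrality and reachability profiling** of the
   unweighted contact network, and
4. a **COREX-style ensemble allosteric model** (EAM) with thermodynamic
   alanine scanning.

## Cross-correlation of residue motions

For residues $i, j$ with node-atom displacement vectors
$\Delta\mathbf r_i$ (deviation from the window-mean position after
rigid-body superposition), the dynamical cross-correlation is

$$C(i,j) \;=\;
\frac{\langle \Delta\mathbf r_i \cdot \Delta\mathbf r_j\rangle}
     {\langle \Delta\mathbf r_i^2\rangle^{1/2}
      \langle \Delta\mathbf r_j^2\rangle^{1/2}},$$

with $\langle\cdot\rangle$ the average over the selected frame window.
$C = +1$ is fully correlated (same-phase) motion, $-1$ fully
anti-correlated.  `superpose_frames()` performs the Kabsch fit (all nodes,
mean reference iterated twice, no scaling), and `compute_dccm()` evaluates
the matrix.  The same normalized covariance serves both the classification
map and the network edge weights; one implementation avoids the two stages
silently diverging.

**Windowing.** Equilibrium analyses conventionally use the tail of a
production run; the default window is the final 10% of frames,
configurable as an absolute frame interval (1-based, inclusive).

**Node schemes.** The DCCM is computed on C$\alpha$ nodes by default,
while both contact networks use C$\beta$ nodes (C$\alpha$ standing in for
glycine, which has no C$\beta$).  Both schemes are exposed everywhere and
share one residue index, so the stage-specific conventions can be followed
or overridden per run.

**Region tiers.** `classify_regions()` partitions residues by their
correlation with an anchor residue into red ($C \ge 0.7$), orange
($0.55 \le C < 0.7$), yellow ($0.4 \le C < 0.55$) and anti-correlated
($C \le -0.4$) tiers, leaving the rest unclassified.  Published
correlation maps present these tiers as a qualitative color scale without
numeric boundaries; the defaults above are therefore explicit
configuration, recorded in each region set's provenance note, and the
classifier is monotone in them (raising a boundary never grows its tier).

## The weighted dynamic network and allosteric pathways

`build_weighted_network()` connects residues $i \ne j$ whose C$\beta$
contact frequency over the trajectory is at least 0.5 at a 5.7 Å cutoff
(the published pruning rule removes frequencies *strictly below* the
threshold, so exactly-0.5 contacts are retained).  Each retained edge
carries the correlation weight $E_{ij} = C_{ij}$ and a path cost.
Dijkstra's algorithm needs strictly positive costs while correlations live
in $[-1, 1]$, so the default transform is

$$w_{ij} = -\ln\lvert C_{ij}\rvert,$$

the standard choice in correlation-based network analysis: strongly
coupled pairs (correlated *or* anti-correlated — both carry the
perturbation) make short edges.  $|C|$ is floored at $1 - 10^{-12}$ so
perfectly correlated pairs keep a positive cost, and $C = 0$ pairs are
dropped (infinite cost).  A linear $w = 1 - |C|$ transform is available by
flag; the transform in force is recorded in the graph's metadata.

`shortest_path()` is a hand-written $O(n^2)$ Dijkstra with fully
deterministic tie-breaking — minimum cost, then fewest hops, then the
lexicographically smallest residue sequence — so reported pathways are
reproducible run to run (library implementations do not specify their tie
behaviour).  `allosteric_pathways()` traces one shortest path from a
mutation site to every residue of a target region and de-duplicates the
union of traversed edges, the representation used to overlay pathways on a
structure.  Unreachable targets produce explicit no-path entries rather
than errors.

## Centrality profiling

The second, unweighted network connects C$\beta$ nodes within 7.0 Å,
per frame.  On it:

* **Betweenness centrality** $BC(v)$ sums, over unordered node pairs
  $(s,t)$ with $s \ne v \ne t$, the fraction of shortest $s$–$t$ paths
  passing through $v$.  The verbal definition of BC in the literature is
  count-based and ambiguous when several equal-length shortest paths
  exist; `allonet` adopts fractional (Brandes) counting, the convention of
  the standard network toolchains, computed via igraph and validated
  exactly against an independent BFS-path-counting oracle.  A normalized
  variant divides by $(N-1)(N-2)/2$.
* **Reachability** $L_i$ is the mean hop-count distance from residue $i$
  to all others.  Pairs unreachable within a frame are excluded from the
  mean (the denominator shrinks) and tallied separately; a residue
  isolated in every frame reports `NA`, never a silent 0.
* `delta_profile()` forms per-residue differences between two states
  (mutant minus wild type, or later window minus first); negative
  $\Delta L_i$ means the protein has become more traversable through
  residue $i$.  Both a two-network mode and a sliding-window mode are
  supported, since a "change in reachability" can be taken along a
  trajectory or between variants.
* `peak_residues()` flags profile peaks (local maxima with z-score
  $\ge 2$ by default, or top-$k$), the residues read as communication
  hubs.

Distances here are hop counts, not correlation costs: this network's edges
are defined purely by the geometric cutoff, in contrast to the weighted
pathway graph.

## The ensemble allosteric model

The chain is tiled N- to C-terminus into contiguous *folding units* of 8
residues, with terminal units no shorter than 4 (a 164-residue chain gives
20 × 8 + 1 × 4 = 21 units; a trailing remainder shorter than 4 merges into
the last unit).  Each unit folds or unfolds as a body, giving $2^U$
exhaustively enumerated states; state free energy is the sum of the
unfolding penalties $g_u$ of unfolded units, the fully folded state is the
$G = 0$ reference, and Boltzmann probabilities use
$R = 1.987 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ at $T = 298.15$ K
(25 °C) by default.  For residue $j$ in unit $u$,

$$\kappa_{f,j} = \frac{\sum_{\text{states: } u \text{ folded}} P}
                     {\sum_{\text{states: } u \text{ unfolded}} P},
\qquad \Delta G_{f,j} = -RT \ln \kappa_{f,j},$$

and a mutation at residue $k$, modelled as a perturbation $\delta_k$ of
$k$'s unit energy, changes every residue's free energy by

$$\Delta\Delta G_{j,\mathrm{mut}\,k} =
  \Delta G_{f,j}^{\mathrm{mut}\,k} - \Delta G_{f,j}^{\mathrm{WT}}.$$

**Unit energies are a declared surrogate.**  The original COREX
surface-area-based enthalpy/entropy parameterization is not published in a
reproducible form, so `allonet` keeps the ensemble machinery exact and
makes the one unspecified ingredient pluggable: uniform $g_u$ calibrated
so the fully unfolded state sits at the overall stability (default
5 kcal/mol — so $U = 5$ units get $g_u = 1.0$ each), user-supplied
energies, or contact-density-derived energies
(`contact_unit_energies()`: $g_u$ proportional to the unit's mean 7.0 Å
node contact number, rescaled to the overall stability).

**Alanine-scan default.**  The energetic magnitude of an Ala substitution
is likewise unspecified; the bundled default is
$\delta = -0.12$ kcal/mol per side-chain heavy atom removed relative to
alanine (destabilizing, since truncation removes packing; glycine gains an
atom and gets $+0.12$), always overridable per run.

**Known limitation — additivity.**  Because state energies are strictly
additive over units, unit stabilities factorize and a mutation's
$\Delta\Delta G$ is confined to its own folding unit; inter-unit
thermodynamic coupling would require an energy function with unit–unit
interaction terms (as the surface-area-based COREX energetics provide).
The susceptibility cutoffs (0.2, 0.6 and 1.0 kcal/mol are the
conventional tiers for mild through strong perturbations) and
`susceptible_regions()` behave identically either way; under the additive
surrogate the default cutoff is 0.2 kcal/mol because the default
$|\delta|$ values (≤ ~1.1 kcal/mol) put responses in the mild regime.
Absolute-value thresholding is the default, signed thresholding a flag,
because published descriptions alternate between "change greater than"
and "absolute change greater than".

**Shifted partitions.**  `make_partition(shift =)` slides the window
start, COREX-style; a single shift-0 partition is the default because
averaging across shifts is not part of the documented procedure.  The
enumeration is capped at $U = 24$ (16.8M states) and never sampled: above
the cap the model asks for a coarser window rather than silently
approximating.

## Consistency metrics

"Percent consistency" between two networks is directional and is read as
recall of the reference set:

$$\text{percent} = 100 \cdot
  \frac{|\text{residues(query)} \cap \text{residues(reference)}|}
       {|\text{residues(reference)}|}.$$

Because method-vs-method comparisons are sometimes quoted symmetrically,
every `consistency_percent()` report also carries the Jaccard index, so
the directional and symmetric readings are never conflated.
`common_regions()` intersects region sets and `render_track()` lays
labelled networks out as a per-residue 0/1 table, the tabular form of the
sequence-track figures used for such comparisons.

## Synthetic data: what it emulates, and what it does not

The generator exists so every stage is testable against analytic ground
truth without simulations or downloads:

* `make_helical_bundle()` builds idealized α-helices (1.5 Å rise, 100°
  twist, 2.3 Å backbone radius, consecutive C$\alpha$ ≈ 3.8 Å) packed on
  a 9 Å axis circle, with a pseudo-C$\beta$ 1.53 Å from the C$\alpha$.
  The pseudo-C$\beta$ is tilted 45° from the radial normal toward the
  N-terminus: a purely radial placement puts even $i,i{+}1$ C$\beta$
  pairs at 5.87 Å — outside the 5.7 Å cutoff — whereas the tilt
  reproduces the canonical helical contact pattern ($i{\pm}1$ and
  $i{\pm}3$ inside 5.7 Å, $i{\pm}4$ inside 7.0 Å).  A 0.01 Å seeded
  jitter breaks exact symmetry.
* `make_correlated_trajectory()` draws per-residue displacements per axis
  from a multivariate normal with a planted correlation matrix, identical
  on x/y/z and rigid within a residue, so the vector-dot DCCM of any pair
  equals the planted scalar in expectation — an analytic oracle.  A block
  $(A, B, \rho)$ implies $\rho$ across the sets and $|\rho|$ within each
  (the rank-one sign completion $C = (1-|\rho|)I + |\rho|\,ss^\top$ on
  $A \cup B$); this completion is what keeps strong cross-block
  correlations positive semi-definite, and the PSD property is validated
  before sampling.  The default displacement scale is 0.5 Å per axis,
  the magnitude of typical equilibrium C$\alpha$ fluctuations in a folded
  protein.
* `make_random_graph()` provides seeded positive-cost graphs small enough
  for exhaustive path enumeration.

What the generator does **not** emulate: a physical force field, solvent,
kinetics or autocorrelation in time (frames are independent draws),
anisotropic or site-dependent fluctuation amplitudes, and side chains
beyond the single pseudo-C$\beta$.  Passing tests therefore demonstrate
the correctness of the *analysis machinery* — recovery of known
correlation structure, exact agreement with graph and ensemble oracles,
deterministic end-to-end behaviour — not the physical fidelity of any
particular molecular system.

## Numerical choices

* Correlations are clamped to $[-1, 1]$, the matrix symmetrized and the
  diagonal pinned to exactly 1 after the vectorized accumulation; the
  result agrees with a naive two-pass direct summation to $10^{-12}$.
* A zero-variance node (a frozen residue) is an error naming the residue,
  since the normalization would divide by zero.
* Degenerate (collinear) frames are rejected before superposition: the
  Kabsch rotation is underdetermined there.
* Dijkstra cost ties use a relative tolerance of $10^{-9}$; tie-breaking
  is fewest hops then lexicographic, and the brute-force enumeration
  oracle implements the identical ordering so determinism itself is
  tested.
* $\kappa_{f,j}$ with no reachable unfolded states is reported as `+Inf`
  with $\Delta G_f = -\infty$ (flagged, never `NaN`).
* All randomness flows through explicit seeds via a local RNG guard; no
  function disturbs the caller's RNG state.

## Problem sizes used by the shipped validation

The test suite validates against oracles at sizes where exhaustive
computation is exact and fast: DCCM fixtures up to 50 residues × 1000
frames (and 5000-frame recovery runs at 12 residues), 200 random graphs
with $n \le 10$ for path enumeration, 100 graphs with $n \le 12$ for
centrality counting, ensemble systems up to $U = 16$ (65,536 states), and
an end-to-end 4-helix, 40-residue bundle with a 120-frame trajectory whose
outputs are byte-compared across reruns and against stored golden copies.
The acceptance script repeats these measurements from scratch at the same
scales plus an 80-residue, 600-frame pipeline run.
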