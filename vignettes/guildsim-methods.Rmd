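---
title: "Methods: eco-evolutionary simulation of foraging guilds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary simulation of foraging guilds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildsim)
```

guildsim is a stochastic, agent-based simulator for studying how foraging
and movement strategies evolve in a guild of consumers exploiting a patchy,
renewing resource. Agents carry a three-parameter heritable movement rule,
accumulate biomass by extracting resources, and reproduce under clonal,
phenotype-averaging sexual, or diploid codominant random-mating genetics.
The central questions it supports are (i) whether guilds self-organize into
coexisting movement-strategy morphs (behavioral polymorphism) and (ii) how
collective biomass production differs between clonal and randomly mating
guilds.

## Model structure

The model runs on three nested clocks:

1. **Tick** (`step_tick`): every agent simultaneously decides to stay or
   relocate within its Moore neighborhood, stayers extract resources, and
   every patch renews.
2. **Generation** (`run_generation`): `n` ticks (default 100). Biomass is
   reset at the start and the final biomass \(B_a(n)\) is the fitness
   measure.
3. **Epoch** (`run_epoch`): `G` generations (default 200). After each
   generation the fittest half reproduces; mutation size anneals over
   generations.

### Landscape

The landscape is a rectangular cellular array (default \(20 \times 20\),
400 patches), toroidal by default. Each cell holds one resource stock
\(R_k\). At the start of every generation each stock is drawn uniformly on
\([R_{\min}, R_{\max}]\) (baseline \([2.99, 3.00]\): nearly homogeneous,
with just enough spread to randomize initial movement). After extraction a
patch renews as

\[ R_k(t+1) = R_k^* + r\,(1 - R_k^*/s)\,(R_k^* + g), \]

where \(R_k^*\) is the post-extraction stock, \(r\) the intrinsic growth
rate, \(s\) the saturation level (a fixed point of the map), and \(g\) a
reservoir term that reseeds an emptied patch. For the baseline parameters
this map is strictly increasing on \([0, s]\) and keeps stocks in
\((0, s]\).

The topology choice (toroidal versus bounded) is genuinely open; we default
to toroidal because it removes edge effects and gives every cell a full
8-cell neighborhood, and retain the bounded mode for sensitivity checks. At
bounded edges, neighborhood means divide by the actual neighbor count so
that cell values remain comparable across the grid.

### Perception and movement

An agent at cell 0 with Moore neighbors \(\ell = 1..8\) perceives, for each
of the nine cells, the resource \(R_\ell\), the occupancy \(J_\ell\), and
their neighborhood means \(R^M_\ell, J^M_\ell\), all from the synchronous
pre-movement state. The focal agent is removed from the occupancy field it
perceives (its own presence is not competition); this is configurable via
`self_excluded`. Each cell is scored

\[ V_\ell = R_\ell - \delta J_\ell + \alpha\,(R^M_\ell - \delta J^M_\ell), \]

with \(\alpha\) the *neighbor-discount* (weight on second-tier information)
and \(\delta\) the *competition-tradeoff* (resource-equivalent penalty per
competitor). The movement rule is:

> **Stay** iff \(V_0 > 0\) and \(\rho\, V_\ell < V_0\) strictly for all
> \(\ell = 1..8\); otherwise **move** to \(\arg\max_{\ell = 0..8} V_\ell\)
> (ties uniform at random; target 0 is a "move in place" that pays the
> movement cost and forgoes extraction).

So an agent abandons its cell only when some neighbor is at least
\(1/\rho\) times as valuable: small \(\rho\) is a sedentary type, \(\rho\)
near 1 a restless one. We note a deliberate reading here. The source
description of this rule can be read with the threshold on the other side
of the ratio (stay iff \(V_\ell / V_0 < \rho\)). Under that reading, on a
near-homogeneous landscape all ratios are \(\approx 1\), no agent with
\(\rho < 1\) can ever stay, nothing is ever extracted, and fitness is
identically zero — which contradicts the description of small-\(\rho\)
types as ones that "resist moving", the reported interior optimum of
\(\rho\) within \([0, 1]\), and every reported fitness level. The
reciprocal form implemented here reproduces all of those qualitative
facts, and we treat the printed inequality placement as a typo. The strict
inequality is kept: the equality case triggers a move.

### Extraction and biomass

After movement, the \(N_k\) agents that chose to stay in cell \(k\) each
extract

\[ F_k = \min\left\{ \frac{R_k}{N_k},\; \frac{u R_k}{h + R_k + q N_k} \right\} \]

(per-capita share capped by a crowding-depressed functional response;
total extraction can never exceed the stock) and gain \(\kappa F_k\)
biomass. Every agent that moved — including in place — extracts nothing
and is charged the multiplicative movement cost \(B \leftarrow (1-c)B\).
Move-in-place agents do not join the extracting set (they pay the cost "as
though they moved") but do count in the next tick's occupancy.

### Genetic algorithm

At the end of a generation agents are ranked by \(B_a(n)\) and the top half
become parents (hard selection; ties broken by agent index). The maximum
mutation size anneals over generations,

\[ \mu(T) = \frac{\mu_0 - \mu_\infty}{1 + (T/\psi)^3} + \mu_\infty, \]

so \(\mu(0) = \mu_0\), \(\mu(\psi) = (\mu_0 - \mu_\infty)/2 + \mu_\infty\)
and \(\mu(T) \to \mu_\infty\): early generations explore, late ones refine.
Every mutation adds an independent draw from
\(\mathrm{Uniform}[-\mu(T), \mu(T)]\), with **no clamping** — evolved traits
can leave \([0,1]\) and negative competition-tradeoff values do occur.

Three reproduction modes (all keep the population at exactly \(N_A\)):

* **Clonal**: parents persist unchanged; each contributes one clone with
  all three traits independently perturbed.
* **Averaging sexual**: parents are shuffled and paired; each pair leaves
  four progeny whose traits are parental midpoints, then mutated; full
  replacement.
* **Diploid codominant random mating**: each trait is a pair of alleles;
  progeny inherit one allele per trait from each parent by random
  segregation with no linkage; every inherited allele is mutated; the
  expressed trait is the allele mean (codominance). Hermaphroditic: any
  two parents can pair, each parent is in exactly one pair.

Founding populations draw every trait (and both alleles of every trait)
independently from \(\mathrm{Uniform}[0, 1]\). The distribution for the
movement threshold follows the reported initialization; the other two
traits are unstated in the source material and we adopt the same
convention, configurable through `init_population`.

Each allele copy carries a lineage tag from the founding generation, so
genotype tabulation (`genotype_counts`) never depends on rounding of
evolved allele values; a value-binning mode (`tol = 0.02`) exists for
value-only snapshots.

## Analysis layer

* `hw_expected_counts` estimates allele frequencies from observed genotype
  counts and computes Hardy-Weinberg expected counts (\(Np_i^2\),
  \(2Np_ip_j\)) with a chi-square over all genotype classes of the observed
  alleles, `df = #classes - #alleles` (frequencies are estimated from the
  data); classes with zero expected count are excluded.
* `classify_morphs` groups phenotypes into morphs by single-linkage
  clustering in trait space cut at a gap threshold (default 0.03, the
  scale of late-epoch mutation noise). The clustering choice is ours: the
  source identifies morphs visually and provides no algorithm.
* `run_experiment`/`compare_modes` run replicate epochs per reproduction
  mode, aggregate per-run biomass totals over two 125-generation phases
  (burn-in, approach to equilibrium), and compare modes with a Welch
  two-sided t-test plus an F variance-ratio test.

## Numerical and implementation choices

* Two tick engines: a plain-R reference (`step_tick`) and a compiled Rcpp
  engine (default). Both consume one RNG stream in a documented order
  (placement, resource initialization, decision tie-breaks, reproduction),
  draw a tie-break uniform only when a tie exists, and accumulate
  neighborhood sums in extended precision, so a fixed seed reproduces the
  same trajectory **bit-exactly** on either engine; the test suite asserts
  exact agreement on random worlds.
* The bound \(N_k F_k \le R_k\) holds mathematically; the one-ulp rounding
  residue of `R - N*F` is clamped at zero before renewal in both engines.
* Argmax ties are broken with `floor(unif() * k)` rather than `sample()`
  so the compiled engine can mirror the draw exactly.
* Initial biomass is \(B_a(0) = 0\) (unstated in the source; fitness is
  then pure accumulated gain, and any common offset would be neutral to
  selection anyway).

## Units of the fitness scale

Movement decisions depend only on the landscape, never on biomass, and the
movement cost is multiplicative; consequently every reported biomass is
*exactly linear* in the conversion rate \(\kappa\), and the evolved
trajectories, rankings, morph structure and mode comparisons are invariant
to it. Absolute fitness levels additionally depend on the cost parameter
\(c\). Under the baseline configuration used here (\(\kappa = 0.1\),
\(c = 0.1\), movers extract nothing) the final biomass of a lone forager
has a ceiling of roughly \((1-c)\kappa h_{\mathrm{cycle}}/c \approx 20\)
(where \(h_{\mathrm{cycle}} \lesssim 23\) resource units is the most a
forage-and-move cycle can harvest from a saturated patch), and the
acceptance script measures two-agent epochs at \(\approx 14\). Reported
absolute levels from other implementations of this model family are
therefore comparable only up to this gain scaling; the relative phenomena
(density dependence of fitness, polymorphism, clonal-versus-sexual
production gap, Hardy-Weinberg structure) are the reproducible content.

## What the simulator emulates — and what it does not

The simulator is its own data generator: all experiments are
self-generating from configuration and seed. It emulates patchily renewing
resources, local perception, intraspecific competition and short-generation
evolution. It does **not** emulate: sensory noise or distance-attenuated
perception, memory, heterospecifics, spatially autocorrelated resource
initialization, patch-specific growth or extraction parameters, soft
selection, assortative mating, dominance, linkage, or distinct sexes.
Passing tests therefore demonstrate internal consistency of the model and
its statistics, not fidelity to any field system.

## Problem sizes used by the test suite

The suite exercises full-size epochs where the scientific claim requires
them (two- and ten-agent epochs at \(G = 200\), a 100-agent epoch at
\(G = 200\), and a 10-runs-per-mode comparison of 100-agent epochs at
\(G = 250\)); engine-equivalence and invariant sweeps use \(5 \times 5\)
worlds with up to 8 agents over 20-40 ticks, which cover all code paths at
a fraction of the cost. Replicate counts for distributional checks (40
replicates of 10,000 progeny for Hardy-Weinberg; 400 neutral generations
for allele-frequency conservation) were chosen to keep Monte-Carlo error
well below the asserted margins.

## Known limitations

* The morph count from `classify_morphs` depends on the gap threshold;
  0.03 suits late-epoch mutation noise under the default schedule but
  should be rescaled if \(\mu_\infty\) changes.
* With two agents, selection retains a single lineage and its clone, so
  evolved-trait readouts are effectively one strategy per run.
* The chi-square in `hw_expected_counts` assumes multinomial sampling;
  scoring whole sibships (four pseudo-replicated progeny per pair)
  overdisperses the counts, so distributional tests score one progeny per
  sibship.
* Long epochs at high density are dominated by competition-mediated
  frequency dependence; absolute biomass levels are sensitive to \(c\) and
  scale with \(\kappa\) as described above.
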