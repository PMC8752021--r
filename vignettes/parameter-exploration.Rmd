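---
title: "Normalized gradient ascent for tuning stochastic evolutionary simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized gradient ascent for tuning stochastic evolutionary simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoxplore)
```

## The problem

Monte-Carlo models of early molecular evolution — RNA pools, replicator
lattices, protocell populations — carry many per-step event probabilities
that cannot be pinned down from prebiotic chemistry. Research in this area
therefore often runs "in reverse": one searches the parameter space for
settings under which a hypothesized scene (a ribozyme spreading, replicators
growing longer) actually happens, and treats the found region as a
prediction about the required chemistry. Done by hand, that search is
laborious and hard to report. `evoxplore` automates it: any scalar readout
of a simulation run becomes an objective function, and the package adjusts
all parameters simultaneously to increase it.

## The update rule

Let $p_1,\dots,p_n$ be the explored parameters and
$O = \mathrm{Model}\{p_1,\dots,p_n\}$ the objective, a single stochastic
simulation readout. One learning round costs $n+1$ simulations:

1. **Base evaluation.** $O$ at the current values.
2. **Probes.** For each $i$, re-evaluate with only $p_i$ moved by the
   testing rate $e$ in its remembered direction $s_i$ (upward:
   $p_i(1+e)$; downward: $p_i(1-e)$, or $p_i/(1+e)$ under the
   multiplicative variant), giving $\Delta O_i$.
3. **Normalized update.** With $M = \max_i |\Delta O_i|$ and the signed
   slope $g_i = s_i \, \Delta O_i$, every parameter moves at once:
   $p_i \leftarrow p_i\,(1 + e \, g_i / M)$ (the downward multiplicative
   form divides by $1 + e\,|g_i|/M$). The parameter with the largest
   $|\Delta O_i|$ takes the full step; all others move in proportion to
   their potential. If $M = 0$ the round changes nothing.
4. **Direction memory.** The next round probes each parameter in the
   direction it just moved, $s_i \leftarrow \mathrm{sign}(g_i)$; a
   parameter whose probe left the objective unchanged is probed upward
   (configurable to downward).

The testing rate and the learning rate are deliberately one quantity `e`:
probing much finer than one is willing to step wastes simulations on a
noisy objective, and stepping further than one has probed is unjustified.
All updates are multiplicative, so parameters never change sign;
probability-kind parameters are clamped to $[10^{-12}, 1]$ (a strictly
positive floor, because a multiplicative update can never leave an exact
zero) and positive reals to $[10^{-12}, 10^6]$, with a warning when a
clamp fires.

Two alternative strategies are provided. **Coordinate ascent** visits the
parameters one at a time, evaluating the current value, three upward
values $p(1+e)^k$ and three downward values $p(1-e)^k$, $k = 1..3$, and
greedily installing the argmax before the next visit; the incumbent is
re-evaluated with a fresh random stream at every visit because a stale
value of a stochastic objective would bias the argmax, and ties break in
the incumbent's favor. **Progressive learning** chains gradient-ascent
stages whose objectives read the simulation at successively later steps;
each stage is warm-started from the previous stage's final parameters and
direction memory, so the cheap early stages move the parameters into the
right region and only the last stage pays for full-length simulations.

### Numerical behavior near an optimum

The full-step normalization means the update never shrinks as the optimum
is approached: the best parameter always moves by the factor $1 \pm e$.
On a smooth deterministic objective the iteration therefore ends in a
limit cycle around the optimum whose log-amplitude is of order $e$, not at
the optimum itself. This is intentional — the method's purpose is to find
*a good region* of a noisy simulator's parameter space, where objective
fluctuations dwarf such wobble, and no learning-rate annealing is applied.
Users who need a polished point estimate should re-run with a smaller `e`
from the found region. The parameter-recovery check in the test suite
documents this floor: with `e = 0.2` the worst recovered coordinate of
the bundled concave objective typically sits 5–20% from the optimum and
does not tighten further with more rounds.

### Randomness and reproducibility

A master seed is the only source of randomness. Every objective
evaluation receives an independent child seed derived from the path
(round, evaluation slot, replicate) by a counter-based congruential mix
(exact in doubles, modulo $2^{31}-1$), so traces are bit-reproducible and
evaluations are independent of execution order. Fresh randomness per
evaluation is the default — matching the visible round-to-round
fluctuation of a stochastic objective; replicate averaging
(`replicates_per_evaluation`) is available for variance reduction.

## The NSR testbed

A toroidal `grid_side` × `grid_side` grid of rooms models a prebiotic RNA
pool. Material is conserved exactly: every unit is at all times a
precursor, a free nucleotide, or a residue in a strand, and the test
suite asserts the invariant under arbitrary parameter values. Each step
applies, in fixed order: nucleotide formation (probability `PNF` per
precursor, or `PNFR` — the enzymatic rate — in rooms holding a functional
nucleotide synthetase ribozyme), nucleotide decay (`PND`), random
ligation of disjoint molecule pairs (`PRL`; free nucleotides count as
length-1 molecules), bond breaking in single-stranded molecules (`PBB`),
template-directed synthesis (attachment `PAT`, false pairing `PFP`,
duplex separation 0.5), and movement to adjacent rooms (`PMV`).

An NSR is any single-stranded molecule containing the 10-nt NSR motif;
the control species is an equal-length motif with no catalytic role;
the complement of a motif is a different molecule. Copying proceeds via a
nascent complementary strand, so an NSR's direct copy is *not* an NSR —
its copy's copy is. A consequence worth knowing when reading counts: a
molecule busy templating is a duplex and is not counted, so the
single-stranded NSR count is a thinned (roughly $1/(1+L)$) but
proportional readout of the true lineage size. Knock-out mode removes
catalytic function while preserving motif identity — the control for the
question "did the explorer exploit the ribozyme's function, or would any
sequence have spread?"; by symmetry the NSR-minus-control readout is then
centered at zero, which the suite checks across replicate runs.

Event order (producers before consumers), the replacement of `PNF` by
`PNFR` in catalyzed rooms, decay acting on free nucleotides only, and
uniform initial distribution of material are all reconstruction choices:
they are the simplest rules consistent with the parameters' meanings, and
the package's contract is the qualitative behavior (decline under the
unfavorable reference setting, spread under the favorable one), not any
absolute count.

## The replicator testbed

A toroidal lattice holds at most one replicator per site. A replicator is
a count vector of monomers devoted to replicase activity (A), fidelity
(B), metabolism (C) and neutral filler (N); length $L$ is the total.
Class activities follow
$\beta_X \, l_X/(l_X+\gamma_X)\, e^{-\alpha_X L}$ — $\beta$ scales,
$\gamma$ half-saturates, $\alpha$ penalizes total length, and class C has
no $\alpha$. Each sweep: every empty site runs a lottery among its Moore
neighbors with claim weight

$$w(T) \;=\; S_A(T)\; a_C(T)\; \big/\; (1 + L_T/\lambda),$$

where $S_A$ sums replicase activity over $T$'s neighbors (a molecule
cannot copy itself, so replicase is strictly trans-acting), $a_C$ is
$T$'s *own* metabolic activity (its products accumulate at its own site),
and $\lambda$ = `copy_cost_scale` is the length scale of the copy-speed
penalty. The site is filled with probability $\min(1, \sum w / K)$ by a
copy of the weight-proportional winner; copying applies a per-monomer
error rate $\varepsilon_0/(1+S_B)$ with $S_B$ including the parent's own
fidelity activity, errors being substitutions to a random class or, with
probability `indel_fraction`, single-monomer insertions/deletions. Decay
(`d`) and dispersal (swap with a random von Neumann neighbor, `D`) close
the sweep.

This division of cis and trans roles is the load-bearing design choice.
With every activity acting purely in trans, a replicator's own genome
could only *penalize* its claim, making shortness unconditionally
advantageous within any cluster; in exploratory runs the population then
collapsed to length-1 genomes under every constant regime tried. Giving
metabolism (and proofreading) a cis component creates a genuine interior
length optimum — more C monomers fuel one's own replication until
saturation meets the copy-speed cost — while keeping replicase trans
preserves the cooperation tension that makes limited dispersal matter:
well-mixed populations (`D = 1`) do no better than weakly-mixed ones, a
one-sided comparison the suite tests.

The fixed constants were chosen once, by scanning for the regime in which
the mechanism of interest is expressed, and then frozen: lattice 30×30
(tests) or 100×100 (full runs), occupancy 0.5, founder length 5
(one monomer of each activity class, two neutral), $d = 0.07$,
$D = 0.01$, $\varepsilon_0 = 0.05$, indel fraction 0.2, $K = 0.2$
(calibrated so initial claim probabilities fall in ≈0.1–0.5),
$\lambda = 25$. In this regime the favorable reference parameter set
($\alpha = 0.1$, $\beta_{A,B} = 3$, $\beta_C = 2$) evolves mean length
from 5 to ≈11–13 within 15,000 sweeps, while the unfavorable start
($\alpha = 0.2$, $\beta_{A,B} = 2$, $\beta_C = 1$) sits just past the
viability edge and goes extinct — whereupon the mean-length objective
reports its starting value 5 by convention (the "odd point" rule). That
edge placement is what makes the unfavorable start learnable: a +20%
probe on $\beta_A$ or $\beta_C$ is viable, handing the explorer a
full-step gradient in the very first round.

## Scaled-down study conditions

Full-scale schedules (30×30-room pools of 40,000 material units read at
step 150,000; 100×100 lattices read at step 10^6) are exposed as
`*-full` presets but cost hours per learning run. The test suite and the
acceptance script use the `*-test` twins, chosen so that each qualitative
contract is expressed in minutes on one core:

* NSR: 10×10 rooms, 3,000 material units, 100 molecules inoculated at
  step 300, objective read at step 5,000. The inoculum size keeps the
  starting objective around 5–15 counts — large enough that probe
  differences carry signal over Monte-Carlo noise, which sets the floor on
  how far this testbed can be scaled down.
* Replicator: 30×30 lattice, objective read at sweep 30,000 (by which
  point the favorable length trajectory has plateaued); progressive
  stages at 3,000/6,000/12,000/30,000 sweeps, 15 rounds each, mirroring
  the 1:2:4:10 ratio of the full schedule.

What passing at this scale shows — and does not show. The scaled worlds
exercise every mechanism (catalysis, template copying, knock-out
symmetry, extinction, warm-started staging) and the full learning loop
against them. They do not reproduce absolute counts of any full-scale
run: a 10×10 pool holds ~13× less material than the full configuration,
so plateau counts, times-to-balance and learned parameter values differ
from full-scale figures, and no test asserts them.

## Degenerate inputs and tie-breaks

* Zero total gradient ($M = 0$): the round is skipped and direction
  memory retained.
* Coordinate-ascent ties: the incumbent wins, then the earlier candidate
  in the fixed order (current, up ×3, down ×3).
* Multiple parameters tying at $M$: all of them take the full step.
* Candidates outside a parameter's bounds are dropped (coordinate
  ascent) or clamped (gradient probes and updates), with a warning on
  clamped updates.
* A non-finite objective value aborts the run with the offending
  candidate named; extinction is *not* non-finite — the replicator
  objective maps it to the fallback length.

## Known limitations

* Both testbeds are reconstructions built from the published meanings of
  their explored parameters, not ports of the original simulators; their
  absolute numbers are not comparable to the original figures.
* The single-rate design (testing = learning rate) means accuracy near
  an optimum is bounded by $e$; there is no annealing by design.
* The NSR readout counts single-stranded molecules only, so it
  undercounts lineages busy templating; this is a consistent,
  monotone readout but not a molecule census.
* Objectives are scalar; multi-objective exploration and
  Metropolis-style or evolutionary-algorithm searches are out of scope.
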