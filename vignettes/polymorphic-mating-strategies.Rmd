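---
title: "Embodied evolution of polymorphic mating strategies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied evolution of polymorphic mating strategies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymate)
```

## The system

`polymate` simulates a small colony of simultaneous-hermaphrodite robots
that must survive by capturing energy sources and can reproduce only by
physically exchanging genotypes with a mating partner over an infrared
channel.  There is no fitness function and no centralized selection:
whoever mates at high energy leaves more offspring, and subpopulations are
refilled by sampling from the offspring pools.  The interesting outcome is
*behavioural polymorphism*: discrete mating strategies — foragers, who only
mate on direct face sight, and trackers, who wait for a partner's
tail-lamp when their energy is high enough — can coexist because of
negative frequency-dependent selection, and the package provides the tools
to phenotype them, to measure their frequency-dependent fitness, and to
analyse stability with discrete replicator dynamics.

Four robots share a 2.5 m x 2.5 m arena with 4–16 respawning energy
sources.  Each robot hosts a subpopulation of 20 individuals that control
it in random order for three periods of 400 time steps (240 ms each), a
1200-step lifetime.  The vision model is a camera with a ±45° field of
view; within ±30° of the optical axis energy sources, tail-lamps and faces
are detectable to 2.0, 1.5 and 1.0 m respectively, and the effective range
falls linearly to 0.2 m at the edge of the field of view.  A partner shows
its face when its heading points within 90° of the observer, otherwise its
tail-lamp (lit whenever the individual is alive and not refractory).
Mating requires both robots inside each other's 1 m / ±30° infrared window
both *before and after* the step's actions, and an explicit IR-initiation
action by one party.

## Genotype and control architecture

Each individual carries 51 real genes:

* **genes 1–5** — the weights $w_0 \dots w_4$ of a linear network over the
  inputs (bias 1, scaled energy, and scaled closeness of nearest energy
  source, tail-lamp, face; invisible channels read $-1$).  A positive
  output selects the *mating module*, otherwise the *foraging module*.
* **genes 6–47** — 14 coefficients per behaviour for the potential-based
  shaping rewards of the three behaviours (foraging, waiting, mating).
  Each potential is a linear combination of 14 fixed Gaussian bases (7
  angle centres x 2 distance centres, width 0.25) on the normalized
  (angle, distance) state square.  This layout is this package's own
  reconstruction: the original system's exact 42-gene parameterization is
  defined in companion work that is not part of this model; what is
  preserved is the gene count and the role of evolutionarily tuned
  shaping.
* **genes 48–51** — meta-parameters through fixed logistic squashings:
  learning rate $\in (0, 0.5]$, discount $\in [0.8, 1)$, trace decay
  $\in [0, 1)$ (plain Sarsa on half the gene range), softmax temperature
  $\in (0, 1]$.  The exact squashings are likewise a reconstruction.

Behaviours are learned from scratch every generation by Sarsa with tile
coding (8 tilings of 8 x 8 tiles per behaviour), softmax exploration, and
the shaping increments $\gamma\Phi(s') - \Phi(s)$ (with
$\Phi(\text{terminal}) = 0$), which provably leave optimal policies
unchanged.  The global reward is +1 per capture and +1 per successful
mating.  The action set is five wheel-speed pairs (forward, two arcs, two
spins); the mating behaviour adds the IR-initiation action.  When the
selected behaviour changes between steps, the outgoing behaviour receives
a terminal update; each behaviour therefore learns on its own transitions
only.  Exploration policy is softmax (the original work leaves it
unspecified).

## Reproduction and the genetic algorithm

At a successful mating each party independently reproduces with
probability $E/E_{max}$, creating two offspring in its own subpopulation
pool by one-point crossover (probability 0.1, cut uniform over the 50
internal boundaries) followed by per-gene Gaussian mutation
($N(0, 0.1^2)$, rate 0.1 per gene — the rate itself is a configurable
reconstruction).  Because the strategy block is 5 genes at the *front* of
the genome, an offspring's strategy mixes both parents only when the cut
falls inside the block:
$p_c (k-1)/(L-1) = 0.1 \cdot 4/50 = 0.8\%$ — the genetic-coherence
property that lets discrete strategy lineages persist.  Fitness is
recorded as *attributed offspring*: each offspring is credited to the
parent contributing the majority of its genes, which makes the expected
fitness per mating $\bar E_{self} + \bar E_{partner}$ and the lifetime
fitness $\bar n(\bar E_{self} + \bar E_{partner})$ — about 20 offspring at
13 matings and energies near 0.78, the scale observed in converged
populations.

Scheduling: each robot's 60 robot-periods per generation are three
independent random permutations of its 20 individuals.  When a controller
dies, the robot is handed to the next scheduled living individual
immediately, who serves a fresh 400-step period; this keeps every
surviving individual at exactly 1200 control steps while letting deaths
shift period boundaries between robots (group composition then drifts
slightly across robots, a deliberate simplification).

## Phenotyping

For an individual seeing an energy source and a tail-lamp but no face, the
waiting threshold is the minimal normalized energy at which the mating
module is selected,
$\theta = \mathrm{clip}\left(\left(\frac{w_4 - w_0 - w_2 x_b - w_3 x_t}{w_1} + 1\right)/2\right)$
for $w_1 > 0$.  For $w_1 = 0$ the output is energy-independent and
$\theta$ is 0 or 1; for $w_1 < 0$ (mating favoured at *low* energy — never
observed in evolved populations) the complementary boundary is reported,
with 0/1 when the output is positive for all/no energies.  These
conventions exist only to make the statistic total and deterministic.

$\bar\theta$ averages $\theta$ over 26 equidistant values in $[0, 1]$ per
input axis — 676 grid points.  The grid is interpreted on the *scaled
closeness* axes (the non-negative half of the input range); the original
text is ambiguous about raw-distance vs scaled semantics, and the choice
is recorded here and in the output metadata.

Classification: populations with median $\bar\theta > 0.98$ are forager
populations; otherwise SD $\le 0.19$ means tracker and larger SD means
polymorphic (the boundary value is assigned to tracker).  Genotype-level
clustering is k-means on the $(w_0, w_4)$ plane, with clusters named by
their median $\bar\theta$; trackers are further split into strong
($\bar\theta \approx 0.22$) and weak ($\bar\theta \approx 0.48$)
sub-phenotypes by 1-D k-means.

## Fitness curves, mating mix, replicator dynamics

`fixed_proportion_experiment()` measures frequency-dependent fitness
directly: subpopulations are assembled from phenotype pools at fixed
ratios (rounded to multiples of 1/80 and logged), a single generation is
simulated without evolving the composition, and per-phenotype mating
counts, energies and attributed offspring are aggregated over replicates.
The mating-mix model summarises who mates with whom: trackers mix in
proportion to availability, foragers over-sample trackers by a factor
$1 + \alpha(1 - r_T)$, and the bookkeeping symmetry
$N_F m_{FT} = N_T m_{TF}$ then forces the mating-frequency ratio
$\gamma(r_T) = 1/(1 + \alpha(1 - r_T))$.  The explicit functional forms
are this package's reconstruction from those three constraints; they
reproduce the qualitative signatures (a $\gamma$ rising from about 0.88
towards 1 as $r_T$ goes from 0.125 to 0.875 at $\alpha = 0.15$).
`fit_mating_model()` fits lines to $\bar n(r_T)$, constants to the
energies, $\alpha$ by least squares on $\gamma$, recomposes predicted
fitness curves, and locates their crossing — the candidate evolutionarily
stable mixture.

Stability analysis uses the discrete replicator map
$p_i' = p_i \bar F_i / \sum_j p_j \bar F_j$.  `stability_map()` evaluates
the one-generation displacement on a simplex lattice (default step 12.5%,
matching the tested proportions), flags attractors (displacement below
0.01 with all neighbouring arrows pointing inward), and supplies
barycentric (de Finetti) coordinates $x = p_2 + p_3/2$,
$y = \frac{\sqrt3}{2} p_3$ for the three-phenotype diagram.  Finite
population corrections (Moran/Wright–Fisher) are out of scope.

## Numerical and calibration choices

The arena, vision ranges, lifetime structure, crossover rate and mutation
SD are the printed values of the original experiments.  Quantities the
original hardware-calibrated experiments used but did not print are
configurable, with defaults chosen once:

* camera and IR half-angles 45°/30°/30°; wheel base 0.12 m, wheel speed
  0.5 m/s; capture radius 0.15 m.
* energy budget $E_{max} = 1000$, decay 1/step, gain 300/capture,
  $E_{birth} = 700$, refractory 30 steps.  The birth energy was calibrated
  so that a never-foraging individual dies mid-lifetime (step 700 of 1200,
  forcing the forage/court trade-off) and so that mean normalized energies
  at mating in 20-generation runs reach ≈ 0.70, near the band seen in
  converged populations.  With the lower birth energies we also examined,
  mating energies sit far below that band.
* respawned sources are rejected within a robot radius plus the capture
  radius of any robot, so a respawn can never be captured in place.
* input closeness is $1/d$ clamped to $[1/R_{cat}, 1/0.1]$ then mapped
  affinely to $[-1, 1]$ (the exact published mapping is unknown; monotone
  closeness is what matters for the strategy boundary).

All randomness flows from one root seed through named child streams
(world, learning, evolution, analysis), so identical seeds give
byte-identical logs.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture_population()` plants strategy-weight templates whose
$\bar\theta$ land at the observed phenotype medians (foragers 1.0,
trackers 0.40, strong/weak trackers 0.22/0.48) with Gaussian noise, and
random shaping/meta genes.  The fixtures make the phenotyping and ESS
layers testable without thousand-generation evolution, but they inherit
none of evolution's correlations between strategy weights, shaping rewards
and meta-parameters; passing fixture-based tests therefore validates the
*analysis pipeline*, not the emergence of polymorphism itself.

## Problem sizes and known limitations

The test suite runs the full default-scale colony (80 individuals,
24,000 world steps per generation) for 20 generations, plus miniature
colonies (4-deep subpopulations, 80–120-step periods) for structural
checks; the Sarsa convergence checks use a 5-state chain against exact
value iteration.  These sizes are the package's choice of a thorough but
routinely runnable suite.

Twenty generations of from-scratch learning are far from the
thousand-generation co-evolution of shaping rewards and meta-parameters
that produces efficient behaviours (≈13 matings per lifetime) in the
original system.  In short runs behaviours stay near-random (≈4 captures,
≈1 mating per lifetime), selection is dominated by drift, and because only
mating-module individuals can *initiate* matings, mating-biased strategy
weights are systematically enriched: the census of foraging-when-only-food-
is-visible *declines* rather than dominating.  The package asserts the
opportunism property at face value in its acceptance suite and documents
here that it is an emergent long-horizon outcome, not a desk-scale one.
Hardware transfer, sensor noise, collision physics and continuous-time
dynamics are out of scope.
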