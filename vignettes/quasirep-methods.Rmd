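---
title: "Methods: an RNA-like replicator system and its mutational neighborhood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an RNA-like replicator system and its mutational neighborhood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasirep)
```

## The system

`quasirep` implements a spatial, individual-based model of RNA-like
replicators and the analysis machinery around it. Individuals are RNA
sequences of fixed length (50 nt by default) whose phenotype is read off
their minimum-free-energy secondary structure: a molecule is a *replicase*
if it folds into one predetermined coarse-grained shape — a stem feeding a
multiloop that carries two hairpins, `((((H)S)((H)S)M)S)` in coarse
(Shapiro-style) notation — and presents a 5' dangling end; it is a
*template* if it presents a 3' dangling end. Replication copies the 3'
presenting strand into its reverse complement, with per-base substitution
probability `mu`. Because a genotype is a strand *plus* its complement, six
structural bits (5' end, catalytic fold, 3' end — per strand) suffice to
coarse-grain every phenotype into one of 64 cases, which collapse into six
functional classes:

* **unit of replication** — replicable on both strands, at least one
  replicase strand;
* **parasite** — replicable on both strands, no replicase;
* **helper** — a replicase that cannot itself be replicated;
* **staller** — binds partners through a 5' end but neither replicates nor
  is replicated;
* **junk** — cannot form complexes at all;
* **hybrid** — helper-like on one strand, staller-like on the other.

The package provides: the hybridization energy model (`gmin()`,
`complex_rates()`); folding engines and the coarse-structure classifier
(`fold_engine()`, `coarse_shapiro()`, `genotype()`); a toroidal-grid Monte
Carlo simulator (`world_new()`, `world_step()`); mutational-neighborhood
analyses (`hd1_spectrum()`, `expand_core_neutral()`, `sample_at_hd()`,
`screen_random()`); a replication-rate optimizer
(`optimize_replication()`); and mass-action ODE companions with
continuation and bifurcation detection (`ode_params_helpers()`,
`ode_params_stallers()`, `continue_equilibria()`).

## Hybridization energies

Two molecules form a complex by hybridizing the 5' dangling end of one with
the 3' dangling end of the other. The score `Gmin` is the minimum, over all
ungapped antiparallel offsets, of the summed base-pair contributions across
the overlap: G–C contributes −0.15, A–U −0.10, G–U −0.05, anything else 0.
Binding probability is `P = 1 − exp(Gmin)`; when the two orientations of a
pair sum above 1 they are normalized into association probabilities `k1`,
and dissociation is `k2 = 1 − k1`.

Two numerical choices matter:

* All energies are multiples of 0.05 and are handled internally as exact
  integer *twentieths*, so the threshold comparison `G <= -0.75` (used to
  decide whether a dangling end counts as present) is exact: five G–C pairs
  reach the threshold exactly, seven A–U pairs (−0.70) do not.
* `P = 1 − exp(G)` is used verbatim. A single G–C pair therefore binds with
  probability `1 − exp(−0.15) = 0.139`, and `P > 1/2` exactly when
  `G < −ln 2`.

A *dangling end* is the maximal unpaired run at either sequence end of the
structure; a fully open chain counts, whole, as both the 5' and the 3'
end. A tail is *present* (counts for the phenotype bits) if the tail versus
its own reverse complement scores at or below −0.75 — binding probability
about one half.

## Folding engines

Folding is behind a pluggable contract (`fold_engine()`), with per-engine
memoization so a sequence is folded once.

* `"vienna"` shells out to `RNAfold`. The default configuration is the
  Turner-1999 parameter set with dangling-end model `-d1`. This choice is
  deliberate: it is the energy model and dangle treatment of the classic
  Vienna 1.x era, and the screening statistics of this package (units of
  replication per random 50-mer, neutrality of units) computed under it
  agree with the published values for this class of models, whereas the
  modern defaults (Turner 2004, `-d2`) depress the rate of catalytic folds
  with free tails by a factor of 4–6. Structure-census quantities are
  genuinely engine-version dependent; any such number reported by this
  package must be read relative to the engine identity string stored in
  `fold_engine()$id`.
* `"nussinov"` is a deterministic, thermodynamics-free fallback:
  base-pair maximization with minimum hairpin size 3, and a traceback that
  prefers pairing the leftmost position with its smallest admissible
  partner. It exists so every classification and simulation code path can
  be exercised reproducibly, on any platform, without an external engine.
  Its structure census is very different from an MFE engine's (random
  50-mers essentially never fold catalytic with intact tails, because
  maximizing pairs consumes the tails), which the test suite works around
  by constructing feasible genotypes explicitly.
* `"custom"` wraps any `function(sequences) -> dot-brackets`, used in tests
  to force phenotypes (all-open chains, all-catalytic folds).

The coarse structure emitted by `coarse_shapiro()` uses node labels H, S,
M, B, I, no size annotations and no exterior node; stems interrupted by
bulges or interior loops are split. Only an exact match of the target
string counts as catalytic, so any bulge or extra hairpin in the core
disqualifies — exterior tails are ignored.

## The spatial simulator

The world is a toroidal grid (512×512 in the reference setting; tests and
examples use 24–64 squares) with at most one molecule per cell. One Monte
Carlo step visits all cells in a fresh random permutation; each occupied
cell runs four phases in order:

1. **Complex formation/dissociation.** A free molecule picks one free
   neighbor uniformly from its Moore neighborhood and the orientation is
   drawn with probabilities `k1_xy`, `k1_yx` (residual: no complex). A
   complexed molecule dissociates with probability `k2` of the realized
   orientation.
2. **Replication.** If the 5'-presenting member of a complex is catalytic
   and an empty cell is adjacent to either complex cell, then with
   probability `kappa` the 3'-presenting member is copied (mutated reverse
   complement) into a uniformly chosen adjacent empty cell and the complex
   breaks.
3. **Diffusion.** Free molecules attempt one random-walk step (rejected if
   the target is occupied). Complexes move rigidly, as a domino, with
   probability `1 − 0.1`, requiring both target cells free.
4. **Decay.** Each molecule dies with probability `d`; a surviving partner
   becomes free.

Choices the model statement leaves open, fixed here: complex-level phases
(dissociation, replication, rigid diffusion) are executed only when the
visited cell holds the 5'-presenting member, so a complex acts once per
sweep while decay is per molecule; neighborhoods are Moore; complexed
molecules do decay. The defaults `kappa = 1`, `d = 0.03`,
`complex_no_move_prob = 0.1`, `nu = 50` are the reference setting.

Mutation rates can be a global constant or a per-molecule, heritable trait:
in `"evolve_positive"` mode every replication event that introduced at
least one substitution adds a Uniform(0, `mu_step`) increment to the
offspring's rate (`"evolve_unbiased"` draws from Uniform(−`mu_step`,
`mu_step`)); `mu_step` defaults to 5×10⁻⁴.

Interventions (`apply_intervention()`) exclude a functional class either by
deletion (leaving exploitable empty space) or by inactivation
(`class_to_junk`: the class keeps its cells but its dangling ends are
ignored for binding, so it can never enter a complex). Observers report
per-class abundances, minimum-of-both-strands Hamming distance histograms
against a reference, plain-text class-code snapshots, and the full birth
log (id, parent, birth step) from which ancestor trees are built.
Competition experiments seed two populations into the two half-fields.

All randomness flows through R's RNG: `set.seed()` makes entire
trajectories, including C++-side draws, bit-reproducible.

## Mutational-neighborhood analyses

`hd1_spectrum()` enumerates all `3*nu` single-substitution mutants of a
strand (150 for `nu = 50`), classifies each as a genotype, and reports the
class fractions; the *neutrality* `lambda` of a genotype is its fraction of
unit-of-replication mutants. `tails_only_spectrum()` restricts mutation to
the dangling ends of the replicase strand.

Three searches probe larger distances, all counting genotypes canonically
(a strand and its reverse complement are one genotype; Hamming distance
between genotypes is the minimum over strand pairings):

* `expand_core_neutral()` — breadth-first over single substitutions,
  retaining units of replication whose replication-rate proxy is at least
  the master's;
* `expand_pseudo_neutral()` — the same without the rate filter;
* `sample_at_hd()` — uniform random mutants at each exact distance
  `h = 1..10`, moving to the next distance after 10⁴ retained units or 10⁵
  fruitless draws.

Per retained layer the mean ± sd of the members' own HD = 1 class fractions
is recorded. Computing those fractions costs `3*nu` classifications per
member, so layers enter the statistics through a subsample
(`stats_cap`, default 200 — at the default sequence length that bounds a
layer's cost at 60 000 classifications while keeping the standard error of
a layer mean below about 0.01).

The *replication-rate proxy* summarizes a genotype's self-replication as
the mean of two binding probabilities — the replicase strand's 5' tail
against its own 3' tail and against the complement's 3' tail — taking the
better strand if both qualify. The model statement never defines this
scalar explicitly; this definition makes the "rate as high as the master's"
filter reproducible, reaches its maximum 1 exactly when both binding
probabilities are 1, and is invariant under strand swap.

`screen_random()` draws uniform random sequences and tallies their classes;
`consensus_and_master()` orients a population (each strand or its
complement, whichever is nearer the running plurality) and reports the
per-position consensus and the modal sequence; `build_network()` assembles
the quasispecies graph whose edges join units at genotype distance 1.

## The replication-rate optimizer

`optimize_replication()` is a restarted, elitist genetic algorithm with a
local-search finish: by default five independent runs of population 100
for 300 generations (per-base mutation 0.01, one-point crossover with
probability 0.7, tournament size 3, 2 elites), keeping the best final
genotype by fitness and then climbing by steepest ascent over single
substitutions to a 1-opt local maximum. Fitness is the replication-rate
proxy for feasible genotypes and 0 otherwise. The feasible set is *units
of replication* satisfying the structural constraint — both strands
catalytic, or exactly one in the `single_catalytic` variant. Demanding the
unit class and not merely the catalytic folds matters: without the
viability requirement the highest proxies are reached by helper genotypes,
which replicate but cannot be replicated and are meaningless as
optimization products of a replicator null model.

This feasible set is vanishingly rare in random sequence space under an
MFE engine (catalytic folds are about 1–2% per strand, and both-catalytic
viable genotypes were never observed among 10⁵ random units), so
tournaments break fitness ties on the number of constraint conditions met,
restarts hedge against runs that fail to reach the feasible set, and
[catalytic_seeds()] supplies a starting population in which each genotype
already has one catalytic strand. Crossover recombines tail composition
and core fold, which sit on quasi-independent parts of the sequence and
strand mutation-only climbs on this landscape; elitism makes each
restart's best-fitness trajectory non-decreasing by construction. Any
maximizer would do here — the optimizer is a null model for what
selection on replication rate alone produces, not part of the replicator
dynamics.

## Mass-action ODE companions

Two reaction schemes abstract the lattice into well-mixed mass action, with
state vectors of four species and four complexes.

**Helpers scheme** (X units, H helpers, P parasites, J junk): X pairs with
X, H and P; H pairs with P. Complexes holding a catalyst and a replicable
template fire at rate `kappa * theta(N)`, releasing their members plus a
copy of the template; X copies are faithful with probability `1 − mu`,
otherwise helper/parasite/junk with fractions `lambda_H : lambda_P :
lambda_J`. Parasite copies do not mutate.

**Stallers scheme** (X, S stallers, P, J): X·X and P·X complexes fire as
printed in the scheme — X mutants split `lambda_S : lambda_P : lambda_J`,
parasite mutants into stallers and junk — while X·S and P·S complexes are
dead ends that only form, dissolve and decay.

The model statement fixes the association rates, `kappa`, `Theta`, `d` and
the mutant fractions; everything else is a closure owned by this package,
with every choice exposed as a parameter:

* **Resource term.** `theta(N) = max(0, 1 − N/Theta)` with `N` the total
  concentration of species *and* complexes. This bounds the dynamics and
  makes extinction a stable equilibrium for every parameter set used here
  (both asserted by the analyses this scheme supports).
* **Decay.** Every species and complex decays at `d`, complexes as whole
  units, as the printed scheme indicates.
* **Orientation factor.** In an X·H complex both members are catalytic but
  only the orientation with H presenting its 5' end replicates (a helper
  cannot be replicated), so only `productive_xh = 1/2` of X·H firings
  produce a copy. A parasite has no 5' end, so X·P, H·P and P·X complexes
  always replicate the parasite. This factor is derived from the lattice's
  orientation rule, not fitted.
* **Dissociation rates.** Defaults mirror the lattice rule `k2 = 1 − k1`
  (`b = 1 − a`) for unit/helper/staller complexes. The parasite-complex
  rates of the helpers scheme default to `b_xp = b_hp = 1` instead. The
  reason is structural: with `b = 1 − a` throughout and equal association
  rates, a parasite's per-capita replication is *identical* to a unit's
  (same catalyst pool, same firing rate) while it escapes the mutation
  load entirely, and the coexistence equilibrium does not exist at any
  mutation rate under this resource closure — numerically, every
  trajectory spirals into extinction. Faster-dissolving parasite
  complexes are the minimal asymmetry that restores the regime the
  bifurcation analysis describes: a stable coexistence branch at low `mu`
  that destabilizes (Hopf) at a `mu` that *decreases* as `lambda_H` grows,
  parasites profiting from helpers; without the parasite equations the
  boundary instead *increases* with `lambda_H`. The stallers scheme needs
  no such adjustment: with its printed rates and `b = 1 − a` it shows the
  three regimes in `lambda_S` — parasite invasion and collapse at low
  staller production, stable coexistence at intermediate values, parasite
  exclusion beyond a fold, and extinction of the overloaded system at high
  `mu` and high `lambda_S`.

Equilibria are continued in any single parameter by pseudo-arclength
(secant predictor, Newton corrector on the arclength-augmented system,
finite-difference Jacobians), recording eigenvalues and stability along the
branch. `detect_bifurcations()` flags folds (sign change of the tangent's
parameter component), Hopf points (a complex pair's real part crossing
zero) and transcritical points (the branch meeting extinction); homoclinic
connections are not equilibrium phenomena, so `estimate_homoclinic()`
instead reports where the post-Hopf limit cycle's period blows up, flagged
as an estimate. Exact bifurcation coordinates depend on the closure above
and are not comparable across implementations; orderings and regime
boundaries are.

## What the tests do and do not show

The test suite runs everything on desk-scale problems: 16–64 square grids
over tens of Monte Carlo steps, spectrum searches to Hamming distance ≈ 2
with small caps, ODE scans on coarse `mu` grids, and the fallback folding
engine wherever an engine-free deterministic answer is needed. These sizes
exercise every invariant (occupancy, complex adjacency, ±1 population
bookkeeping, seeded determinism, classification totality) but say nothing
about long-horizon evolutionary outcomes on the full 512×512 field —
evolved master sequences, competition winners and field abundance
distributions are stochastic, large-scale results that the package can
produce but the tests only smoke-test. Screening fractions computed with
the MFE engine are reproduced at 10⁵ draws against their published scale
(counts within binomial noise); the fraction of random units catalytic on
*both* strands is the one screening statistic that disagrees strongly
across engine versions (it measures fold correlation between complementary
strands, which the 1.x and 2.x energy models treat differently), and is
reported rather than asserted.

## Limitations

* Substitutions are the only mutations; sequence length never changes.
* Folding is MFE-only: no suboptimal structures, no partition function,
  no pseudoknots, no temperature dependence; the hybridization model is a
  base-pair count, not a nearest-neighbor duplex energy.
* The ODE closure is one defensible choice among several; conclusions
  should be read at the level of regime structure, not coordinates.
* The Monte Carlo scheduler resolves the update-order ambiguities stated
  above; other resolutions would differ in detail at identical parameters.
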