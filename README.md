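# quasirep

Spatial eco-evolutionary dynamics of RNA-like replicators near the error
threshold, in R.

## What this is for

In quasispecies theory, high per-base mutation rates limit how much
information a genome can maintain: beyond an error threshold, selection can
no longer hold a master sequence against its mutant cloud. `quasirep`
implements a model system for studying how *interacting* replicators evade
that limit. Individuals are 50-nt RNA-like sequences on a toroidal lattice;
their phenotype is read from their minimum-free-energy secondary structure.
A molecule can replicate a neighbor when it folds into a fixed coarse
catalytic shape (`((((H)S)((H)S)M)S)` — a stem feeding a multiloop with two
hairpins) and the two molecules hybridize 5'-tail-to-3'-tail with
probability `P = 1 − exp(Gmin)`, where `Gmin` is an ungapped
sliding-alignment score (G–C −0.15, A–U −0.10, G–U −0.05). Since a genotype
is a strand plus its reverse complement, six structural bits classify all
64 coarse phenotypes into six functional classes: units of replication,
parasites, helpers, stallers, junk and hybrids.

The package provides, as one toolkit:

* the hybridization energy model and complex formation/dissociation
  probabilities (`gmin()`, `binding_probability()`, `complex_rates()`);
* folding engines (`RNAfold`-backed or a deterministic engine-free
  fallback) and the coarse-structure phenotype map (`fold_engine()`,
  `coarse_shapiro()`, `genotype()`, `classify()`);
* a Monte Carlo lattice simulator with complex formation, replication with
  mutation, diffusion, decay, evolvable mutation rates, class-knockout
  interventions, competition seeding and observers (`world_new()`,
  `world_run()`, `apply_intervention()`, `hd_histogram()`);
* mutational-neighborhood analysis: HD = 1 spectra and neutrality,
  tails-only spectra, core-/pseudo-neutral network expansion, fixed-distance
  sampling, random-sequence screening, consensus/master detection and the
  quasispecies network (`hd1_spectrum()`, `expand_core_neutral()`,
  `sample_at_hd()`, `screen_random()`, `build_network()`);
* an evolutionary optimizer for replication rate (`optimize_replication()`);
* mass-action ODE companions for the unit–helper–parasite and
  unit–staller–parasite systems, with equilibrium continuation and
  bifurcation detection (`ode_params_helpers()`, `ode_params_stallers()`,
  `continue_equilibria()`, `detect_bifurcations()`).

The methods vignette (`vignettes/quasirep-methods.Rmd`) documents the model
conventions, the numerical choices, and the degrees of freedom in the ODE
closure.

## Worked example

Classify a replicator, then ask how its mutational neighborhood is
composed:

```r
library(quasirep)
eng <- fold_engine("vienna")   # RNAfold, Turner-1999 parameters, dangles 1

s <- "AAAACGUGUAAAGGAGCGAAUCGCAGGCAGAGCCACCAUAAAAGUUAUUA"
genotype(s, eng)
#> Genotype: unit
#>   + AAAACGUGUAAAGGAGCGAAUCGCAGGCAGAGCCACCAUAAAAGUUAUUA  [5' 1  cat 1  3' 1]
#>   - UAAUAACUUUUAUGGUGGCUCUGCCUGCGAUUCGCUCCUUUACACGUUUU  [5' 1  cat 1  3' 1]

replication_rate_proxy(s, eng)
#> [1] 0.6341966

sp <- hd1_spectrum(s, eng)
sp$lambdas
#> lambda_neutral       lambda_P       lambda_H       lambda_S       lambda_J
#>     0.43333333     0.12000000     0.12666667     0.18666667     0.08000000
#>  lambda_hybrid
#>     0.05333333
```

Both strands of this genotype fold into the catalytic structure and carry
usable dangling ends, so it is a unit of replication; its replication-rate
proxy (mean probability of binding its own strand and its complement) is
0.63. Of its 150 single-substitution mutants, 43% remain units of
replication (its neutrality λ), 12% become parasites, 13% helpers — the
remainder stallers, junk and hybrids. A spatial run is just as short:

```r
set.seed(1)
w <- world_new(sim_params(width = 64, height = 64, mu = 0.015), eng)
world_seed(w, c(s, reverse_complement(s)), n = 600)
obs <- world_run(w, steps = 200, sample_every = 50)
tail(obs$abundance, 2)
#>   unit parasite helper staller junk hybrid complexed total step
#> 4  706     1239    204    1072  521     41      2262  3783  150
#> 5  501     1266    154    1036  485     65      2030  3507  200
```

At `mu = 0.015` (probability 0.53 of at least one substitution per
replication) the mutant cloud dominates the standing population: most
molecules in the field are nonviable mutants — helpers, stallers, junk —
of the seeded unit of replication, which is the regime this system is
built to study.

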