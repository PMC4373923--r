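# tcellsim

Twin simulators — one deterministic, one stochastic — of the age-related
depletion of the naive T-cell repertoire, built from the same
three-compartment model, plus the statistical machinery to ask whether
the two simulation paradigms can be used interchangeably.

## The problem

Immunosenescence is driven in part by the loss of naive T cells: the
thymus involutes with a half-life of about 15.7 years, and the
peripheral mechanisms that partly compensate (division of existing
naive cells, reversion of memory cells to a naive phenotype) copy
existing receptor specificities instead of creating new ones.  The
model tracks, per mm³ of peripheral blood, thymic-origin naive cells
`N`, proliferation-origin naive cells `Np` and memory cells `M`, driven
by an external activated-CD4⁺ count `A(t)`:

    dN/dt  = s0·e^(−λt·t)·s(Np) − [λn + μn·g(Np)]·N
    dNp/dt = λn·N + [c·h(N,Np) − μNp]·Np + λmn·M
    dM/dt  = λa·A(t) − μm·M − λmn·M

with homeostatic modifiers s(Np) = 1/(1 + s̄·Np/N̄p),
g(Np) = (1 + b·Np/N̄p)/(1 + Np/N̄p) and h(N,Np) = 1/(1 + (N+Np)/N̄p).
Five scenarios (`scenario_parameters(1:5)`) switch the individual
homeostatic mechanisms on and off.

The package runs this model both as a **stock-and-flow ODE simulation**
(`simulate_sd`, fixed-step RK4) and as a **stochastic agent-based
simulation** (`simulate_abm_ensemble`, one agent = one cell/mm³,
rate-driven state transitions, 50 seeded replicates), then compares the
two paradigms' yearly trajectories with two-sided Wilcoxon rank-sum
tests (`compare_trajectories`) and validates the thymic-naive curve
against bundled TREC (T-cell receptor excision circle) tables
(`trec_goodness_of_fit`, `load_trec_table`).

## Worked example

```r
library(tcellsim)

actives <- synthetic_active_table()          # activated-CD4+ lookup, A(t)
sd  <- simulate_sd(2, actives)               # deterministic arm
ens <- simulate_abm_ensemble(2, actives,     # stochastic arm, 50 runs
                             abm_config(seed = 2000))
compare_trajectories(sd, ens$mean)
```

```
SD vs ABM comparison, scenario 2 (rank-sum, level 0.05)
  N            p = 0.8975
  Np           p = 0.8652
  M            p = 0.9856
  total_naive  p = 0.8899
  verdict: similar (headline total-naive p = 0.8899)
```

Every p-value is far above 0.05: over a 100-year life course starting
from 3673 naive cells/mm³, the mean of 50 agent-based replicates is
statistically indistinguishable from the deterministic trajectory for
every population — the two paradigms tell the same story, and the
deterministic arm is the cheaper way to tell it.  The full study over
all five scenarios, with per-scenario CSV/JSON artifacts and a summary
table, is one call:

```r
study <- run_comparison_study(study_options(seed = 1, out_dir = "out"))
study$summary
```

A thin command-line wrapper with `simulate` / `compare` / `study`
subcommands lives at `inst/cli/tcellsim.R`.

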