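# detoursim

Spiking-network simulation of behavior selection in the inward
semitransparent-V detour task.

## The problem

In the detour paradigm of comparative psychology, an animal faces a
V-shaped barrier with a visible reward behind it. The barrier's vertical
stripes alternate between opaque and see-through, so the reward is in
plain sight while the direct path is blocked; getting the reward requires
suppressing the direct approach and walking around an arm of the V. The
time the subject spends in the *barrier zone* directly in front of the
barrier measures its inhibitory control.

`detoursim` is for computational neuroscientists and comparative-cognition
researchers who want to explore how two neural factors shape this
behavior: the strength **w ∈ [0, 1]** of a single inhibitory connection
carrying obstacle evidence into the direct-approach channel, and the size
**N** of the spiking populations carrying each signal. The package
simulates whole trials in a closed 10 Hz loop and sweeps the (w, N) grid,
measuring barrier-zone time per trial.

## The model

Each of four populations (barrier, reward-proximity, and one per
strategy) consists of N regular-spiking Izhikevich units

```
dv/dt = 0.04 v² + 5v + 140 − u + I        v ← c,  u ← u + d   when v = 30 mV
du/dt = a (b v − u)
```

with a = 0.02, b = 0.2, c = −65 + 15γ², d = 8 − 6γ², γ ~ U[0, 1] redrawn
per unit at every trial reset. The egocentric (direct approach)
population receives `gain · (reward_drive − w · barrier_drive)`; the
allocentric (map) population receives `gain · barrier_drive`. Each
strategy population's normalized spike-count drive feeds a leaky
integrator (ω = 0.024, ε = 0.1, λ = 0.9, τ = 1), and the behavioral
choice each world step is the argmax of the two integrator values.

The egocentric policy homes on the centroid of pure-red camera rays; the
allocentric policy follows the gradient of a breadth-first wavefront
distance map from the goal over the rasterized arena, which is what makes
detours possible. A trial ends on reaching the goal (within 5 world
units) or after 1,200 steps (120 s).

See the methods vignette (`vignettes/detour-model.Rmd`) for the full
model description, parameter table and design rationale.

## Worked example

```r
library(detoursim)

arena <- default_arena()
trial <- run_trial(arena, network_config(n = 10, w = 0.6), seed = 7)
trial
#> <trial_result> n=10 w=0.60 goal reached in 109 steps, 4.6 s in barrier zone

sw <- sweep_config(inhibition_levels = c(0, 0.5, 1),
                   population_sizes = c(1, 10),
                   trials_per_cell = 5, master_seed = 42)
trials  <- run_sweep(sw)
summary <- summarize_trials(trials)
#> Warning: 1 timed-out trial(s) excluded from summary statistics
print(summary, digits = 3)
#>   pop_size inhibition  mean    sd median  iqr min  max n_trials
#> 1        1        0.0 12.00 9.453   8.75 10.2 5.2 25.3        4
#> 2        1        0.5  5.36 1.159   5.00  0.1 4.5  7.4        5
#> 3        1        1.0  4.82 0.205   4.80  0.2 4.5  5.0        5
#> 4       10        0.0  5.30 0.245   5.40  0.3 5.0  5.6        5
#> 5       10        0.5  4.96 0.152   5.00  0.0 4.7  5.1        5
#> 6       10        1.0  5.18 0.973   4.70  0.3 4.6  6.9        5

trend_report(summary)
#> <trend_report>
#>  adjacent median increases over inhibition, per population size:
#>  pop_size inversions
#>         1          0
#>        10          0
#>  Pearson r (cell mean vs SD): 0.996
```

Reading the output: each row is one (population size, inhibition) cell of
the sweep. Median barrier time falls as inhibition rises (8.75 → 4.80 s
for single-unit populations), and the spread collapses as the population
grows (SD 9.45 at N = 1, w = 0 versus 0.25 at N = 10, w = 0): stronger
inhibition shortens perseverance at the barrier, larger populations make
it consistent. The one excluded trial timed out at zero inhibition with
single-unit populations — the regime with the weakest impulse control.
The trend report counts adjacent median increases over the inhibition
levels (0 = monotone decreasing) and correlates per-cell mean with SD.

`plot_barrier_times(trials)` draws the log-median barrier time per
inhibition level with bootstrap CIs, faceted by population size;
`plot_mean_sd(compare_animals(summary, "animals.csv"))` overlays
user-supplied animal summary statistics (`species, mean_s, sd_s`) on the
simulation's mean-vs-SD scatter. A synthetic example CSV ships in
`inst/extdata/animals_synthetic.csv`.

A thin command-line front end is included:

```sh
Rscript inst/cli/detoursim.R run --levels 0,0.5,1 --sizes 1,10 \
        --trials 5 --seed 42 --out trials.csv
Rscript inst/cli/detoursim.R summarize trials.csv --out summary.csv
Rscript inst/cli/detoursim.R report summary.csv --plots figs/
```

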