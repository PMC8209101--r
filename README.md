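# tatbatch

Choosing how long a clinical laboratory should wait before loading
accumulated samples into an analyzer.

## The problem

Technologists in a hospital chemistry laboratory interleave several task
types — receiving samples, pre-treating them, loading analyzers, verifying
results — and every change of task type costs attention and time. Handling
each emergency-room (ER) sample the moment it arrives produces heavily
alternating task sequences (P–A–PP–AA–P–A: five switches) where a blocked
schedule (PPPP–AAAA: one switch) would do the same work. Waiting lets
arrivals accumulate into a single analyzer-loading task, but ER samples
carry a turnaround-time (TAT) guideline — 60 minutes or less from arrival
(`x`, "Receipt 1") through analyzer loading (`y`, "Receipt 2") to the
reported result (`z`) — so waiting too long trades switches for late
reports.

`tatbatch` resolves the trade-off. For a waiting interval *M*, samples are
batched greedily: the earliest unassigned sample *k* anchors a batch with
deadline *x<sub>k</sub> + M*, every later sample with original
*y<sub>i</sub> ≤ x<sub>k</sub> + M* joins it, batch members are loaded
together at the deadline (*y′ = x<sub>k</sub> + M*), and reports shift with
the analytical phase unchanged (*z′ = y′ + (z − y)*). Sweeping *M* over a
grid (default 0–60 min) yields, per *M*, the task count *l<sub>M</sub>*
(number of batches) and the TAT satisfaction rate *r<sub>M</sub>* (fraction
with *z′ − x* ≤ 60). Both are min-max normalized to *f₂* and
*f₁ = 1 − r<sub>M</sub>* respectively, and the optimal interval is

> M₀ = argmin<sub>M</sub> [ w<sub>tat</sub>·f₁(M) + w<sub>switch</sub>·f₂(M) ],  w<sub>tat</sub> + w<sub>switch</sub> = 1,

with ties broken toward the smallest *M*. The package also counts task
switches in labeled task sequences, labels duty/staffing shifts, generates
seeded synthetic ER event logs (hospital logs are confidential), and
produces evaluation reports: compliance-stratified phase summaries, boxplot
statistics, per-duty switching tables, and batch-deadline alert schedules
for a monitoring system.

## Worked example

```r
library(tatbatch)

log <- generate_event_log(generator_config(horizon_days = 7), seed = 42)
log
#> <event_log> 1349 samples, TAT limit 60 min
#>    sample_id        x         y         z
#> 1    S000001  8.11383  55.46150  65.54963
#> 2    S000002  8.17775  33.50629  52.64668
#> ...

recommend_interval(log)
#> <interval_recommendation>
#>   w_tat = 0.60, w_switch = 0.40  ->  M0 = 34 min
#>   w_tat = 0.50, w_switch = 0.50  ->  M0 = 34 min
#>   w_tat = 0.40, w_switch = 0.60  ->  M0 = 39 min
#>   recommended interval spans [34, 39] min

phase_summary(log)
#> <phase_summary> TAT limit 60 min
#>       stratum              n pre_analytical analytical_post   overall_tat
#>       overall 1349 (100.00%)   20.43 ± 8.64    16.62 ± 8.80 37.05 ± 11.95
#>  within_limit  1290 (95.63%)   19.88 ± 8.01    15.82 ± 7.83 35.70 ± 10.29
#>   after_limit     59 (4.37%)  32.54 ± 12.37   34.01 ± 10.76  66.55 ± 6.39
```

Reading the output: on this simulated week of 1,349 ER samples, putting
more weight on technician workload (w_switch = 0.6) stretches the
recommended waiting interval from 34 to 39 minutes; 4.37% of raw samples
miss the 60-minute guideline, and the phase summary gives mean ± SD minutes
for the pre-analytical and analytical + post-analytical phases per
compliance stratum. `plot_tradeoff()` and `plot_objective()` draw the
normalized trade-off and the scalarized objective curves; `count_switches()`
/ `switches_per_100()` quantify switching in observed task sequences;
`monitor_alerts()` turns a batched log into the alert schedule a monitoring
system would fire.

A command-line wrapper covers the same pipeline:

```sh
Rscript inst/scripts/tatbatch.R simulate --seed 7 --horizon-days 7 --out out/
Rscript inst/scripts/tatbatch.R optimize --input out/event_log.csv --out out/
Rscript inst/scripts/tatbatch.R report   --input out/event_log.csv --out out/
```

See `vignettes/batch-interval-optimization.Rmd` for the model's
assumptions, parameter choices, and known limitations.

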