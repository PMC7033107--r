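# coordrqa

Attractor stability of movement coordination patterns via recurrence
quantification analysis.

## What it is for

In redundant rhythmic tasks — the running example is metronome-paced
three-ball cascade juggling — different people settle into different
coordination patterns, from *rhythmic* (smooth, oscillator-like hand
motion) to *discrete* (move, then dwell while waiting for the next
event). `coordrqa` is for movement scientists who want to quantify, from
3D marker trajectories and event times:

* **where a pattern sits on that continuum** — the Coordination Pattern
  Index (CPI), the proportion of vertical hand-velocity spectral power in
  a band of total width 10% around the fundamental movement frequency
  f₀: CPI = Σ P(f), f ∈ [0.95 f₀, 1.05 f₀], divided by the total non-DC
  power (1 for a pure sinusoid, → 0 as power spreads into harmonics);
* **how stable its attractor is** — delay-embed the standardized signal
  (τ = 25 frames, m = 6), threshold pairwise distances at 15% of the
  maximum with a 10-frame Theiler band, and read off
  %REC (recurrence rate), %DET (share of recurrent points on diagonal
  lines ≥ 10), and %MAXLINE (longest line / longest achievable);
* **how well the mover adapts** to tempo ramps — %Asynchrony, the
  absolute catch-to-beep error scaled by the local inter-beep interval,
  averaged over the 95 analyzed catches of a 101-beep ramp;
* **how these covary** across a cohort — Pearson/Spearman correlations
  with a Shapiro–Wilk gate, per-participant Fisher-z summaries, and
  Bonferroni-corrected levels.

A synthetic-kinematics generator with a single "dwell fraction" knob
spans the rhythmic-to-discrete continuum, so the entire chain runs and is
tested end to end without any motion-capture data.

## Worked example

```r
library(coordrqa)

co <- simulate_cohort(n_participants = 10, seed = 1, n_trials = 3)
s  <- cohort_summary(co, analysis_params(channels = "SI"))
round(s[, c("dwell_fraction", "cpi", "det_SI")], 3)
#>    dwell_fraction   cpi det_SI
#> 1           0.000 0.964 99.351
#> 2           0.067 0.595 76.547
#> 4           0.200 0.362 88.721
#> 7           0.400 0.134 61.450
#> 10          0.600 0.023 22.931   # (rows abridged)

correlation_test(s$cpi, s$det_SI, "spearman")   # r = 0.84, p = 0.0045
correlation_test(s$cpi, s$asyn_up, "pearson")   # r = 0.95, p = 3.5e-05
```

Read: as patterns become more discrete (dwell fraction up), the CPI falls
from 0.96 to 0.02; determinism (%DET of the vertical wrist channel) falls
from ~99 to ~23; and the positive CPI–%Asynchrony correlation says the
rhythmic movers mistime the ramped metronome more — the stability and
adaptability signature the package is built to measure. The experiment
drivers reproduce the two full designs:

```r
e1 <- run_experiment1(seed = 1)  # 7 experts x 10 tempos (260-620 ms)
e1$cpi_tempo$r                   # negative: slower tempo -> more discrete
e2 <- run_experiment2(seed = 1)  # 10 intermediates: free tempo + ramps
e2$cpi_asyn                      # CPI vs %Asynchrony, Up and Down
```

A thin CLI over the same functions lives in `exec/coordrqa`
(`simulate`, `exp1`, `exp2`, `rqa`, `cpi`).

## Documentation

The methods vignette (`vignettes/attractor-stability.Rmd`) describes the
measurement chain, every tunable parameter with units and defaults, the
generator's design and its limits, and the numerical edge cases.
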