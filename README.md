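# spikegc

Directed functional-connectivity analysis of multi-neuron spike recordings,
with a non-negative low-rank embedding of the population and conditional
Granger causality on sliding windows.

## What it is for

Systems-neuroscience experiments that record tens of neurons simultaneously
while an animal performs a task (e.g. a spatial working-memory maze) often
ask how the *interactions* among neurons — not just their firing rates —
evolve around a behavioural event. spikegc implements that analysis as a
reproducible pipeline:

1. **Rate reconstruction** — each spike train becomes a continuous
   instantaneous firing-rate series: the reciprocal-ISI rate
   `r(t) = 1/(t_{i+1} − t_i)` is averaged over a short horizon
   `δT = δ · mean(ISI)` (δ = 0.25) and evaluated in closed form on a uniform
   grid.
2. **Non-negative embedding** — each trial's neurons × samples matrix is
   factorised as `X ≈ WH` (`W, H ≥ 0`, multiplicative updates); the rank is
   the smallest `r` with variance accounted for
   `VAF = 1 − ‖X − WH‖²_F / ‖X‖²_F > 0.9`, subject to `r < mn/(m+n)`, and is
   harmonised to the per-animal maximum across trials.
3. **Network construction** — a 0.5-s window (step 0.125 s) slides over each
   trial; within a window a VAR(p) (p by BIC) is fitted and the causality
   from series j to i conditioned on all others is
   `F_{j→i} = ln(ρ_ii / Σ_ii)`; per-edge F-tests with Benjamini–Hochberg
   correction zero the non-significant connections. The same procedure runs
   in neuron space and in component space.
4. **Network properties** — causal density `Cd = N_sig / N(N−1)` and global
   efficiency `E = mean over ordered pairs of 1/L_ij` (edge length = 1/F)
   form RT-aligned time courses; peak-window means are compared between
   trial groups (correct / error / baseline) with Welch's t-test.

A point-process simulator with known ground-truth latent coupling (shared
non-negative assembly components whose directed coupling ramps up shortly
before the reference time in correct trials) makes every stage testable
without any recorded data.

## Worked example

```r
library(spikegc)

cfg <- sim_config(n_neurons = 12, n_components = 3,
                  n_correct = 8, n_error = 8, n_baseline = 8, seed = 42)
ds  <- build_dataset(cfg)
ds
#> <spike_dataset> 24 trials (baseline: 8, correct: 8, error: 8), 12 neurons

res <- run_pipeline(pipeline_config(seed = 42, n_restarts = 5), dataset = ds)
res
#> <pipeline_result>
#>   trials: 24 (baseline: 8, correct: 8, error: 8)
#>   NMF animal rank: 8 (mean VAF 0.980)
#>   cd_correct_vs_baseline: t = 1.48, p = 0.17 (a>b)
#>   cd_error_vs_baseline: t = 1.23, p = 0.241 (a>b)
#>   eff_correct_vs_baseline: t = 1.61, p = 0.13 (a>b)
#>   eff_error_vs_baseline: t = 0.86, p = 0.404 (a>b)
#>   weight_nmf_vs_original: t = -4.37, p = 0.00314 (b>a)
```

Reading the output: the embedding needed 8 components to keep every trial's
VAF above 0.9 (mean 0.98). Peak-window causal density and efficiency in
correct trials sit above baseline (direction `a>b`) without reaching
significance at this small trial count, error trials show no excess, and at
n = 8 trials the mean surviving-edge weight comparison between spaces is
still unstable. `res$group_mean` holds the group-mean metric time courses
(`plot_metric_timecourse()` draws them with an SEM band), `res$trial_table`
the per-trial peak summaries, and passing `out_dir` to `pipeline_config()`
writes every artifact as TSV/JSON with a hashed manifest.

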