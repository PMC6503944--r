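# rtdetrend

Causal detrending for real-time fMRI time series, plus the simulation
test-bed to benchmark it.

In real-time fMRI (neurofeedback, brain–computer interfaces, online quality
assurance) the signal of a volume of interest (VOI) must be cleaned *as it
streams in*: scanner instabilities and slow head motion produce
low-frequency drifts, and only samples up to the current TR are available.
`rtdetrend` implements the standard causal detrenders used by real-time
pipelines, the offline references they are compared against, and a fully
seeded synthetic benchmark for choosing their free parameters:

**Online (streaming) detrenders** — each exposes a `*_state()` constructor,
a one-sample `*_update()` and a batch runner via `detrend()`:

- **EMA** — exponential moving average high-pass: `m_1 = x_1`,
  `m_t = α m_{t−1} + (1−α) x_t`, output `d_t = x_t − m_t`. One free
  parameter α ∈ (0,1]: close to 1 → slow convergence to trends but little
  signal distortion; smaller → fast convergence, more distortion.
- **iGLM** — incremental general linear model: the normal equations
  `X'X`, `X'y` of an OLS fit are accumulated sample by sample, so the
  coefficient estimate at sample *t* equals the batch fit on samples 1..*t*.
  Design matrix: constant, task regressor, linear drift, and 7 discrete
  cosine high-pass terms (p = 10). Output = sample minus fitted nuisance
  (everything except the task column).
- **iGLM^window** — the same fit restricted to the most recent *n* samples
  (add/downdate of the accumulators, with periodic exact recomputation).
  Free parameter: the window length *n* ≥ p.

**Offline references**: piecewise straight-line removal (`line_detrend`)
and discrete-cosine-basis high-pass regression (`cosine_detrend`, order
*k* ↔ cutoff period `2·N·TR/k`).

**Simulator and benchmark**: block-design BOLD signals (boxcar convolved
with the canonical double-gamma HRF, peak normalized to 1) degraded by six
artifact models — Gaussian noise at exact SNR (dB), linear drift,
low-frequency non-linear drift, AR(1) colored noise, spikes, and stepped
baseline shifts — with exact seeded reproducibility
(`generate_suite()`), scored by Pearson correlation between the detrended
output and the clean signal (`run_benchmark()`), and optimized by
exhaustive grid search (`grid_search()`).

## Worked example

```r
library(rtdetrend)

# a 10-TR regulation / 10-TR baseline design, 15 repetitions, TR = 2 s
design <- block_design(n_reg = 10, n_bl = 10, n_blocks = 15)
clean  <- make_clean_signal(design)        # boxcar * canonical HRF, peak = 1

# add a scanner drift of 0.3 signal units per TR
drifted <- add_linear_drift(clean, slope = 0.3)

ema  <- detrend(drifted, "ema",  alpha = 0.995)
iglm <- detrend(drifted, "iglm", design = design)
wind <- detrend(drifted, "iglm_window", design = design, window = 30)

# correlation with the clean signal over the post-warm-up samples
round(c(raw  = pearson_corr(drifted, clean, skip = 14),
        ema  = pearson_corr(ema$detrended,  clean, skip = 14),
        iglm = pearson_corr(iglm$detrended, clean, skip = 14),
        iglm_window = pearson_corr(wind$detrended, clean, skip = 14)), 3)
#>         raw         ema        iglm iglm_window
#>       0.011       0.020       1.000       1.000
```

The drift destroys the raw correlation with the underlying response
(r = 0.011). The EMA, whose time constant at α = 0.995 is ~200 samples,
cannot converge to a drift this steep within the run (r = 0.020), while
both GLM variants carry a linear term in their design matrix and remove the
drift exactly once past their 14-sample warm-up (r = 1.000). `skip = 14`
excludes the warm-up samples, during which the streaming GLMs output the
running-mean-subtracted signal and flag `warmup`.

GLM β and t statistics for a paradigm + constant fit (the usual validation
on recorded VOI time courses) are available via `glm_stats(series,
paradigm)`; VOI tables are read and written as plain TSV with
`read_series_table()` / `write_series_table()`.

## Command line

A thin CLI over the same functions is installed at
`inst/cli/rtdetrend.R`:

```sh
Rscript inst/cli/rtdetrend.R simulate  --out suite/ --designs "10,10" --seed 1
Rscript inst/cli/rtdetrend.R detrend   --method ema --alpha 0.995 --in x.tsv --out y.tsv
Rscript inst/cli/rtdetrend.R optimize  --method iglm-window --design 40,40 --seed 1 --out opt.json
Rscript inst/cli/rtdetrend.R benchmark --out records.csv --designs "10,10" --seed 1
Rscript inst/cli/rtdetrend.R report    --in records.csv --out report/
```

Every run writes a log with the resolved configuration, master seed and a
configuration hash that is embedded in all output artifacts.

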