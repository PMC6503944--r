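Package: rtdetrend
Title: Online Detrending Algorithms for Real-Time fMRI Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A test-bed for causal (real-time) detrending of single-voxel or
    VOI-averaged fMRI time series. Implements the exponential moving average
    (EMA) high-pass filter, the incremental general linear model (iGLM), and
    the sliding-window iGLM as streaming, sample-by-sample estimators,
    together with retrospective references (piecewise straight-line removal
    and discrete-cosine-basis high-pass regression). Includes a block-design
    BOLD simulator (boxcar convolved with the canonical double-gamma
    haemodynamic response) with six seeded artifact models (Gaussian noise,
    linear and non-linear drift, autocorrelated noise, spikes, stepped
    baseline shifts), a correlation-based benchmark, and a grid-search
    optimizer for the free parameters of the online algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
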