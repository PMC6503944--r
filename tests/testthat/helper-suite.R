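# Shared fixtures, generated in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Master seed for all test fixtures.
TEST_SEED <- 20190501L

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Full-ensemble suites at the two benchmark block lengths.
full_suite_10 <- function() cached("s10", function() {
  generate_suite(suite_config(master_seed = TEST_SEED), designs = list(c(10, 10)))
})

full_suite_40 <- function() cached("s40", function() {
  generate_suite(suite_config(master_seed = TEST_SEED), designs = list(c(40, 40)))
})

# A reduced configuration for cheap bookkeeping tests.
small_config <- function(...) {
  defaults <- list(n_reg = c(10L, 20L), n_bl = 10L, n_blocks = 3L,
                   snr_db = c(10, 20), slopes = c(0.1, 0.2),
                   nonlinear_sd = 0.5, colored_sd = 0.5,
                   n_replicates = 2L, master_seed = TEST_SEED)
  do.call(suite_config, utils::modifyList(defaults, list(...)))
}

design_10 <- function() cached("d10", function() block_design(10, 10, 15))
clean_10 <- function() cached("c10", function() make_clean_signal(design_10()))
dm_10 <- function() cached("dm10", function() build_design_matrix(design_10()))

# Run a streaming detrender over a vector via its update function.
stream_run <- function(state, update, x) {
  out <- numeric(length(x))
  warm <- logical(length(x))
  for (t in seq_along(x)) {
    up <- update(state, x[t])
    state <- up$state
    out[t] <- up$output$detrended_value
    warm[t] <- up$output$warmup_flag
  }
  list(detrended = out, warmup = warm, state = state)
}
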