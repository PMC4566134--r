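# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small toy problem: quick to simulate and phase, still P212121
small_truth <- function() {
  fixture("small_truth", function() {
    make_toy_structure(seed = 3, n_atoms = 12, cell = unit_cell(18, 22, 26),
                       d_min = 3.0)
  })
}

# default-size toy problem (the study conditions)
default_truth <- function() {
  fixture("default_truth", function() make_toy_structure(seed = 42))
}

noiseless_config <- function(seed = 11, n_patterns = 2) {
  sim_config(seed = seed, n_patterns = n_patterns, observed_fraction = 1,
             p_min = 1, scale_sdlog = 0, background = 0,
             counting_noise = FALSE)
}

# noiseless exact merged data for a truth object
exact_merged <- function(truth, which = "native") {
  key <- paste0("exact_merged_", substr(which, 1, 3), "_",
                signif(truth$cell$volume, 6), "_", nrow(truth$atoms_native))
  fixture(key, function() {
    st <- simulate_patterns(truth, which, noiseless_config())
    merge_patterns(st, truth$cell, truth$sg, keep_friedel_separate = TRUE)
  })
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
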