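# Shared fixtures for the test suite.

# Reduced grammar for exhaustive small-L work: under the default grammar
# (minimum helix 15) no string of length <= 10 can contain a membrane
# segment, so exhaustive checks at that size would leave most rules
# unexercised.
relaxed_grammar <- function() {
  grammar_config(min_helix_len = 3L, min_sp_len = 2L, max_sp_len = 6L)
}

# A random voting profile built from fully random (not necessarily
# grammar-valid) per-method label strings, as raw predictors might emit.
random_profile <- function(L, n_methods) {
  preds <- vapply(seq_len(n_methods), function(m) {
    paste(sample(topo_labels, L, replace = TRUE), collapse = "")
  }, character(1))
  topo_profile(preds)
}

# Small noise-free simulation config helpers.
quiet_sim_config <- function(...) {
  defaults <- list(boundary_shift_max = 0L, helix_drop_prob = 0,
                   helix_add_prob = 0, sp_tm_swap_prob = 0,
                   sp_drop_prob = 0, invert_prob = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "topoconsensus", mustWork = TRUE)
}

toy_scale <- function(value = 0.5, window = 21L, ...) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  dg_scale(rlang::set_names(rep(value, 20L), aa), window = window, ...)
}

random_scale <- function(window = 21L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  dg_scale(rlang::set_names(stats::runif(20L, -2, 4), aa), window = window)
}
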