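# Small panels used across test files, plus a one-slot cache for the
# expensive shared fixtures so several tests can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_compounds = 100, n_cell_lines = 10, n_tissues = 4,
         n_clusters = 2, seed = 7),
    list(...))
  do.call(panel_spec, args)
}

small_panel <- function() {
  cached("small_panel", {
    sp <- generate_panel(small_spec())
    list(sp = sp, panel = as_pgm_panel(sp))
  })
}

# medium panel for strategy/conformal unit tests
medium_panel <- function() {
  cached("medium_panel", {
    sp <- generate_panel(panel_spec(n_compounds = 300, n_cell_lines = 12,
                                    n_tissues = 5, seed = 11))
    panel <- as_pgm_panel(sp)
    enc <- encode_cell_lines(sort(unique(panel$pairs$cell_line_id)),
                             "view", sp$views$expr)
    list(sp = sp, panel = panel, enc = enc)
  })
}

fast_rf <- function(seed = 1L) model_config(mtry = "sqrt", seed = seed)

# hand-made panel from explicit replicate records
panel_from_records <- function(records, tissues, default_uncertainty = NULL) {
  aggregate_replicates(records, tissues, default_uncertainty)
}
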