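# Shared fixtures: small random arrays and the scaled phantom study used by
# the end-to-end tests. The study runs are cached per seed so several tests
# can interrogate the same trained model.

rand_arr <- function(dims, seed = 1, sd = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims), 0, sd), dims)
}

study_phantom_spec <- function(seed = 1) {
  phantom_spec(grid_shape = c(16, 16, 16), n_vertebrae = 3,
               curve_amplitude = 1.5, seed = seed)
}

study_config <- function(seed) {
  train_config(epochs = 30, decay_start_epoch = 15, batch_size = 2,
               patch_shape = c(16, 16, 16), steps_per_epoch = 4,
               gen_depth = 2, gen_base_filters = 4,
               disc_n_layers = 2, disc_base_filters = 4, seed = seed)
}

.study_cache <- new.env(parent = emptyenv())

# Train the scaled spine study for one seed: 8 unpaired 16^3 phantoms,
# 30 epochs, gradient consistency + uncertainty on; evaluate the aleatoric
# tissue/bone contrast on a held-out phantom.
run_study <- function(seed) {
  key <- paste0("seed", seed)
  hit <- .study_cache[[key]]
  if (!is.null(hit)) return(hit)
  ds <- make_unpaired_dataset(study_phantom_spec(seed), 4, 4, seed = seed)
  run <- fit(ds$a, ds$b, study_config(seed))
  heldout <- make_phantom(study_phantom_spec(seed + 555))
  ev <- evaluate_aleatoric_contrast(run, heldout, T = 20, seed = seed)
  out <- list(run = run, heldout = heldout, eval = ev)
  .study_cache[[key]] <- out
  out
}

epoch_totals <- function(run) {
  stats::aggregate(total ~ epoch, run$log, mean)$total
}

# Tiny training config for smoke-level tests (8^3 volumes, seconds).
tiny_config <- function(..., seed = 1) {
  defaults <- list(epochs = 2, decay_start_epoch = 1, batch_size = 2,
                   patch_shape = c(8, 8, 8), gen_depth = 2,
                   gen_base_filters = 2, disc_n_layers = 2,
                   disc_base_filters = 2, pool_size = 4, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

tiny_dataset <- function(n_a = 2, n_b = 2, seed = 1) {
  spec <- phantom_spec(grid_shape = c(8, 8, 8), n_vertebrae = 1,
                       curve_amplitude = 1, seed = seed)
  make_unpaired_dataset(spec, n_a, n_b, seed = seed)
}
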