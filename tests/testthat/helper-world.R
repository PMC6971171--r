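# Shared test world: the reduced-scale configuration (50 neurons/layer, 50
# epochs, seed 1) and its calibration, computed once per test run and reused
# by every file (helpers persist across test files within one test_dir run).

.world <- new.env(parent = emptyenv())

reduced_config <- function(n_layers = 0, ...) {
  pathway_config(n_interneuron_layers = n_layers, neurons_per_layer = 50,
                 epochs = 50, seed = 1, ...)
}

world_calibration <- function() {
  if (is.null(.world$cal)) {
    .world$cal <- calibrate_pathway(reduced_config(2))
  }
  .world$cal
}

# Layer sweep (layers 0..3, 10 repetitions) shared between the headline
# acceptance claims; computed on first use.
world_layer_sweep <- function() {
  if (is.null(.world$sweep)) {
    spec <- experiment_spec("layer_sweep", tier = "reduced", layers = 0:3, seed = 1)
    .world$sweep <- run_layer_sweep(spec, calibration = world_calibration())
  }
  .world$sweep
}
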