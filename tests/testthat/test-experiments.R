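# Experiment protocols: fixtures, spec validation, manifests and the exact
# consistency contracts between protocols under shared seeds.

test_that("coupling fixtures carry their analytic targets", {
  fa <- make_coupling_fixtures("identical", epochs = 40, seed = 1)
  expect_equal(fa$target$nmc, 1)
  expect_equal(nmc(fa$x, fa$y, 25, 25), 1, tolerance = 1e-12)
  fb <- make_coupling_fixtures("phase_locked", f0 = 10, f1 = 20, epochs = 60, seed = 2)
  expect_equal(nmc(fb$x, fb$y, fb$target$f_x, fb$target$f_y), fb$target$nmc,
               tolerance = 1e-10)
  fc <- make_coupling_fixtures("independent", epochs = 60, seed = 3)
  expect_lt(nmc(fc$x, fc$y, 10, 20), 0.35)
  expect_equal(fc$target$nmc, 0)
  fm <- make_coupling_fixtures("mixture", f0 = 10, f1 = 20, epochs = 60,
                               strength = 0.5, seed = 4)
  expect_gt(fm$target$nmc, 0.4)
  expect_lt(fm$target$nmc, 0.95)
  expect_equal(nmc(fm$x, fm$y, 10, 20), fm$target$nmc, tolerance = 1e-12)
})

test_that("experiment specifications validate the protocol constraints", {
  s <- experiment_spec("layer_sweep", tier = "reduced")
  expect_equal(s$epochs, 50L)
  expect_equal(s$repetitions, 10L)
  expect_equal(s$neurons_per_layer, 50L)
  expect_error(experiment_spec("layer_sweep", layers = 1:3), "start at 0")
  expect_error(experiment_spec("dual_drive", proportions = c(0, 0.3)),
               "multiples of 20")
  full <- experiment_spec("per_layer", tier = "full")
  expect_equal(full$epochs, 200L)
  expect_equal(full$repetitions, 100L)
})

test_that("protocols agree exactly under shared seeds (tiny scale)", {
  # tiny world: 20 neurons/layer, 8 epochs, 1 repetition; hand-made
  # calibration constants (this is a consistency contract, not a physiology
  # claim, so the drive only needs to produce spikes)
  cal <- structure(list(g_peak_in = 0.016, g_peak_mn = 0.007,
                        dc_in = 1.7, q_in = 0.2, fan_in = 10L,
                        mn_spread = 4, el_cap_mn = -53,
                        dc_mn = 2, q_mn = 2, achieved = list()),
                   class = "pathway_calibration")
  spec <- experiment_spec("layer_sweep", layers = 0:2, repetitions = 1,
                          epochs = 8, neurons_per_layer = 20,
                          n_surrogates = 60, seed = 4)
  sweep <- run_layer_sweep(spec, calibration = cal)
  expect_setequal(sweep$layers, 0:2)

  # deterministic rerun: bit-identical table
  sweep2 <- run_layer_sweep(spec, calibration = cal)
  expect_identical(sweep, sweep2)

  # dual drive at 0% indirect equals the mono-synaptic pathway, and at 100%
  # equals the 2-layer pathway, under shared seeds
  dspec <- experiment_spec("dual_drive", proportions = c(0, 1), repetitions = 1,
                           epochs = 8, neurons_per_layer = 20,
                           n_surrogates = 60, seed = 4)
  dual <- run_dual_drive(dspec, calibration = cal)
  cfg0 <- pathway_config(0, neurons_per_layer = 20, epochs = 8, seed = 4)
  cfg2 <- pathway_config(2, neurons_per_layer = 20, epochs = 8, seed = 4,
                         inputs_per_interneuron = 10)
  sim0 <- simulate_pathway(cfg0, cal, noise_rep = 1)
  sim2 <- simulate_pathway(cfg2, cal, noise_rep = 1)
  cst0 <- cumulative_spike_train(sim0)
  cst2 <- cumulative_spike_train(sim2)
  # rebuild the dual-drive motoneuron output at the endpoints directly
  cfg_w0 <- pathway_config(2, neurons_per_layer = 20, epochs = 8, seed = 4,
                           inputs_per_interneuron = 10, indirect_weight = 0)
  chain <- simulate_chain(cfg_w0, cal, noise_rep = 1)
  mn_w0 <- simulate_mn_pool(cfg_w0, cal, chain, noise_rep = 1)
  expect_identical(mn_w0$spikes, sim0$mn_spikes)
  cfg_w1 <- pathway_config(2, neurons_per_layer = 20, epochs = 8, seed = 4,
                           inputs_per_interneuron = 10, indirect_weight = 1)
  mn_w1 <- simulate_mn_pool(cfg_w1, cal, chain, noise_rep = 1)
  expect_identical(mn_w1$spikes, sim2$mn_spikes)
  # and the summarized COI rows match the sweep rows at the endpoints
  expect_equal(dual$ifc[dual$indirect == 0], sweep$ifc[sweep$layers == 0])
  expect_equal(dual$ifc[dual$indirect == 1], sweep$ifc[sweep$layers == 2])

  # per-layer protocol: the motoneuron row of a depth-D pathway equals the
  # D-layer sweep entry
  pspec <- experiment_spec("per_layer", layers = 2, repetitions = 1,
                           epochs = 8, neurons_per_layer = 20,
                           n_surrogates = 60, seed = 4)
  pl <- run_per_layer(pspec, calibration = cal)
  expect_equal(pl$ifc[pl$layer == "mn"], sweep$ifc[sweep$layers == 2])
  expect_setequal(unique(pl$layer), c("1", "2", "mn"))
})

test_that("experiment outputs include a reproducibility manifest", {
  dir <- tempfile("exp")
  cal <- structure(list(g_peak_in = 0.016, g_peak_mn = 0.007, dc_in = 1.7,
                        q_in = 0.2, fan_in = 5L, mn_spread = 4,
                        el_cap_mn = -53, dc_mn = 2, q_mn = 1,
                        achieved = list()), class = "pathway_calibration")
  spec <- experiment_spec("layer_sweep", layers = 0:1, repetitions = 1,
                          epochs = 4, neurons_per_layer = 10,
                          n_surrogates = 30, seed = 2, out_dir = dir)
  res <- run_layer_sweep(spec, calibration = cal)
  files <- write_experiment(res, spec)
  expect_true(all(file.exists(files)))
  man <- jsonlite::read_json(files[["manifest"]])
  expect_true(all(c("package_version", "spec_hash", "params_hash", "spec") %in%
                    names(man)))
  expect_equal(man$spec$seed, 2)
  back <- utils::read.csv(files[["data"]])
  expect_equal(nrow(back), nrow(res))
})

test_that("the command-line interface parses flags and rejects bad usage", {
  fl <- nmcoupling:::cli_flags(c("--seed", "7", "--tier", "full", "--quiet"))
  expect_equal(fl$seed, "7")
  expect_equal(fl$tier, "full")
  expect_true(fl$quiet)
  expect_error(nmcoupling:::cli_flags(c("oops")), "unexpected argument")
  expect_equal(nmc_cli(character(0), exit = FALSE), 2)
  expect_equal(suppressMessages(nmc_cli("frobnicate", exit = FALSE)), 2)
})

test_that("fixtures subcommand writes signals and targets", {
  dir <- tempfile("fix")
  status <- suppressMessages(nmc_cli(c("fixtures", "--kind", "phase_locked",
                                       "--seed", "3", "--out", dir),
                                     exit = FALSE))
  expect_equal(status, 0)
  expect_true(file.exists(file.path(dir, "fixture_target.csv")))
  tg <- utils::read.csv(file.path(dir, "fixture_target.csv"))
  expect_equal(tg$nmc, 1)
})
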