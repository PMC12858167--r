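# Shared fixtures, built once per test run and memoised. All synthetic: the
# generator is the package's own first-class module.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small boundary-scenario dataset: 4 subjects x 256 trials
fx_boundary_trials <- function() {
  fixture("boundary_trials", function() {
    simulate_experiment(design_spec(4),
                        ground_truth(4, scenario = "boundary", seed = 5),
                        seed = 7)
  })
}

# matching fit at a modest but convergent budget (3 chains)
fx_boundary_fit <- function() {
  fixture("boundary_fit", function() {
    fit_hddm(fx_boundary_trials(),
             mcmc_config(n_chains = 3, burn_in = 1500, draws = 3000,
                         thin = 3),
             seed = 11)
  })
}

# neural-coupled dataset (boundary coupling, gamma = 0.4) and decoupled one
fx_neural_trials <- function() {
  fixture("neural_trials", function() {
    simulate_experiment(design_spec(4),
                        ground_truth(4, scenario = "boundary", gamma = 0.4,
                                     seed = 21),
                        seed = 23)
  })
}

fx_null_trials <- function() {
  fixture("null_trials", function() {
    simulate_experiment(design_spec(4),
                        ground_truth(4, scenario = "null", seed = 31),
                        seed = 33)
  })
}

quick_cfg <- function(chains = 1) {
  mcmc_config(n_chains = chains, burn_in = 400, draws = 800, thin = 2)
}

# bare 2x2 trial table with known per-cell success probabilities, for
# closed-form logit oracles
saturated_records <- function(probs, n_per_cell, seed, n_subjects = 20) {
  set.seed(seed)
  grid <- expand.grid(task = c("perceptual", "value"),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(4), function(i) {
    data.frame(subject_id = sample.int(n_subjects, n_per_cell,
                                       replace = TRUE),
               task = grid$task[i], phase = grid$phase[i],
               evidence_level = sample(1:4, n_per_cell, replace = TRUE),
               ev_irrelevant = sample(1:4, n_per_cell, replace = TRUE),
               correct = rbinom(n_per_cell, 1, probs[i]),
               rt_s = runif(n_per_cell, 0.4, 2.5), valid = 1L)
  })
  do.call(rbind, rows)
}

# single-chain Model-1 fits on the coupled and decoupled datasets
fx_m1_coupled_fit <- function() {
  fixture("m1_coupled_fit", function() {
    suppressWarnings(fit_neural_ddm(
      fx_neural_trials(), 1,
      mcmc_config(n_chains = 1, burn_in = 600, draws = 1200, thin = 2),
      seed = 52))
  })
}

fx_m1_null_fit <- function() {
  fixture("m1_null_fit", function() {
    suppressWarnings(fit_neural_ddm(
      fx_null_trials(), 1,
      mcmc_config(n_chains = 1, burn_in = 600, draws = 1200, thin = 2),
      seed = 53))
  })
}
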