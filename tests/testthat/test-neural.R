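test_that("neural modulation arithmetic and clipping behave as specified", {
  expect_equal(neural_boundary(1.5, 0, 2), 1.5)
  expect_equal(neural_boundary(1.5, 0.2, 0), 1.5)
  expect_equal(neural_boundary(1.5, 0.2, 1.5), 1.8)
  expect_equal(neural_boundary(1.5, 0.5, -3.2), 0.05)  # floored
  expect_equal(neural_drift(0.5, 4, 0, 1), 2)
  expect_equal(neural_drift(0.5, 4, 0.3, -1), 1.7)
  expect_equal(neural_drift(0.5, 4, 0.3, 1) - 0.5 * 4,
               -(neural_drift(0.5, 4, 0.3, -1) - 0.5 * 4))
})

test_that("model specifications pin the modulated parameter sets", {
  expect_identical(neural_model_spec(1)$modulates, "boundary")
  expect_identical(neural_model_spec(2)$modulates, "drift")
  m3 <- neural_model_spec(3)
  m4 <- neural_model_spec(4)
  expect_setequal(m3$modulates, c("boundary", "drift"))
  expect_identical(m3$gamma_structure, "separate")
  expect_identical(m4$gamma_structure, "shared")
  expect_error(neural_model_spec(9), "unknown model")
})

test_that("with gamma pinned at zero every neural likelihood equals baseline", {
  rec <- fx_neural_trials()
  v <- rec[rec$valid == 1 & rec$subject_id == 1 &
             rec$task == "perceptual" & rec$phase == "pre", ]
  base <- driftdid:::cpp_loglik_cell(v$rt_s, v$correct, v$evidence_level,
                                     0.45, 1.6, 0.3, 0.5)
  neur <- driftdid:::cpp_loglik_cell_neural(v$rt_s, v$correct,
                                            v$evidence_level, v$sfs_beta,
                                            0.45, 1.6, 0.3, 0, 0, 0.5,
                                            0.05)
  expect_equal(neur[1], base, tolerance = 1e-10)
  expect_identical(neur[2], 0)
})

test_that("missing betas on valid trials abort a neural fit", {
  rec <- fx_neural_trials()
  rec$sfs_beta[which(rec$valid == 1)[1]] <- NA
  expect_error(fit_neural_ddm(rec, 1, quick_cfg()), "betas missing")
})

test_that("boundary-coupled data recover gamma and the null covers zero", {
  # coupled generator (gamma = 0.4 before measurement-noise attenuation)
  f1 <- fx_m1_coupled_fit()
  g <- rowMeans(extract_draws(f1, "^gamma_a\\[", regex = TRUE))
  expect_gt(mean(g), 0.1)
  expect_lt(mean(g), 0.6)
  expect_lt(f1$clip_frac, 0.01)
  # decoupled generator: the across-subject mean coupling covers 0
  f0 <- fx_m1_null_fit()
  g0 <- rowMeans(extract_draws(f0, "^gamma_a\\[", regex = TRUE))
  ci <- quantile(g0, c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("shared- and separate-gamma models agree when both couplings are equal", {
  # bespoke generator: equal coupling of boundary and drift, built directly
  # on the trial simulator
  set.seed(64)
  g <- 0.3
  rows <- list()
  for (s in 1:4) {
    for (cl in c("perceptual.pre", "perceptual.post", "value.pre",
                 "value.post")) {
      n <- 64
      th <- rnorm(n)
      ev <- rep(1:4, 16)
      a <- pmax(1.6 + g * th, 0.05)
      v <- 0.4 * ev + g * th
      sim <- driftdid:::cpp_sim_trials(v, a, rep(0.5, n), rep(0.3, n), n,
                                       1e-3, 60, s * 1000 + nchar(cl),
                                       0.5826 * sqrt(1e-3))
      tp <- strsplit(cl, ".", fixed = TRUE)[[1]]
      rows[[paste(s, cl)]] <- data.frame(
        subject_id = s, task = tp[1], phase = tp[2],
        evidence_level = ev, correct = sim$upper,
        rt_s = sim$rt, sfs_beta = (th - mean(th)) / sd(th), valid = 1L)
    }
  }
  rec <- do.call(rbind, rows)
  rec <- rec[rec$rt_s <= 3, ]
  cfg <- mcmc_config(n_chains = 1, burn_in = 500, draws = 1000, thin = 2)
  f3 <- suppressWarnings(fit_neural_ddm(rec, 3, cfg, seed = 65))
  f4 <- suppressWarnings(fit_neural_ddm(rec, 4, cfg, seed = 66))
  g3a <- mean(extract_draws(f3, "^gamma_a\\[", regex = TRUE))
  g3d <- mean(extract_draws(f3, "^gamma_d\\[", regex = TRUE))
  g4 <- mean(extract_draws(f4, "^gamma\\[", regex = TRUE))
  expect_lt(abs(g3a - g4), 0.15)
  expect_lt(abs(g3d - g4), 0.15)
  expect_gt(g4, 0.05)
})

test_that("DIC definition matches an explicit per-draw recomputation", {
  f0 <- fx_m1_null_fit()
  rec <- fx_null_trials()
  d <- dic(f0, rec)
  expect_equal(d$dic, d$dbar + d$pd, tolerance = 1e-12)
  # brute-force oracle: recompute the deviance of 25 draws through the
  # R-level likelihood with per-cell parameter tables
  dr <- f0$draws
  flat <- matrix(dr, nrow = dim(dr)[1] * dim(dr)[2],
                 dimnames = list(NULL, dimnames(dr)[[3]]))
  take <- seq(1, nrow(flat), length.out = 25)
  grid <- expand.grid(s = 1:4, task = c("perceptual", "value"),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  devs <- vapply(take, function(i) {
    pars <- data.frame(subject_id = f0$subjects[grid$s], task = grid$task,
                       phase = grid$phase,
                       kappa = flat[i, sprintf("kappa[%d,%s.%s]", grid$s,
                                               grid$task, grid$phase)],
                       alpha = flat[i, sprintf("alpha[%d,%s.%s]", grid$s,
                                               grid$task, grid$phase)],
                       tau = flat[i, sprintf("tau[%d,%s.%s]", grid$s,
                                             grid$task, grid$phase)])
    ga <- flat[i, sprintf("gamma_a[%d]", grid$s)]
    # gamma enters the boundary trialwise; fold it in through the records
    rec_v <- rec[rec$valid == 1, ]
    key <- paste(rec_v$subject_id, rec_v$task, rec_v$phase)
    idx <- match(key, paste(pars$subject_id, pars$task, pars$phase))
    a_eff <- neural_boundary(pars$alpha[idx],
                             ga[match(rec_v$subject_id, f0$subjects)],
                             rec_v$sfs_beta)
    ll <- driftdid:::cpp_fpt_log_density(
      rec_v$rt_s, as.integer(rec_v$correct),
      pars$kappa[idx] * rec_v$evidence_level, a_eff, pars$tau[idx], 0.5)
    -2 * sum(ll)
  }, numeric(1))
  # the same draws through dic()'s internal path
  nm <- driftdid:::likelihood_param_names(f0)
  gcn <- driftdid:::gamma_cols(f0)
  prep <- driftdid:::prepare_cells(rec, need_theta = TRUE)
  devs2 <- vapply(take, function(i) {
    driftdid:::deviance_at(prep$dat, 4,
                           matrix(flat[i, nm$kappa], 4, 4),
                           matrix(flat[i, nm$alpha], 4, 4),
                           matrix(flat[i, nm$tau], 4, 4),
                           flat[i, gcn$ga], NULL, f0$w, f0$floor_a)
  }, numeric(1))
  expect_equal(devs, devs2, tolerance = 1e-8)
})

test_that("an inert coupling parameter cannot improve DIC materially", {
  f0 <- fx_m1_null_fit()
  rec <- fx_null_trials()
  cfg <- mcmc_config(n_chains = 1, burn_in = 600, draws = 1200, thin = 2)
  fb <- suppressWarnings(fit_hddm(rec, cfg, seed = 54))
  d_base <- dic(fb, rec)
  d_m1 <- dic(f0, rec)
  # gamma is decoupled from behaviour: model 1 cannot beat baseline beyond
  # Monte-Carlo error in the deviance estimate
  expect_gt(d_m1$dic - d_base$dic, -15)
  cmp <- compare_models(list(d_base, d_m1))
  expect_identical(cmp$relative_dic[cmp$model_id == "baseline"], 0)
  # mismatched data are refused
  other <- dic(suppressWarnings(fit_hddm(fx_boundary_trials(), cfg,
                                         seed = 55)),
               fx_boundary_trials())
  expect_error(compare_models(list(d_base, other)), "different datasets")
})
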