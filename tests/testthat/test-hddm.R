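# independent reference for the lower-boundary first-passage density:
# pure large-time series with a fixed large number of terms, written
# directly from the standardized series (valid for the decision times used
# here), independent of the package's adaptive small/large-time switch.
ref_wfpt_lower <- function(t, v, a, w, K = 300) {
  tt <- t / a^2
  k <- seq_len(K)
  f <- pi * sum(k * exp(-k^2 * pi^2 * tt / 2) * sin(k * pi * w))
  f / a^2 * exp(-v * a * w - v^2 * t / 2)
}

test_that("trialwise log-likelihood matches an independent series evaluation", {
  trials <- data.frame(subject_id = 1, task = "perceptual", phase = "pre",
                       evidence_level = c(2, 3, 1), correct = c(1L, 0L, 1L),
                       rt_s = c(0.9, 1.4, 2.1), valid = 1L)
  kappa <- 0.5; alpha <- 1.7; tau <- 0.3
  ref <- sum(vapply(seq_len(3), function(i) {
    v <- kappa * trials$evidence_level[i]
    td <- trials$rt_s[i] - tau
    # upper boundary by reflection (v, w) -> (-v, 1 - w)
    d <- if (trials$correct[i] == 1) ref_wfpt_lower(td, -v, alpha, 0.5)
         else ref_wfpt_lower(td, v, alpha, 0.5)
    log(d)
  }, numeric(1)))
  got <- log_likelihood(trials, list(kappa = kappa, alpha = alpha,
                                     tau = tau))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("log-likelihood is additive and guards its support", {
  t2 <- data.frame(subject_id = 1, task = "value", phase = "post",
                   evidence_level = c(1, 4), correct = c(0L, 1L),
                   rt_s = c(0.7, 1.1), valid = 1L)
  p <- list(kappa = 0.4, alpha = 1.5, tau = 0.25)
  ll12 <- log_likelihood(t2, p)
  ll1 <- log_likelihood(t2[1, ], p)
  ll2 <- log_likelihood(t2[2, ], p)
  expect_equal(ll12, ll1 + ll2, tolerance = 1e-12)
  # rt at or below tau sinks the whole table and reports the trial
  bad <- t2; bad$rt_s[2] <- 0.2
  llb <- log_likelihood(bad, p)
  expect_identical(as.numeric(llb), -Inf)
  expect_identical(attr(llb, "offending_trial"), 2L)
})

test_that("chain bookkeeping follows the thinning arithmetic exactly", {
  cfg <- mcmc_config(n_chains = 3, burn_in = 10, draws = 120, thin = 4)
  expect_identical(retained_draws(cfg), 30L)
  expect_identical(retained_draws(paper_scale_config()), 1000L)
  expect_error(mcmc_config(draws = 100, thin = 7), "exact multiple")
  d <- rw_mcmc(function(x) dnorm(x, log = TRUE), c(th = 0),
               mcmc_config(2, 50, 120, 4), seed = 3)
  expect_identical(dim(unclass(d)), c(2L, 30L, 1L))
})

test_that("Gelman-Rubin separates stationary from divergent chains", {
  set.seed(61)
  # 20 repetitions of three independent stationary chains all converge
  rh <- replicate(20, {
    x <- array(rnorm(3 * 1000), dim = c(3, 1000, 1))
    gelman_rubin(x)[1]
  })
  expect_true(all(rh < 1.05))
  # grossly separated chains must fail loudly
  bad <- array(c(rnorm(1000, 0), rnorm(1000, 10), rnorm(1000, 0)),
               dim = c(1000, 3, 1))
  bad <- aperm(bad, c(2, 1, 3))
  expect_gt(gelman_rubin(bad)[1], 1.5)
  expect_error(gelman_rubin(array(rnorm(100), dim = c(1, 100, 1))),
               "2 chains")
})

test_that("posterior tail probabilities count the opposite side with a floor", {
  expect_equal(posterior_p(rep(1, 1000), "above_zero")$p_mcmc, 1 / 1001)
  expect_equal(posterior_p(c(rep(-1, 970), rep(1, 30)),
                           "below_zero")$p_mcmc, 0.03)
  sym <- c(seq(-1, -0.01, length.out = 500),
           seq(0.01, 1, length.out = 500))
  expect_equal(posterior_p(sym, "below_zero")$p_mcmc, 0.5)
  expect_error(posterior_p(rnorm(50), "below_zero"), "at least 100")
  expect_error(posterior_p(numeric(0)), "no draws")
})

test_that("posterior DID equals the explicit drawwise contrast", {
  set.seed(71)
  cells <- list(perceptual.pre = rnorm(500), perceptual.post = rnorm(500),
                value.pre = rnorm(500), value.post = rnorm(500))
  eff <- posterior_did(cells)
  loop <- vapply(seq_len(500), function(i) {
    (cells$perceptual.post[i] - cells$perceptual.pre[i]) -
      (cells$value.post[i] - cells$value.pre[i])
  }, numeric(1))
  expect_equal(eff, loop, tolerance = 1e-12)
  same <- lapply(cells[c(1, 1, 1, 1)], identity)
  names(same) <- names(cells)
  expect_true(all(posterior_did(same) == 0))
  shifted <- cells
  shifted$perceptual.post <- cells$perceptual.pre - 0.4 +
    (cells$value.post - cells$value.pre)
  expect_equal(mean(posterior_did(shifted)), -0.4, tolerance = 1e-12)
  expect_error(posterior_did(cells[c(1, 2, 3)]), "must contain")
  short <- cells; short$value.post <- short$value.post[1:10]
  expect_error(posterior_did(short), "mismatched")
})

test_that("a zero-data fit reproduces its prior", {
  rec <- fx_null_trials()[0, ]
  f <- suppressWarnings(fit_hddm(rec, mcmc_config(2, 800, 3200, 4),
                                 seed = 3))
  set.seed(81)
  pr_a <- rnorm(40000, 1.5, 1); pr_a <- pr_a[pr_a > 0][1:3000]
  pr_t <- rnorm(40000, 0.3, 0.25); pr_t <- pr_t[pr_t >= 0][1:3000]
  ks_a <- suppressWarnings(ks.test(
    extract_draws(f, "mu_alpha[perceptual.pre]")[, 1], pr_a))$statistic
  ks_t <- suppressWarnings(ks.test(
    extract_draws(f, "mu_tau[value.post]")[, 1], pr_t))$statistic
  expect_lt(ks_a, 0.05)
  expect_lt(ks_t, 0.05)
})

test_that("the hierarchical fit converges and recovers the boundary effect", {
  fit <- fx_boundary_fit()
  expect_identical(dim(fit$draws)[1:2], c(3L, 1000L))
  expect_lt(max(fit$rhat), 1.05)
  expect_true(fit$converged)
  # no stored draw violates its positivity constraint
  alphas <- extract_draws(fit, "^alpha\\[", regex = TRUE)
  taus <- extract_draws(fit, "^tau\\[", regex = TRUE)
  sigmas <- extract_draws(fit, "^sigma_", regex = TRUE)
  expect_true(all(alphas > 0) && all(taus >= 0) && all(sigmas > 0))
  # the generating boundary drop (-0.35 in perceptual post cells) appears
  # in the group-level posterior contrast
  did_a <- hddm_did(fit, "alpha", "below_zero")
  expect_lt(did_a$mean, 0)
})

test_that("group posterior means are insensitive to doubling prior scales", {
  rec <- fx_boundary_trials()
  cfg <- mcmc_config(n_chains = 1, burn_in = 500, draws = 1200, thin = 2)
  f1 <- suppressWarnings(fit_hddm(rec, cfg, priors = hddm_priors(1),
                                  seed = 41))
  f2 <- suppressWarnings(fit_hddm(rec, cfg, priors = hddm_priors(2),
                                  seed = 41))
  for (nm in c("mu_kappa", "mu_alpha", "mu_tau")) {
    m1 <- colMeans(extract_draws(f1, paste0("^", nm), regex = TRUE))
    m2 <- colMeans(extract_draws(f2, paste0("^", nm), regex = TRUE))
    expect_lt(max(abs(m2 - m1) / pmax(abs(m1), 0.2)), 0.05)
  }
})

test_that("posterior predictive brackets the data it was fitted to and flags a mismatch", {
  fit <- fx_boundary_fit()
  rec <- fx_boundary_trials()
  ppc <- posterior_predictive(fit, rec, n_draws = 80, seed = 91)
  acc <- ppc[ppc$stat == "accuracy", ]
  expect_gte(sum(acc$inside), 3)  # at least 3 of 4 cells bracketed
  # predictive RT floor respects the posterior non-decision time
  q10 <- ppc[ppc$stat == "rt_q10", ]
  mean_tau <- mean(extract_draws(fit, "^tau\\[", regex = TRUE))
  expect_true(all(q10$pred_mean > mean_tau * 0.5))
  # data generated at a doubled boundary should fall outside
  tr2 <- ground_truth(4, scenario = "boundary", seed = 5, mu_alpha = 3.2)
  rec2 <- simulate_experiment(design_spec(4), tr2, seed = 7)
  ppc2 <- suppressWarnings(posterior_predictive(fit, rec2, n_draws = 80,
                                                seed = 92))
  acc2 <- ppc2[ppc2$stat == "accuracy", ]
  expect_gte(sum(!acc2$inside), 3)
})
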