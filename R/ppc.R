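#' Posterior-predictive check of choice proportions and RT quantiles
#'
#' Simulates the experiment's valid trials from a subsample of posterior
#' draws (each draw's subject-by-cell parameters, including any neural
#' coupling applied to the observed trialwise covariate) and compares the
#' per-cell predicted accuracy and RT deciles, with Monte-Carlo 95%
#' intervals, against the observed values.
#'
#' @param fit an `hddm_fit`.
#' @param records the trial table the model was fitted to.
#' @param n_draws number of posterior draws to simulate (subsampled evenly).
#' @param seed integer seed.
#' @param dt Euler-Maruyama step for the predictive simulations.
#' @return A data.frame with columns `cell`, `stat` (accuracy or RT decile),
#'   `observed`, `pred_mean`, `lo`, `hi`, `inside` (observed within the 95%
#'   predictive interval).
#' @export
posterior_predictive <- function(fit, records, n_draws = 100, seed = 1,
                                 dt = 1e-3) {
  stopifnot(inherits(fit, "hddm_fit"))
  neural <- fit$model$model_id != "baseline"
  prep <- prepare_cells(records, need_theta = neural)
  if (prep$fingerprint != fit$data_fingerprint) {
    warning("records differ from the data this model was fitted to; ",
            "interpreting as an out-of-sample predictive check",
            call. = FALSE)
  }
  S <- length(fit$subjects)
  nm <- likelihood_param_names(fit)
  gc <- gamma_cols(fit)
  dr <- fit$draws
  flat <- matrix(dr, nrow = dim(dr)[1] * dim(dr)[2],
                 dimnames = list(NULL, dimnames(dr)[[3]]))
  take <- unique(round(seq(1, nrow(flat), length.out = min(n_draws,
                                                           nrow(flat)))))
  qs <- seq(0.1, 0.9, by = 0.1)
  stats <- c("accuracy", sprintf("rt_q%d", as.integer(qs * 100)))
  pred <- array(NA_real_, dim = c(length(take), 4, length(stats)))
  with_seed(derive_seed(seed, "ppc"), {
    for (di in seq_along(take)) {
      i <- take[di]
      K <- matrix(flat[i, nm$kappa], S, 4)
      A <- matrix(flat[i, nm$alpha], S, 4)
      Tau <- matrix(flat[i, nm$tau], S, 4)
      Ga <- if (is.null(gc$ga)) rep(0, S) else flat[i, gc$ga]
      Gd <- if (is.null(gc$gd)) rep(0, S) else flat[i, gc$gd]
      for (ci in 1:4) {
        acc_all <- c(); rt_all <- c()
        for (s in seq_len(S)) {
          d <- prep$dat[[s]][[ci]]
          nti <- length(d$rt)
          th <- if (length(d$theta)) d$theta else rep(0, nti)
          a_eff <- neural_boundary(A[s, ci], Ga[s], th, fit$floor_a)
          v <- neural_drift(K[s, ci], d$ev, Gd[s], th)
          sim <- cpp_sim_trials(v, a_eff, rep(fit$w, nti),
                                rep(Tau[s, ci], nti), nti, dt, 30,
                                cpp_seed(), 0.5826 * sqrt(dt))
          ok <- sim$censored == 0L
          acc_all <- c(acc_all, sim$upper[ok])
          rt_all <- c(rt_all, sim$rt[ok])
        }
        pred[di, ci, 1] <- mean(acc_all)
        pred[di, ci, -1] <- quantile(rt_all, qs)
      }
    }
  })
  obs <- matrix(NA_real_, 4, length(stats))
  for (ci in 1:4) {
    rt <- unlist(lapply(seq_len(S), function(s) prep$dat[[s]][[ci]]$rt))
    cr <- unlist(lapply(seq_len(S), function(s) prep$dat[[s]][[ci]]$correct))
    obs[ci, ] <- c(mean(cr), quantile(rt, qs))
  }
  out <- expand.grid(cell = CELLS, stat = stats, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$observed <- as.vector(obs)
  out$pred_mean <- as.vector(apply(pred, c(2, 3), mean))
  out$lo <- as.vector(apply(pred, c(2, 3), quantile, 0.025))
  out$hi <- as.vector(apply(pred, c(2, 3), quantile, 0.975))
  out$inside <- out$observed >= out$lo & out$observed <= out$hi
  out
}
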