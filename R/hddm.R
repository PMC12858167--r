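CELLS <- c("perceptual.pre", "perceptual.post", "value.pre", "value.post")

#' Default priors for the hierarchical diffusion model
#'
#' Weakly informative, positivity-respecting priors. Group hyper-means:
#' drift scale kappa ~ N(0, 5); boundary alpha ~ N(1.5, 1) truncated > 0;
#' non-decision time tau ~ N(0.3, 0.25) truncated >= 0. All group scales
#' half-normal(0, 1). Neural coupling scales are estimated per subject
#' under a fixed group prior N(0, 0.5).
#'
#' @param scale multiply all prior scales by this factor (for sensitivity
#'   checks).
#' @return A named list of prior hyperparameters.
#' @export
hddm_priors <- function(scale = 1) {
  list(mu_kappa = c(0, 5 * scale),
       mu_alpha = c(1.5, 1 * scale),
       mu_tau = c(0.3, 0.25 * scale),
       sigma_scale = 1 * scale,       # half-normal sd for group scales
       gamma_prior = c(0, 0.5 * scale))
}

#' Neural model specification
#'
#' Which diffusion parameters the trialwise neural covariate modulates:
#' Model 1 the boundary only, Model 2 the drift only, Model 3 both with
#' separate coupling scales, Model 4 both with one shared scale;
#' `"baseline"` has no neural term.
#'
#' @param model_id `"baseline"`, `1`, `2`, `3` or `4`.
#' @return A `neural_model_spec` list with `model_id`, `modulates` and
#'   `gamma_structure`.
#' @export
neural_model_spec <- function(model_id) {
  id <- as.character(model_id)
  spec <- switch(id,
    baseline = list(modulates = character(0), gamma_structure = "none"),
    "1" = list(modulates = "boundary", gamma_structure = "single"),
    "2" = list(modulates = "drift", gamma_structure = "single"),
    "3" = list(modulates = c("boundary", "drift"),
               gamma_structure = "separate"),
    "4" = list(modulates = c("boundary", "drift"),
               gamma_structure = "shared"),
    stop("unknown model id: ", id, call. = FALSE))
  structure(c(list(model_id = id), spec), class = "neural_model_spec")
}

#' Neural modulation of boundary and drift
#'
#' Effective parameters when a z-scored trialwise neural covariate `theta`
#' enters the diffusion process: boundary `alpha + gamma * theta` (floored
#' at a small positive value to keep the likelihood defined) and drift
#' `kappa * evidence + gamma * theta`.
#'
#' @param alpha boundary separation.
#' @param kappa drift scale.
#' @param evidence ordinal evidence level.
#' @param gamma coupling scale.
#' @param theta z-scored neural covariate.
#' @param floor_a positive floor applied to the effective boundary.
#' @return Effective boundary / drift (vectorised).
#' @export
neural_boundary <- function(alpha, gamma, theta, floor_a = 0.05) {
  pmax(alpha + gamma * theta, floor_a)
}

#' @rdname neural_boundary
#' @export
neural_drift <- function(kappa, evidence, gamma, theta) {
  kappa * evidence + gamma * theta
}

# --- data preparation -------------------------------------------------------

cell_key <- function(records) paste(records$task, records$phase, sep = ".")

prepare_cells <- function(records, need_theta = FALSE) {
  req <- c("subject_id", "task", "phase", "evidence_level", "correct",
           "rt_s", "valid")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rec <- records[records$valid == 1, ]
  if (nrow(rec) == 0) {
    # zero-data fit: two pseudo-subjects with empty cells, so the sampler
    # targets the prior (a Bayesian sanity mode, not an analysis path)
    empty <- lapply(CELLS, function(cl) {
      list(rt = numeric(0), correct = integer(0), ev = numeric(0),
           theta = numeric(0))
    })
    names(empty) <- CELLS
    return(list(dat = list(empty, empty), subjects = 1:2, n_trials = 0L,
                fingerprint = "0:0:0"))
  }
  if (need_theta) {
    if (!"sfs_beta" %in% names(rec) || anyNA(rec$sfs_beta)) {
      bad <- if ("sfs_beta" %in% names(rec)) which(is.na(rec$sfs_beta)) else
        seq_len(nrow(rec))
      stop("neural betas missing on valid trials (e.g. rows ",
           paste(head(bad, 3), collapse = ", "), ")", call. = FALSE)
    }
  }
  subjects <- sort(unique(rec$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  key <- cell_key(rec)
  dat <- lapply(subjects, function(s) {
    out <- lapply(CELLS, function(cl) {
      i <- which(rec$subject_id == s & key == cl)
      if (length(i) < 2) {
        stop("subject ", s, " has fewer than 2 valid trials in cell ", cl,
             call. = FALSE)
      }
      list(rt = rec$rt_s[i], correct = as.integer(rec$correct[i]),
           ev = as.numeric(rec$evidence_level[i]),
           theta = if (need_theta) rec$sfs_beta[i] else numeric(0))
    })
    names(out) <- CELLS
    out
  })
  list(dat = dat, subjects = subjects, n_trials = nrow(rec),
       fingerprint = sprintf("%d:%.6f:%d", nrow(rec), sum(rec$rt_s),
                             sum(rec$correct)))
}

# --- likelihood -------------------------------------------------------------

cell_ll <- function(d, kappa, alpha, tau, ga, gd, w, floor_a) {
  if (ga == 0 && gd == 0) {
    c(cpp_loglik_cell(d$rt, d$correct, d$ev, kappa, alpha, tau, w), 0)
  } else {
    cpp_loglik_cell_neural(d$rt, d$correct, d$ev, d$theta, kappa, alpha,
                           tau, ga, gd, w, floor_a)
  }
}

#' Trial-table log-likelihood under a diffusion parameter assignment
#'
#' Sums the Wiener first-passage log density over all valid trials, with
#' per-trial drift `kappa * evidence_level` signed by accuracy coding (the
#' upper boundary is the correct response). Returns `-Inf`, with the first
#' offending trial index attached as an attribute, when any RT is at or
#' below the non-decision time.
#'
#' @param records trial table (valid trials are used).
#' @param params either a list with scalars `kappa`, `alpha`, `tau` applied
#'   to every trial, or a data.frame with columns `subject_id`, `task`,
#'   `phase`, `kappa`, `alpha`, `tau` giving one row per cell.
#' @param w start fraction (default 0.5).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(records, params, w = 0.5) {
  rec <- records[records$valid == 1, ]
  if (is.data.frame(params)) {
    key <- paste(rec$subject_id, rec$task, rec$phase)
    pk <- paste(params$subject_id, params$task, params$phase)
    idx <- match(key, pk)
    if (anyNA(idx)) stop("params lack a cell for some trials", call. = FALSE)
    kap <- params$kappa[idx]; alp <- params$alpha[idx]; tau <- params$tau[idx]
  } else {
    for (nm in c("kappa", "alpha", "tau")) {
      assert_scalar_num(params[[nm]], nm)
    }
    kap <- rep(params$kappa, nrow(rec))
    alp <- rep(params$alpha, nrow(rec))
    tau <- rep(params$tau, nrow(rec))
  }
  bad <- which(rec$rt_s <= tau)
  if (length(bad)) {
    out <- -Inf
    attr(out, "offending_trial") <- bad[1]
    return(out)
  }
  ll <- cpp_fpt_log_density(rec$rt_s, as.integer(rec$correct),
                            kap * rec$evidence_level, alp, tau, w)
  sum(ll)
}

# --- the sampler ------------------------------------------------------------

ltnorm <- function(x, mu, sg, lb) {
  if (!is.na(lb) && x < lb) return(-Inf)
  dnorm(x, mu, sg, log = TRUE)
}

# exact log target for hyper (mu, sg) of a possibly-truncated normal level
hyper_logf <- function(xs, mu, sg, lb, prior_mu, prior_sd, mu_lb) {
  if (sg <= 0) return(-Inf)
  if (!is.na(mu_lb) && mu < mu_lb) return(-Inf)
  ll <- sum(dnorm(xs, mu, sg, log = TRUE))
  if (!is.na(lb)) {  # renormalise for truncation at lb
    ll <- ll - length(xs) * pnorm(lb, mu, sg, lower.tail = FALSE,
                                  log.p = TRUE)
  }
  ll + dnorm(mu, prior_mu, prior_sd, log = TRUE)
}

fit_ddm_engine <- function(records, model = "baseline",
                           cfg = mcmc_config(), priors = hddm_priors(),
                           seed = 1, w = 0.5, floor_a = 0.05,
                           rhat_warn = TRUE) {
  mspec <- if (inherits(model, "neural_model_spec")) model else
    neural_model_spec(model)
  neural <- mspec$model_id != "baseline"
  prep <- prepare_cells(records, need_theta = neural)
  dat <- prep$dat
  S <- length(prep$subjects)
  has_ga <- "boundary" %in% mspec$modulates
  has_gd <- "drift" %in% mspec$modulates
  shared <- identical(mspec$gamma_structure, "shared")

  # parameter naming
  core_names <- c(
    as.vector(outer(seq_len(S), CELLS,
                    function(s, cl) sprintf("kappa[%d,%s]", s, cl))),
    as.vector(outer(seq_len(S), CELLS,
                    function(s, cl) sprintf("alpha[%d,%s]", s, cl))),
    as.vector(outer(seq_len(S), CELLS,
                    function(s, cl) sprintf("tau[%d,%s]", s, cl))))
  hyper_names <- c(sprintf("mu_kappa[%s]", CELLS),
                   sprintf("sigma_kappa[%s]", CELLS),
                   sprintf("mu_alpha[%s]", CELLS),
                   sprintf("sigma_alpha[%s]", CELLS),
                   sprintf("mu_tau[%s]", CELLS),
                   sprintf("sigma_tau[%s]", CELLS))
  gamma_names <- character(0)
  if (shared) {
    gamma_names <- sprintf("gamma[%d]", seq_len(S))
  } else {
    if (has_ga) gamma_names <- c(gamma_names,
                                 sprintf("gamma_a[%d]", seq_len(S)))
    if (has_gd) gamma_names <- c(gamma_names,
                                 sprintf("gamma_d[%d]", seq_len(S)))
  }
  par_names <- c(core_names, hyper_names, gamma_names)
  nk <- retained_draws(cfg)
  seeds <- config_seeds(cfg, seed)
  draws <- array(NA_real_, dim = c(cfg$n_chains, nk, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  clip_tot <- 0; clip_n <- 0

  lb <- c(kappa = NA, alpha = 0, tau = 0)  # truncation per parameter type
  prior_mu <- list(kappa = priors$mu_kappa, alpha = priors$mu_alpha,
                   tau = priors$mu_tau)

  for (ch in seq_len(cfg$n_chains)) {
    with_seed(seeds[ch], {
      # --- initial state, jittered per chain
      K <- matrix(0.3 * exp(rnorm(S * 4, 0, 0.15)), S, 4)
      A <- matrix(1.3 * exp(rnorm(S * 4, 0, 0.1)), S, 4)
      Tau <- matrix(NA_real_, S, 4)
      for (s in seq_len(S)) for (ci in 1:4) {
        Tau[s, ci] <- if (length(dat[[s]][[ci]]$rt) == 0) 0.3 else
          min(dat[[s]][[ci]]$rt) * runif(1, 0.5, 0.8)
      }
      Ga <- rep(0, S); Gd <- rep(0, S)
      if (has_ga || has_gd) {
        g0 <- rnorm(S, 0, 0.05)
        if (shared) { Ga <- g0; Gd <- g0 }
        else { if (has_ga) Ga <- g0; if (has_gd) Gd <- rnorm(S, 0, 0.05) }
      }
      MU <- matrix(c(rep(0.3, 4), rep(1.3, 4), rep(0.4, 4)), 3, 4,
                   byrow = TRUE,
                   dimnames = list(c("kappa", "alpha", "tau"), CELLS))
      SG <- matrix(c(rep(0.15, 4), rep(0.25, 4), rep(0.08, 4)), 3, 4,
                   byrow = TRUE, dimnames = dimnames(MU))

      # cached cell log-likelihoods and clip counts
      LL <- matrix(0, S, 4); NC <- matrix(0, S, 4)
      for (s in seq_len(S)) for (ci in 1:4) {
        r <- cell_ll(dat[[s]][[ci]], K[s, ci], A[s, ci], Tau[s, ci],
                     if (has_ga) Ga[s] else 0, if (has_gd) Gd[s] else 0,
                     w, floor_a)
        LL[s, ci] <- r[1]; NC[s, ci] <- r[2]
      }
      if (any(!is.finite(LL))) {
        # shrink tau until the likelihood is finite at the start
        for (s in seq_len(S)) for (ci in 1:4) {
          while (!is.finite(LL[s, ci]) && Tau[s, ci] > 1e-4) {
            Tau[s, ci] <- Tau[s, ci] * 0.5
            r <- cell_ll(dat[[s]][[ci]], K[s, ci], A[s, ci], Tau[s, ci],
                         if (has_ga) Ga[s] else 0,
                         if (has_gd) Gd[s] else 0, w, floor_a)
            LL[s, ci] <- r[1]; NC[s, ci] <- r[2]
          }
        }
      }

      LS <- array(log(c(0.08, 0.12, 0.03)), dim = c(3, S, 4))  # step sizes
      ls_g <- matrix(log(0.05), 2, S)
      ls_shift <- matrix(log(0.3), 3, 4)  # joint translation moves
      shift_period <- if (prep$n_trials == 0) 1L else 4L

      total <- cfg$burn_in + cfg$draws
      kept <- 0L
      for (it in seq_len(total)) {
        adapt <- it <= cfg$burn_in
        gain <- min(0.1, 1 / sqrt(it))
        for (s in seq_len(S)) {
          ga_s <- if (has_ga) Ga[s] else 0
          gd_s <- if (has_gd) Gd[s] else 0
          for (ci in 1:4) {
            cur <- c(K[s, ci], A[s, ci], Tau[s, ci])
            for (j in 1:3) {
              prop <- cur
              prop[j] <- cur[j] + exp(LS[j, s, ci]) * rnorm(1)
              type <- c("kappa", "alpha", "tau")[j]
              lp_new <- ltnorm(prop[j], MU[type, ci], SG[type, ci], lb[type])
              acc <- FALSE
              if (is.finite(lp_new)) {
                r <- cell_ll(dat[[s]][[ci]], prop[1], prop[2], prop[3],
                             ga_s, gd_s, w, floor_a)
                lp_old <- ltnorm(cur[j], MU[type, ci], SG[type, ci],
                                 lb[type])
                if (is.finite(r[1]) &&
                    log(runif(1)) < r[1] + lp_new - LL[s, ci] - lp_old) {
                  acc <- TRUE
                  cur <- prop
                  LL[s, ci] <- r[1]; NC[s, ci] <- r[2]
                }
              }
              if (adapt) {
                LS[j, s, ci] <- LS[j, s, ci] +
                  (as.numeric(acc) - 0.44) * gain
              }
            }
            K[s, ci] <- cur[1]; A[s, ci] <- cur[2]; Tau[s, ci] <- cur[3]
          }
          # subject-level coupling scales (span all four cells)
          if (has_ga || has_gd) {
            which_g <- if (shared) "s" else c(if (has_ga) "a",
                                              if (has_gd) "d")
            for (gk in which_g) {
              gi <- if (gk == "d") 2L else 1L
              old_g <- if (gk == "d") Gd[s] else Ga[s]
              new_g <- old_g + exp(ls_g[gi, s]) * rnorm(1)
              ga_n <- if (gk %in% c("a", "s")) new_g else
                (if (has_ga) Ga[s] else 0)
              gd_n <- if (gk %in% c("d", "s")) new_g else
                (if (has_gd) Gd[s] else 0)
              llr <- matrix(0, 2, 4); ok <- TRUE
              for (ci in 1:4) {
                r <- cell_ll(dat[[s]][[ci]], K[s, ci], A[s, ci],
                             Tau[s, ci], ga_n, gd_n, w, floor_a)
                if (!is.finite(r[1])) { ok <- FALSE; break }
                llr[, ci] <- r
              }
              lp_new <- dnorm(new_g, priors$gamma_prior[1],
                              priors$gamma_prior[2], log = TRUE)
              lp_old <- dnorm(old_g, priors$gamma_prior[1],
                              priors$gamma_prior[2], log = TRUE)
              acc <- FALSE
              if (ok && log(runif(1)) <
                    sum(llr[1, ]) + lp_new - sum(LL[s, ]) - lp_old) {
                acc <- TRUE
                if (gk %in% c("a", "s")) Ga[s] <- new_g
                if (gk %in% c("d", "s")) Gd[s] <- new_g
                LL[s, ] <- llr[1, ]; NC[s, ] <- llr[2, ]
              }
              if (adapt) {
                ls_g[gi, s] <- ls_g[gi, s] + (as.numeric(acc) - 0.44) * gain
              }
            }
          }
        }
        # --- joint translation of (group mean, all subject values) per
        # cell; de-funnels the hierarchy (essential when data are sparse)
        if (it %% shift_period == 0L) {
          for (tj in 1:3) {
            type <- c("kappa", "alpha", "tau")[tj]
            X <- switch(type, kappa = K, alpha = A, tau = Tau)
            pm <- prior_mu[[type]]
            mu_lb <- if (type == "kappa") NA_real_ else 0
            for (ci in 1:4) {
              delta <- exp(ls_shift[tj, ci]) * rnorm(1)
              mu_new <- MU[type, ci] + delta
              x_new <- X[, ci] + delta
              ok <- (is.na(mu_lb) || mu_new > mu_lb) &&
                (is.na(lb[type]) || all(x_new > lb[type]))
              acc <- FALSE
              if (ok) {
                ll_new <- numeric(S); nc_new <- numeric(S); fin <- TRUE
                for (s in seq_len(S)) {
                  Kv <- K[s, ci]; Av <- A[s, ci]; Tv <- Tau[s, ci]
                  if (type == "kappa") Kv <- x_new[s]
                  if (type == "alpha") Av <- x_new[s]
                  if (type == "tau") Tv <- x_new[s]
                  r <- cell_ll(dat[[s]][[ci]], Kv, Av, Tv,
                               if (has_ga) Ga[s] else 0,
                               if (has_gd) Gd[s] else 0, w, floor_a)
                  if (!is.finite(r[1])) { fin <- FALSE; break }
                  ll_new[s] <- r[1]; nc_new[s] <- r[2]
                }
                if (fin) {
                  lr <- sum(ll_new) - sum(LL[, ci]) +
                    dnorm(mu_new, pm[1], pm[2], log = TRUE) -
                    dnorm(MU[type, ci], pm[1], pm[2], log = TRUE)
                  if (!is.na(lb[type])) {  # truncation normaliser moves
                    lr <- lr - S * pnorm(lb[type], mu_new, SG[type, ci],
                                         lower.tail = FALSE, log.p = TRUE) +
                      S * pnorm(lb[type], MU[type, ci], SG[type, ci],
                                lower.tail = FALSE, log.p = TRUE)
                  }
                  if (log(runif(1)) < lr) {
                    acc <- TRUE
                    MU[type, ci] <- mu_new
                    if (type == "kappa") K[, ci] <- x_new
                    if (type == "alpha") A[, ci] <- x_new
                    if (type == "tau") Tau[, ci] <- x_new
                    LL[, ci] <- ll_new; NC[, ci] <- nc_new
                  }
                }
              }
              if (adapt) {
                ls_shift[tj, ci] <- ls_shift[tj, ci] +
                  (as.numeric(acc) - 0.25) * gain
              }
            }
          }
        }
        # --- hyperparameters: slice updates on the exact conditional
        for (type in c("kappa", "alpha", "tau")) {
          X <- switch(type, kappa = K, alpha = A, tau = Tau)
          pm <- prior_mu[[type]]
          mu_lb <- if (type == "kappa") NA_real_ else 0
          for (ci in 1:4) {
            xs <- X[, ci]
            MU[type, ci] <- slice_sample1(
              MU[type, ci],
              function(m) hyper_logf(xs, m, SG[type, ci], lb[type],
                                     pm[1], pm[2], mu_lb),
              w = 0.3, lower = if (is.na(mu_lb)) -Inf else 0)
            SG[type, ci] <- slice_sample1(
              SG[type, ci],
              function(sg) hyper_logf(xs, MU[type, ci], sg, lb[type],
                                      pm[1], pm[2], mu_lb) +
                dnorm(sg, 0, priors$sigma_scale, log = TRUE),
              w = 0.2, lower = 1e-6)
          }
        }
        # --- storage
        if (!adapt && (it - cfg$burn_in) %% cfg$thin == 0) {
          kept <- kept + 1L
          gvals <- if (shared) Ga else
            c(if (has_ga) Ga, if (has_gd) Gd)
          draws[ch, kept, ] <- c(
            as.vector(K), as.vector(A), as.vector(Tau),
            MU["kappa", ], SG["kappa", ], MU["alpha", ], SG["alpha", ],
            MU["tau", ], SG["tau", ], gvals)
          clip_tot <- clip_tot + sum(NC)
          clip_n <- clip_n + prep$n_trials
        }
      }
    })
  }

  rhat <- if (cfg$n_chains >= 2 && nk >= 10) gelman_rubin(draws) else NULL
  converged <- if (is.null(rhat)) NA else all(rhat < attr(rhat, "threshold"))
  if (isFALSE(converged) && rhat_warn) {
    bad <- names(rhat)[rhat >= 1.05]
    warning("chains not converged: R-hat >= 1.05 for ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5),
            call. = FALSE)
  }
  structure(list(draws = structure(draws, class = "posterior_draws",
                                   config = cfg, seeds = seeds),
                 model = mspec, cells = CELLS, subjects = prep$subjects,
                 config = cfg, priors = priors, seeds = seeds,
                 w = w, floor_a = floor_a,
                 rhat = rhat, converged = converged,
                 clip_frac = if (clip_n > 0) clip_tot / clip_n else 0,
                 n_trials = prep$n_trials,
                 data_fingerprint = prep$fingerprint),
            class = "hddm_fit")
}

#' Fit the hierarchical Bayesian drift-diffusion model
#'
#' Subject-by-cell diffusion parameters (drift scale kappa, boundary alpha,
#' non-decision time tau; one cell per task x stimulation phase) with
#' cell-level group means and scales, estimated by adaptive
#' Metropolis-within-Gibbs: random-walk updates for subject parameters with
#' Robbins-Monro step adaptation during burn-in, slice updates for the
#' hyperparameters on their exact conditionals (including truncation
#' normalisers). Chains are run sequentially with derived per-chain seeds;
#' retained draws honour the thinning arithmetic exactly. A convergence
#' warning (never silence) is raised when any rank-normalised split R-hat
#' reaches 1.05.
#'
#' @param records trial table (only `valid == 1` rows enter the likelihood).
#' @param cfg an [mcmc_config()].
#' @param priors from [hddm_priors()].
#' @param seed base integer seed.
#' @param w fixed start fraction (0.5, unbiased).
#' @return An `hddm_fit` object: `draws` (chain x draw x parameter array),
#'   `rhat`, `converged`, seeds, config and data fingerprint.
#' @export
fit_hddm <- function(records, cfg = mcmc_config(), priors = hddm_priors(),
                     seed = 1, w = 0.5) {
  fit_ddm_engine(records, "baseline", cfg, priors, seed, w)
}

#' Fit a neural-covariate-modulated diffusion model
#'
#' Adds subject-level coupling scales gamma between the z-scored trialwise
#' neural covariate and the boundary and/or drift (see
#' [neural_model_spec()]), each under a fixed group prior N(0, 0.5). The
#' effective boundary is floored at `floor_a`, with the fraction of floored
#' trials reported as `clip_frac`.
#'
#' @inheritParams fit_hddm
#' @param model_id 1 (boundary), 2 (drift), 3 (both, separate gammas) or
#'   4 (both, shared gamma); `"baseline"` reduces to [fit_hddm()].
#' @param floor_a positive floor for the effective boundary.
#' @return An `hddm_fit` object.
#' @export
fit_neural_ddm <- function(records, model_id, cfg = mcmc_config(),
                           priors = hddm_priors(), seed = 1, w = 0.5,
                           floor_a = 0.05) {
  fit_ddm_engine(records, neural_model_spec(model_id), cfg, priors, seed,
                 w, floor_a)
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM fit (model %s): %d subjects, %d trials, %d chains x %d draws\n",
    x$model$model_id, length(x$subjects), x$n_trials, x$config$n_chains,
    dim(x$draws)[2]))
  if (!is.null(x$rhat)) {
    cat(sprintf("  max R-hat = %.3f (%s)\n", max(x$rhat),
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  if (x$model$model_id != "baseline") {
    cat(sprintf("  boundary-floor clip fraction = %.4f\n", x$clip_frac))
  }
  invisible(x)
}

#' Extract pooled posterior draws for named parameters
#'
#' @param fit an `hddm_fit`.
#' @param pars parameter names (exact) or a regular expression when
#'   `regex = TRUE`.
#' @param regex interpret `pars` as a regular expression?
#' @return Matrix of draws (chains stacked) x selected parameters.
#' @export
extract_draws <- function(fit, pars, regex = FALSE) {
  draws <- if (inherits(fit, "hddm_fit")) fit$draws else fit
  nm <- dimnames(draws)[[3]]
  idx <- if (regex) grep(pars, nm) else match(pars, nm)
  if (anyNA(idx) || length(idx) == 0) {
    stop("unknown parameter(s): ",
         paste(pars[is.na(match(pars, nm))], collapse = ", "),
         call. = FALSE)
  }
  out <- apply(draws[, , idx, drop = FALSE], 3, as.vector)
  colnames(out) <- nm[idx]
  out
}

#' Posterior difference-in-differences of a group-level diffusion parameter
#'
#' Drawwise `[post - pre]_perceptual - [post - pre]_value` contrast on the
#' group means of `kappa`, `alpha` or `tau`, summarised by its posterior
#' tail probability in the given direction.
#'
#' @param fit an `hddm_fit`.
#' @param param `"alpha"`, `"kappa"` or `"tau"`.
#' @param direction hypothesised sign, passed to [posterior_p()].
#' @return A `posterior_test` with the effect draws attached as
#'   `$effect_draws`.
#' @export
hddm_did <- function(fit, param = c("alpha", "kappa", "tau"),
                     direction = "below_zero") {
  param <- match.arg(param)
  nm <- sprintf("mu_%s[%s]", param, CELLS)
  d <- extract_draws(fit, nm)
  eff <- posterior_did(list(
    perceptual.pre = d[, nm[1]], perceptual.post = d[, nm[2]],
    value.pre = d[, nm[3]], value.post = d[, nm[4]]))
  out <- posterior_p(eff, direction)
  out$effect <- sprintf("%s_did", param)
  out$effect_draws <- eff
  out
}

# subject-by-cell posterior mean parameter table from a fit
posterior_mean_cells <- function(fit) {
  S <- length(fit$subjects)
  grid <- expand.grid(s = seq_len(S), cell = CELLS,
                      stringsAsFactors = FALSE)
  nm_k <- sprintf("kappa[%d,%s]", grid$s, grid$cell)
  nm_a <- sprintf("alpha[%d,%s]", grid$s, grid$cell)
  nm_t <- sprintf("tau[%d,%s]", grid$s, grid$cell)
  d <- fit$draws
  cm <- apply(d, 3, mean)
  tp <- strsplit(grid$cell, ".", fixed = TRUE)
  data.frame(subject_id = fit$subjects[grid$s],
             task = vapply(tp, `[`, "", 1),
             phase = vapply(tp, `[`, "", 2),
             kappa = unname(cm[nm_k]), alpha = unname(cm[nm_a]),
             tau = unname(cm[nm_t]), stringsAsFactors = FALSE)
}
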