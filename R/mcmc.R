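#' MCMC configuration
#'
#' Chain bookkeeping for the hierarchical samplers. Retained draws per chain
#' are exactly `draws / thin`, so `draws` must be a multiple of `thin`.
#'
#' @param n_chains number of chains (default 3).
#' @param burn_in adaptation/warm-up sweeps discarded per chain.
#' @param draws post-burn-in sweeps per chain.
#' @param thin thinning factor: every `thin`-th sweep is stored.
#' @param seeds optional integer seed per chain (length `n_chains`).
#' @return An object of class `mcmc_config`.
#' @examples
#' mcmc_config()                   # desk-scale default
#' paper_scale_config()            # 100,000/100,000, thin 100 -> 1,000 kept
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 2000, draws = 5000,
                        thin = 5, seeds = NULL) {
  assert_scalar_num(n_chains, "n_chains", lower = 1)
  assert_scalar_num(burn_in, "burn_in", lower = 0)
  assert_scalar_num(draws, "draws", lower = 1)
  assert_scalar_num(thin, "thin", lower = 1)
  if (draws %% thin != 0) {
    stop("`draws` must be an exact multiple of `thin` so the retained-draw ",
         "count is exact", call. = FALSE)
  }
  if (!is.null(seeds) && length(seeds) != n_chains) {
    stop("`seeds` must have one entry per chain", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), draws = as.integer(draws),
                 thin = as.integer(thin), seeds = seeds),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
paper_scale_config <- function(n_chains = 3, seeds = NULL) {
  mcmc_config(n_chains = n_chains, burn_in = 100000, draws = 100000,
              thin = 100, seeds = seeds)
}

#' @rdname mcmc_config
#' @param cfg an `mcmc_config`.
#' @export
retained_draws <- function(cfg) {
  stopifnot(inherits(cfg, "mcmc_config"))
  cfg$draws %/% cfg$thin
}

config_seeds <- function(cfg, base_seed) {
  cfg$seeds %||% vapply(seq_len(cfg$n_chains), function(k) {
    derive_seed(base_seed, paste0("chain", k))
  }, integer(1))
}

#' Adaptive random-walk Metropolis sampler for an arbitrary log target
#'
#' One-at-a-time Gaussian random-walk Metropolis with Robbins-Monro scale
#' adaptation during burn-in (target acceptance 0.44 per coordinate).
#' Used for toy targets and as the building block of the hierarchical
#' samplers; storage honours the config's thinning arithmetic exactly.
#'
#' @param log_target function taking a parameter vector, returning a scalar
#'   log density (may be `-Inf` outside the support).
#' @param init named numeric vector of starting values.
#' @param cfg an [mcmc_config()].
#' @param seed base integer seed (per-chain seeds derived from it unless the
#'   config carries explicit seeds).
#' @param step_init initial proposal standard deviation.
#' @return A `posterior_draws` object: a 3-d array
#'   (chain x retained draw x parameter) with attributes recording the
#'   config and seeds.
#' @export
rw_mcmc <- function(log_target, init, cfg = mcmc_config(), seed = 1,
                    step_init = 0.5) {
  p <- length(init)
  nk <- retained_draws(cfg)
  seeds <- config_seeds(cfg, seed)
  draws <- array(NA_real_, dim = c(cfg$n_chains, nk, p),
                 dimnames = list(NULL, NULL,
                                 names(init) %||% paste0("par", seq_len(p))))
  for (ch in seq_len(cfg$n_chains)) {
    with_seed(seeds[ch], {
      x <- init + rnorm(p, 0, 0.1 * step_init)  # overdispersed start
      lp <- log_target(x)
      if (!is.finite(lp)) { x <- init; lp <- log_target(x) }
      ls <- rep(log(step_init), p)
      total <- cfg$burn_in + cfg$draws
      kept <- 0L
      for (it in seq_len(total)) {
        for (j in seq_len(p)) {
          xp <- x
          xp[j] <- x[j] + exp(ls[j]) * rnorm(1)
          lpp <- log_target(xp)
          acc <- is.finite(lpp) && log(runif(1)) < lpp - lp
          if (acc) { x <- xp; lp <- lpp }
          if (it <= cfg$burn_in) {
            ls[j] <- ls[j] + (as.numeric(acc) - 0.44) * min(0.1, 1 / sqrt(it))
          }
        }
        if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
          kept <- kept + 1L
          draws[ch, kept, ] <- x
        }
      }
    })
  }
  structure(draws, class = "posterior_draws", config = cfg, seeds = seeds)
}

# univariate slice sampler (stepping out + shrinkage); logf need not be
# normalised. lower/upper bound the support.
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside support")
  y <- f0 + log(runif(1))
  u <- runif(1)
  L <- max(lower, x0 - u * w)
  R <- min(upper, L + w)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > y) { L <- max(lower, L - w); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > y) { R <- min(upper, R + w); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

#' Rank-normalised split Gelman-Rubin diagnostic
#'
#' Each chain is split in half, all draws are rank-normalised jointly, and
#' the classic between/within variance ratio is computed on the normalised
#' ranks. Values near 1 indicate convergence; the conventional bound used
#' throughout the package is 1.05.
#'
#' @param draws a `posterior_draws` array (chain x draw x parameter) or a
#'   fit object carrying one, or a matrix (chain x draw) for one parameter.
#' @return Named vector of R-hat values with attribute `threshold` (1.05)
#'   and `converged` (logical vector).
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "hddm_fit")) draws <- draws$draws
  if (is.matrix(draws)) draws <- array(draws, dim = c(dim(draws), 1))
  stopifnot(length(dim(draws)) == 3)
  m <- dim(draws)[1]
  if (m < 2) stop("Gelman-Rubin diagnostic requires at least 2 chains",
                  call. = FALSE)
  if (dim(draws)[2] < 10) stop("need at least 10 draws per chain",
                               call. = FALSE)
  rhat <- apply(draws, 3, function(x) split_rhat(x))
  names(rhat) <- dimnames(draws)[[3]]
  attr(rhat, "threshold") <- 1.05
  attr(rhat, "converged") <- rhat < 1.05
  rhat
}

# x: chains x draws matrix for one parameter
split_rhat <- function(x) {
  n <- ncol(x)
  half <- n %/% 2
  sub <- rbind(x[, seq_len(half), drop = FALSE],
               x[, (n - half + 1):n, drop = FALSE])
  if (max(sub) - min(sub) < 1e-300) return(1)  # constant parameter
  r <- matrix(rank(sub, ties.method = "average"), nrow = nrow(sub))
  z <- qnorm((r - 3 / 8) / (length(sub) + 1 / 4))
  m <- nrow(z); nn <- ncol(z)
  W <- mean(apply(z, 1, var))
  B <- nn * var(rowMeans(z))
  vhat <- (nn - 1) / nn * W + B / nn
  sqrt(vhat / W)
}

#' Posterior tail probability of a directed effect
#'
#' Bayesian "p-value": the posterior mass on the side of zero opposite to
#' the hypothesised direction, floored at `1 / (N + 1)` so a finite sample
#' never reports exactly zero.
#'
#' @param effect_draws numeric vector of posterior draws of the effect
#'   (at least 100).
#' @param direction `"below_zero"` (hypothesis: effect < 0) or
#'   `"above_zero"`.
#' @return A `posterior_test` list: `p_mcmc`, `direction`, posterior `mean`
#'   and central 95% interval.
#' @export
posterior_p <- function(effect_draws, direction = c("below_zero",
                                                    "above_zero")) {
  direction <- match.arg(direction)
  if (length(effect_draws) == 0) stop("no draws supplied", call. = FALSE)
  if (length(effect_draws) < 100) {
    stop("need at least 100 draws for a stable tail probability",
         call. = FALSE)
  }
  n <- length(effect_draws)
  tail_p <- if (direction == "below_zero") mean(effect_draws >= 0)
            else mean(effect_draws <= 0)
  structure(list(p_mcmc = max(tail_p, 1 / (n + 1)),
                 direction = direction,
                 mean = mean(effect_draws),
                 ci95 = unname(quantile(effect_draws, c(0.025, 0.975))),
                 n_draws = n),
            class = "posterior_test")
}

#' @export
print.posterior_test <- function(x, ...) {
  cat(sprintf(
    "posterior effect: mean %.4f, 95%% CI [%.4f, %.4f], p_mcmc(%s) = %.4f\n",
    x$mean, x$ci95[1], x$ci95[2], x$direction, x$p_mcmc))
  invisible(x)
}

#' Posterior difference-in-differences across task x phase cells
#'
#' Drawwise causal contrast
#' `[post - pre]_perceptual - [post - pre]_value` over four matched posterior
#' sample sequences.
#'
#' @param cell_draws named list with components `perceptual.pre`,
#'   `perceptual.post`, `value.pre`, `value.post`, equal-length numeric
#'   vectors matched by draw index.
#' @return Numeric vector of effect draws.
#' @export
posterior_did <- function(cell_draws) {
  need <- c("perceptual.pre", "perceptual.post", "value.pre", "value.post")
  if (!all(need %in% names(cell_draws))) {
    stop("cell_draws must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  len <- vapply(cell_draws[need], length, integer(1))
  if (length(unique(len)) != 1) {
    stop("cell draw sequences have mismatched lengths", call. = FALSE)
  }
  (cell_draws$perceptual.post - cell_draws$perceptual.pre) -
    (cell_draws$value.post - cell_draws$value.pre)
}
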