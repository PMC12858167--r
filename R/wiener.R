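#' Wiener diffusion parameters
#'
#' Bundles the parameters of a one-dimensional Wiener accumulation process
#' between two absorbing boundaries: drift rate `delta` (evidence units per
#' second), boundary separation `alpha` (evidence units), non-decision time
#' `tau` (seconds), relative starting point `beta_start` (fraction of `alpha`,
#' 0.5 = unbiased) and diffusion coefficient `sigma` (fixed at 1 by
#' convention; the triplet delta/alpha/sigma is only identified up to a common
#' scale).
#'
#' @param delta drift rate.
#' @param alpha boundary separation, must be positive.
#' @param tau non-decision time in seconds, must be non-negative.
#' @param beta_start starting point as a fraction of `alpha`, in (0, 1).
#' @param sigma diffusion coefficient, must be positive.
#' @return An object of class `wiener_params`.
#' @examples
#' p <- wiener_params(delta = 1, alpha = 2, tau = 0.3)
#' choice_probability(p)
#' @export
wiener_params <- function(delta, alpha, tau = 0, beta_start = 0.5,
                          sigma = 1) {
  assert_scalar_num(delta, "delta")
  assert_scalar_num(alpha, "alpha", lower = 0, strict_lower = TRUE)
  assert_scalar_num(tau, "tau", lower = 0)
  assert_scalar_num(beta_start, "beta_start", lower = 0, upper = 1,
                    strict_lower = TRUE)
  if (beta_start >= 1) stop("`beta_start` must be < 1", call. = FALSE)
  assert_scalar_num(sigma, "sigma", lower = 0, strict_lower = TRUE)
  structure(list(delta = delta, alpha = alpha, tau = tau,
                 beta_start = beta_start, sigma = sigma),
            class = "wiener_params")
}

#' @export
print.wiener_params <- function(x, ...) {
  cat(sprintf(
    "Wiener process: delta = %g, alpha = %g, tau = %g s, beta = %g, sigma = %g\n",
    x$delta, x$alpha, x$tau, x$beta_start, x$sigma))
  invisible(x)
}

# reduce to the sigma = 1 convention used by the C++ kernels
std_params <- function(p) {
  list(v = p$delta / p$sigma, a = p$alpha / p$sigma, w = p$beta_start,
       tau = p$tau)
}

#' First-passage-time density of the Wiener process
#'
#' Defective density of absorption at the given boundary at time `t`
#' (including non-decision time: the decision-time argument of the underlying
#' series is `t - tau`). The two branches jointly integrate to 1 over
#' t in (tau, Inf). Computed with complementary small-time/large-time series
#' expansions and an adaptive truncation rule.
#'
#' @param t vector of response times in seconds.
#' @param boundary `"upper"` or `"lower"`.
#' @param p a [wiener_params()] object.
#' @param log return the log density?
#' @return Numeric vector of (log) densities; 0 (or `-Inf`) for `t <= tau`.
#' @export
fpt_density <- function(t, boundary = c("upper", "lower"), p, log = FALSE) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "wiener_params"))
  s <- std_params(p)
  ld <- cpp_fpt_log_density(as.numeric(t), as.integer(boundary == "upper"),
                            s$v, s$a, s$tau, s$w)
  # time rescaling for sigma != 1: t' = t in the standardized process only
  # when sigma = 1; general case uses (delta/sigma, alpha/sigma) with the
  # same clock, which is exact because variance sigma^2 per unit time.
  if (log) ld else exp(ld)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form absorption probability of drifted Brownian motion on
#' `(0, alpha)` started at `beta_start * alpha`. Used as the analytic oracle
#' for the trial simulator.
#'
#' @inheritParams fpt_density
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(p) {
  stopifnot(inherits(p, "wiener_params"))
  s2 <- p$sigma^2
  z <- p$beta_start * p$alpha
  arg <- 2 * p$delta * p$alpha / s2
  if (abs(arg) < 1e-10) return(p$beta_start)  # removable singularity at 0
  expm1(-2 * p$delta * z / s2) / expm1(-arg)
}

#' Mean first-passage (decision) time of the Wiener process
#'
#' Unconditional mean time to absorption at either boundary, excluding
#' non-decision time. Closed form for drifted Brownian motion; serves as an
#' independent oracle for the path simulator.
#'
#' @inheritParams fpt_density
#' @return Mean decision time in seconds.
#' @export
mean_fpt <- function(p) {
  stopifnot(inherits(p, "wiener_params"))
  s2 <- p$sigma^2
  z <- p$beta_start * p$alpha
  if (abs(p$delta) * p$alpha / s2 < 1e-8) {
    return(z * (p$alpha - z) / s2)
  }
  (p$alpha * choice_probability(p) - z) / p$delta
}

#' Simulate first-passage trials by Euler-Maruyama integration
#'
#' Brute-force path simulation of the accumulation process; deliberately
#' simple so it can serve as an auditable oracle for the closed-form density
#' and choice probability.
#'
#' @param n number of trials.
#' @param p a [wiener_params()] object, or a list of per-trial numeric vectors
#'   `delta`, `alpha`, `tau` (recycled) with optional `beta_start`, `sigma`.
#' @param dt integration step in seconds (1e-4 recommended).
#' @param t_max hard cap on decision time; unabsorbed paths are returned as
#'   censored with `NA` outcome.
#' @param seed integer seed for the simulator's own RNG stream.
#' @param boundary_correction apply the continuity correction for the
#'   discrete-time boundary overshoot (boundaries moved inward by
#'   `0.5826 * sigma * sqrt(dt)`)? Default `TRUE`; set `FALSE` for the
#'   plain Euler-Maruyama scheme, whose first-passage times carry a known
#'   O(sqrt(dt)) upward bias.
#' @return A data.frame with columns `rt_s` (tau + decision time), `upper`
#'   (logical, upper-boundary hit) and `censored`.
#' @export
simulate_trials <- function(n, p, dt = 1e-4, t_max = 60, seed = 1,
                            boundary_correction = TRUE) {
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  if (inherits(p, "wiener_params")) {
    s <- std_params(p)
    v <- s$v; a <- s$a; w <- s$w; tau <- s$tau
  } else {
    sig <- p$sigma %||% 1
    v <- p$delta / sig; a <- p$alpha / sig
    w <- p$beta_start %||% 0.5; tau <- p$tau %||% 0
  }
  out <- cpp_sim_trials(as.numeric(v), as.numeric(a), as.numeric(w),
                        as.numeric(tau), as.integer(n), dt, t_max,
                        as.numeric(seed),
                        if (boundary_correction) 0.5826 * sqrt(dt) else 0)
  data.frame(rt_s = out$rt, upper = out$upper == 1L,
             censored = out$censored == 1L)
}

#' Mean decision time from boundary and drift scale
#'
#' The hyperbolic-tangent expression for mean decision time,
#' `t_d = (alpha / kappa) * tanh(kappa * alpha)`, where `kappa` is the drift
#' scale per evidence unit. At `kappa = 0` the small-argument limit `alpha^2`
#' is returned. Note this convention differs from the classical mean
#' first-passage time from a midpoint start, `(alpha / (2 delta))
#' tanh(delta * alpha / 2)`, which is available as [mean_fpt()]; the
#' discrepancy between the two is a documented property of this measure, not
#' a bug (see the methods vignette).
#'
#' @param alpha boundary separation (positive).
#' @param kappa drift scale.
#' @return Mean decision time in seconds (vectorised).
#' @export
decision_time <- function(alpha, kappa) {
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)
  out <- ifelse(abs(kappa) < 1e-12,
                alpha^2,
                (alpha / kappa) * tanh(kappa * alpha))
  out
}

#' Accumulated evidence at decision
#'
#' Triangle-area proxy for the total evidence integrated before the boundary
#' is reached: decision time is the base and the boundary the height, giving
#' `alpha * t_d / 2`.
#'
#' @param alpha boundary separation (positive).
#' @param t_d decision time in seconds (non-negative).
#' @return Accumulated evidence (evidence x seconds), vectorised.
#' @export
accumulated_evidence <- function(alpha, t_d) {
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)
  if (any(t_d < 0)) stop("`t_d` must be non-negative", call. = FALSE)
  alpha * t_d / 2
}

#' Trialwise accumulated-evidence regressor
#'
#' Single-trial surrogate for accumulated evidence, `sqrt(rt / E)`: response
#' time is proportional to the boundary and the ordinal evidence level to the
#' drift rate, and the square root captures the concave growth of accumulated
#' evidence over time. Used as a parametric BOLD regressor.
#'
#' @param rt response times in seconds (positive).
#' @param evidence_level ordinal evidence levels (integers >= 1).
#' @return Numeric vector of regressor values.
#' @export
trialwise_ae <- function(rt, evidence_level) {
  if (any(rt <= 0)) stop("`rt` must be positive", call. = FALSE)
  if (any(evidence_level < 1)) {
    stop("`evidence_level` must be >= 1", call. = FALSE)
  }
  sqrt(rt / evidence_level)
}
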