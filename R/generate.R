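#' Generative ground truth for a synthetic stimulation experiment
#'
#' Draws per-subject diffusion parameters for each task and specifies the
#' stimulation effects applied to the post-phase cells. The default scenario
#' is the boundary-reduction account of the stimulation effect: the
#' perceptual-task boundary drops after stimulation while the value task's
#' non-decision time is untouched; the `"ndt"` scenario instead shortens the
#' value task's non-decision time; `"both"` combines them and `"null"`
#' applies no effect.
#'
#' @param n_subjects number of subjects.
#' @param scenario `"boundary"`, `"ndt"`, `"both"` or `"null"`.
#' @param seed integer seed for the subject-level parameter draws.
#' @param mu_kappa,mu_alpha,mu_tau group means of the drift scale
#'   (evidence^-1 s^-1), boundary (evidence units) and non-decision time (s).
#' @param sd_kappa,sd_alpha,sd_tau between-subject standard deviations.
#' @param d_alpha_pdm_post boundary change in post-stimulation perceptual
#'   cells (used by `"boundary"`/`"both"`).
#' @param d_tau_vdm_post non-decision-time change in post-stimulation value
#'   cells (used by `"ndt"`/`"both"`).
#' @param gamma trialwise neural coupling scale: the effective boundary of a
#'   trial is `alpha + gamma * theta` with `theta` the latent neural signal.
#' @param neural_noise_sd standard deviation of the measurement noise added
#'   to `theta` before z-scoring into the observed beta.
#' @param miss_rate probability that a trial is a non-response, in [0, 1).
#' @return An object of class `ground_truth` holding a long data.frame of
#'   per-subject x task x phase cell parameters plus the coupling settings.
#' @export
ground_truth <- function(n_subjects,
                         scenario = c("boundary", "ndt", "both", "null"),
                         seed = 1,
                         mu_kappa = 0.4, mu_alpha = 1.6, mu_tau = 0.35,
                         sd_kappa = 0.08, sd_alpha = 0.2, sd_tau = 0.05,
                         d_alpha_pdm_post = -0.35,
                         d_tau_vdm_post = -0.06,
                         gamma = 0, neural_noise_sd = 0.5,
                         miss_rate = 0.02) {
  scenario <- match.arg(scenario)
  assert_scalar_num(miss_rate, "miss_rate", lower = 0)
  if (miss_rate >= 1) stop("`miss_rate` must be < 1", call. = FALSE)
  d_alpha <- if (scenario %in% c("boundary", "both")) d_alpha_pdm_post else 0
  d_tau <- if (scenario %in% c("ndt", "both")) d_tau_vdm_post else 0
  cells <- with_seed(derive_seed(seed, "truth"), {
    base <- expand.grid(subject_id = seq_len(n_subjects),
                        task = c("perceptual", "value"),
                        stringsAsFactors = FALSE)
    base$kappa <- pmax(rnorm(nrow(base), mu_kappa, sd_kappa), 0.05)
    base$alpha <- pmax(rnorm(nrow(base), mu_alpha, sd_alpha), 0.3)
    base$tau <- pmax(rnorm(nrow(base), mu_tau, sd_tau), 0.05)
    pre <- transform(base, phase = "pre")
    post <- transform(base, phase = "post")
    post$alpha <- post$alpha + ifelse(post$task == "perceptual", d_alpha, 0)
    post$tau <- post$tau + ifelse(post$task == "value", d_tau, 0)
    rbind(pre, post)
  })
  if (any(cells$alpha <= 0) || any(cells$tau < 0)) {
    stop("ground truth invalid: a cell has alpha <= 0 or tau < 0 after ",
         "applying stimulation deltas", call. = FALSE)
  }
  structure(list(cells = cells, scenario = scenario,
                 d_alpha_pdm_post = d_alpha, d_tau_vdm_post = d_tau,
                 gamma = gamma, neural_noise_sd = neural_noise_sd,
                 miss_rate = miss_rate,
                 group_means = c(kappa = mu_kappa, alpha = mu_alpha,
                                 tau = mu_tau)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d subjects, scenario '%s' (d_alpha_pdm_post = %g, d_tau_vdm_post = %g), gamma = %g, miss rate = %g\n",
    length(unique(x$cells$subject_id)), x$scenario, x$d_alpha_pdm_post,
    x$d_tau_vdm_post, x$gamma, x$miss_rate))
  invisible(x)
}

# join cell parameters onto a design table, erroring on missing cells
truth_for_design <- function(design, truth) {
  key <- paste(design$subject_id, design$task, design$phase)
  ckey <- paste(truth$cells$subject_id, truth$cells$task, truth$cells$phase)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    stop("design rows without a ground-truth cell: e.g. ",
         key[which(is.na(idx))[1]], call. = FALSE)
  }
  truth$cells[idx, c("kappa", "alpha", "tau")]
}

#' Fill a design with simulated choices and response times
#'
#' Simulates every trial with the Euler-Maruyama path simulator at the
#' trial's cell parameters (drift `kappa * E` toward the correct boundary,
#' unbiased start). When the ground truth couples a neural signal to the
#' boundary (`gamma > 0`), a latent standard-normal `theta` is drawn per
#' trial and the effective boundary is `alpha + gamma * theta` (floored at
#' 0.05). Trials sampled as misses, or whose response time exceeds the 3 s
#' response window, are marked invalid and carry no response or RT.
#'
#' @param design a trial table from [build_design()].
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @param dt Euler-Maruyama step (s).
#' @param response_window_s response deadline in seconds (default 3).
#' @return The design with added columns `response` ("upper"/"lower"),
#'   `correct` (0/1), `rt_s`, `theta` (latent neural signal; `NA` when
#'   `gamma` plays no role it is still drawn so [generate_neural()] can
#'   attach observed betas) and `valid` (0/1).
#' @export
generate_behaviour <- function(design, truth, seed = 1, dt = 1e-4,
                               response_window_s = 3) {
  stopifnot(inherits(truth, "ground_truth"))
  pars <- truth_for_design(design, truth)
  if (any(pars$alpha <= 0) || any(pars$tau < 0)) {
    stop("generation error: cell with alpha <= 0 or tau < 0", call. = FALSE)
  }
  n <- nrow(design)
  with_seed(derive_seed(seed, "behaviour"), {
    theta <- rnorm(n)
    a_eff <- pmax(pars$alpha + truth$gamma * theta, 0.05)
    v <- pars$kappa * design$evidence_level
    sim <- cpp_sim_trials(v, a_eff, rep(0.5, n), pars$tau, n, dt, 60,
                          cpp_seed(), 0.5826 * sqrt(dt))
    miss <- rbinom(n, 1, truth$miss_rate) == 1
    rt <- sim$rt
    correct <- sim$upper == 1L
    valid <- !miss & !is.na(rt) & rt <= response_window_s
    out <- design
    out$response <- ifelse(correct, out$target,
                           ifelse(out$target == "upper", "lower", "upper"))
    out$correct <- as.integer(correct)
    out$rt_s <- rt
    out$theta <- theta
    out$valid <- as.integer(valid)
    out$response[!valid] <- NA_character_
    out$correct[!valid] <- NA_integer_
    out$rt_s[!valid] <- NA_real_
    out
  })
}

#' Attach observed neural betas to generated trials
#'
#' The observed single-trial beta is the latent neural signal `theta` plus
#' Gaussian measurement noise, z-scored within subject over valid trials
#' (invalid trials carry no beta). If the records lack a latent `theta`
#' column (e.g. an externally supplied table), a fresh decoupled signal is
#' drawn.
#'
#' @param records a trial table from [generate_behaviour()].
#' @param truth the [ground_truth()] used to generate it.
#' @param seed integer seed for the measurement noise.
#' @return `records` with an `sfs_beta` column (per-subject mean 0, sd 1 on
#'   valid trials).
#' @export
generate_neural <- function(records, truth, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(records)
  with_seed(derive_seed(seed, "neural"), {
    theta <- if ("theta" %in% names(records)) records$theta else rnorm(n)
    obs <- theta + truth$neural_noise_sd * rnorm(n)
    beta <- rep(NA_real_, n)
    for (s in unique(records$subject_id)) {
      idx <- which(records$subject_id == s & records$valid == 1)
      if (length(idx) < 2) {
        stop("subject ", s, " has fewer than 2 valid trials; z-scoring ",
             "undefined", call. = FALSE)
      }
      beta[idx] <- (obs[idx] - mean(obs[idx])) / sd(obs[idx])
    }
    records$sfs_beta <- beta
    records
  })
}

#' Simulate a complete synthetic experiment
#'
#' Convenience chain: [build_design()] -> [generate_behaviour()] ->
#' [generate_neural()], with stage seeds derived from one base seed.
#'
#' @param spec a [design_spec()] or a subject count (default spec then).
#' @param truth a [ground_truth()]; defaults to the boundary scenario for the
#'   spec's subject count.
#' @param seed integer base seed.
#' @param dt Euler-Maruyama step (s).
#' @return A filled trial table (see [generate_behaviour()]).
#' @examples
#' trials <- simulate_experiment(design_spec(2), seed = 7)
#' table(trials$task, trials$phase)
#' @export
simulate_experiment <- function(spec, truth = NULL, seed = 1, dt = 1e-4) {
  if (is.numeric(spec)) spec <- design_spec(spec)
  if (is.null(truth)) truth <- ground_truth(spec$n_subjects, seed = seed)
  design <- build_design(spec, seed = seed)
  rec <- generate_behaviour(design, truth, seed = seed, dt = dt)
  generate_neural(rec, truth, seed = seed)
}

#' Write / read a trial table as delimited text
#'
#' The CSV carries the canonical column set (`subject_id, session, phase,
#' task, block_id, evidence_level, response, correct, rt_s, sfs_beta,
#' valid`) plus any extra columns present; missing values are empty fields
#' and RTs keep full precision.
#'
#' @param records trial table.
#' @param path output file.
#' @param truth optional [ground_truth()]; when given, a YAML sidecar
#'   `<path>.truth.yml` with the generating parameters is written alongside
#'   (for recovery tests).
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path, truth = NULL) {
  first <- intersect(c("subject_id", "session", "phase", "task", "block_id",
                       "evidence_level", "response", "correct", "rt_s",
                       "sfs_beta", "valid"), names(records))
  rec <- records[, c(first, setdiff(names(records), first))]
  if ("rt_s" %in% names(rec)) {
    rec$rt_s <- ifelse(is.na(rec$rt_s), NA, sprintf("%.6f", rec$rt_s))
  }
  write.csv(rec, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(truth)) {
    yaml::write_yaml(list(scenario = truth$scenario,
                          d_alpha_pdm_post = truth$d_alpha_pdm_post,
                          d_tau_vdm_post = truth$d_tau_vdm_post,
                          gamma = truth$gamma,
                          neural_noise_sd = truth$neural_noise_sd,
                          miss_rate = truth$miss_rate,
                          cells = truth$cells),
                     paste0(path, ".truth.yml"))
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  num <- intersect(c("rt_s", "sfs_beta", "theta"), names(rec))
  for (cn in num) rec[[cn]] <- as.numeric(rec[[cn]])
  rec
}
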