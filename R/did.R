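# shared construction of the regression frame: Task (perceptual = 1),
# TMS (post = 1), Neur (z-scored trialwise covariate), controls.
did_frame <- function(records, outcome, neural, controls) {
  d <- records[records$valid == 1, ]
  d$Task <- as.integer(d$task == "perceptual")
  d$TMS <- as.integer(d$phase == "post")
  if (neural) {
    if (!"sfs_beta" %in% names(d)) {
      stop("records carry no `sfs_beta` column", call. = FALSE)
    }
    d$Neur <- d$sfs_beta
    if (sd(d$Neur, na.rm = TRUE) < 1e-12) {
      stop("neural covariate is constant (collinear)", call. = FALSE)
    }
  }
  d$ev_relevant <- d$evidence_level
  if ("ev_irrelevant" %in% names(d)) d$ev_irrelevant <- d$ev_irrelevant
  keep <- c("subject_id", outcome, "Task", "TMS",
            if (neural) "Neur", controls)
  keep <- intersect(keep, names(d))
  d <- d[complete.cases(d[, keep]), keep]
  if (length(unique(d$subject_id)) < 2) {
    stop("cluster-robust inference needs at least 2 subjects",
         call. = FALSE)
  }
  d
}

default_controls <- function(outcome, records) {
  ctl <- c("ev_relevant",
           if ("ev_irrelevant" %in% names(records)) "ev_irrelevant")
  if (outcome == "correct") ctl <- c(ctl, "rt_s")
  ctl
}

# Firth-type penalised logistic fit (Jeffreys prior), used as a fallback
# when ML separation is detected. Returns coef and the penalised
# information matrix.
firth_logit <- function(X, y, max_iter = 60, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    Wv <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(Wv)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- solve(info, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = setNames(beta, colnames(X)), info = info, fitted = plogis(drop(X %*% beta)))
}

cluster_vcov_scores <- function(scores, bread_inv, cluster) {
  G <- length(unique(cluster))
  n <- nrow(scores); k <- ncol(scores)
  cs <- rowsum(scores, cluster)
  meat <- crossprod(cs)
  adj <- G / (G - 1) * (n - 1) / (n - k)  # CR1 small-sample factor
  bread_inv %*% (adj * meat) %*% bread_inv
}

#' Difference-in-differences regression on trialwise outcomes
#'
#' Fits the causal DID model on valid trials: a logit regression for choice
#' accuracy or a linear model for response time, with `Task` (perceptual =
#' 1), `TMS` (post-stimulation = 1), their product (whose coefficient is
#' the causal effect phi), optional neural covariate terms and control
#' regressors. Standard errors are cluster-robust at the subject level (CR1
#' small-sample correction; inference on t with clusters - 1 degrees of
#' freedom). For the logit link the two-model nonlinearity correction is
#' applied automatically: the interaction coefficient itself is biased away
#' from zero on the probability scale, so the corrected effect is the mean
#' difference between predicted probabilities of the model with and without
#' the interaction. Complete separation triggers a Firth-penalised fallback
#' with a warning.
#'
#' @param records trial table.
#' @param outcome `"correct"` (logit) or `"rt"` (identity link).
#' @param neural include the z-scored neural covariate and all its
#'   interactions, making phi the `Neur x Task x TMS` coefficient?
#' @param controls character vector of control regressors (default:
#'   task-relevant evidence, task-irrelevant evidence, and RT for choice
#'   models). Use `character(0)` for none.
#' @return A `did_estimate`: `phi`, `se_cluster`, `ci95`, `p`, the full
#'   coefficient table, `n_clusters`, and for the logit link
#'   `corrected_effect` (overall and per task x phase cell).
#' @export
fit_did <- function(records, outcome = c("correct", "rt"), neural = FALSE,
                    controls = NULL) {
  outcome <- match.arg(outcome)
  ocol <- if (outcome == "rt") "rt_s" else "correct"
  if (is.null(controls)) controls <- default_controls(ocol, records)
  d <- did_frame(records, ocol, neural, controls)
  base <- if (neural) "Neur * Task * TMS" else "Task * TMS"
  rhs <- paste(c(base, controls), collapse = " + ")
  f_with <- as.formula(paste(ocol, "~", rhs))
  phi_term <- if (neural) "Neur:Task:TMS" else "Task:TMS"
  f_without <- update(f_with, paste(". ~ . -", phi_term))
  if (outcome == "rt") {
    fit <- lm(f_with, data = d)
    V <- sandwich::vcovCL(fit, cluster = d$subject_id, type = "HC1")
    corrected <- NULL
    models <- list(with = fit, without = lm(f_without, data = d))
    penalised <- FALSE
    cf <- coef(fit)
  } else {
    fit <- suppressWarnings(glm(f_with, family = binomial(), data = d))
    penalised <- !fit$converged || any(abs(coef(fit)) > 15)
    if (penalised) {
      warning("separation detected; falling back to Firth-penalised logit",
              call. = FALSE)
      X <- model.matrix(f_with, d)
      fw <- firth_logit(X, d[[ocol]])
      Xo <- model.matrix(f_without, d)
      fo <- firth_logit(Xo, d[[ocol]])
      scores <- X * (d[[ocol]] - fw$fitted)
      V <- cluster_vcov_scores(scores, solve(fw$info), d$subject_id)
      dimnames(V) <- list(names(fw$coef), names(fw$coef))
      cf <- fw$coef
      models <- list(with = fw, without = fo)
      corrected <- correct_probs(fw$fitted, fo$fitted, d)
    } else {
      fit0 <- suppressWarnings(glm(f_without, family = binomial(),
                                   data = d))
      V <- sandwich::vcovCL(fit, cluster = d$subject_id, type = "HC1")
      cf <- coef(fit)
      models <- list(with = fit, without = fit0)
      corrected <- correct_did_nonlinearity(fit, fit0, d)
    }
  }
  G <- length(unique(d$subject_id))
  se <- sqrt(diag(V))
  tval <- cf / se
  pval <- 2 * pt(-abs(tval), df = G - 1)
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    se_cluster = unname(se), t = unname(tval),
                    p = unname(pval),
                    ci_lo = unname(cf - qt(0.975, G - 1) * se),
                    ci_hi = unname(cf + qt(0.975, G - 1) * se),
                    stringsAsFactors = FALSE)
  i <- match(phi_term, tab$term)
  structure(list(phi = tab$estimate[i], se_cluster = tab$se_cluster[i],
                 p = tab$p[i], ci95 = c(tab$ci_lo[i], tab$ci_hi[i]),
                 phi_term = phi_term, outcome = outcome,
                 link = if (outcome == "rt") "identity" else "logit",
                 n_clusters = G, n_trials = nrow(d),
                 coef_table = tab, corrected_effect = corrected,
                 penalised = penalised, models = models, data = d),
            class = "did_estimate")
}

#' @importFrom stats qt
#' @export
print.did_estimate <- function(x, ...) {
  cat(sprintf(
    "DID %s regression (%d trials, %d clusters)\nphi [%s] = %.4f (cluster SE %.4f), 95%% CI [%.4f, %.4f], p = %.4g\n",
    x$link, x$n_trials, x$n_clusters, x$phi_term, x$phi, x$se_cluster,
    x$ci95[1], x$ci95[2], x$p))
  if (!is.null(x$corrected_effect)) {
    cat(sprintf("corrected probability-scale DID = %.4f\n",
                x$corrected_effect$overall))
  }
  invisible(x)
}

correct_probs <- function(p_with, p_without, d) {
  diff <- p_with - p_without
  cellkey <- paste0("Task=", d$Task, ",TMS=", d$TMS)
  list(overall = mean(diff),
       by_cell = tapply(diff, cellkey, mean),
       trialwise = diff)
}

#' Two-model correction of logit DID nonlinearity
#'
#' The raw interaction coefficient of a logit DID model is a biased
#' estimate of the probability-scale causal effect even when the true
#' effect is zero, because the logistic link is nonlinear. The corrected
#' effect is the trial-averaged difference between predicted probabilities
#' of the full model and of the same model refitted without the interaction
#' term.
#'
#' @param model_with fitted logit model containing the DID interaction.
#' @param model_without the same model without the interaction, on the same
#'   data.
#' @param records the data both models were fitted to.
#' @return A list: `overall` (average partial effect), `by_cell` (per
#'   Task x TMS cell), `trialwise`.
#' @export
correct_did_nonlinearity <- function(model_with, model_without, records) {
  n1 <- length(model_with$fitted.values %||% model_with$fitted)
  n0 <- length(model_without$fitted.values %||% model_without$fitted)
  if (n1 != n0 || n1 != nrow(records)) {
    stop("models were not fitted to the same data as `records`",
         call. = FALSE)
  }
  p1 <- if (inherits(model_with, "glm")) {
    predict(model_with, newdata = records, type = "response")
  } else model_with$fitted
  p0 <- if (inherits(model_without, "glm")) {
    predict(model_without, newdata = records, type = "response")
  } else model_without$fitted
  d <- records
  if (is.null(d$Task)) d$Task <- as.integer(d$task == "perceptual")
  if (is.null(d$TMS)) d$TMS <- as.integer(d$phase == "post")
  correct_probs(p1, p0, d)
}

#' Three-way neural x task x stimulation marginal-effect regression
#'
#' Trialwise regression in which the causal effect phi is the coefficient
#' of `Neur x Task x TMS`: whether the marginal effect of the neural
#' covariate on behaviour changes after stimulation specifically in the
#' perceptual task. All lower-order neural terms are always included (the
#' model is invalid without them, and supplying `terms` that omit them is
#' an error). For the choice outcome the two-model nonlinearity correction
#' is applied as in [fit_did()]; the fitted marginal slope of the neural
#' covariate per task x phase cell is reported as `marginal_slopes`.
#'
#' @inheritParams fit_did
#' @param terms optional character vector naming the structural regressors;
#'   must include `Neur`, `Task`, `TMS` and all their two-way products.
#' @return A `did_estimate` with `marginal_slopes` attached.
#' @export
marginal_effect_threeway <- function(records, outcome = c("correct", "rt"),
                                     controls = NULL, terms = NULL) {
  outcome <- match.arg(outcome)
  if (!is.null(terms)) {
    need <- c("Neur", "Task", "TMS", "Neur:Task", "Neur:TMS", "Task:TMS")
    missing_terms <- setdiff(need, terms)
    if (length(missing_terms)) {
      stop("three-way DID spec must include all lower-order terms; ",
           "missing: ", paste(missing_terms, collapse = ", "),
           call. = FALSE)
    }
  }
  est <- fit_did(records, outcome = outcome, neural = TRUE,
                 controls = controls)
  cf <- setNames(est$coef_table$estimate, est$coef_table$term)
  d <- est$data
  slopes <- sapply(split(seq_len(nrow(d)),
                         paste0("Task=", d$Task, ",TMS=", d$TMS)),
                   function(idx) {
    ta <- d$Task[idx][1]; tm <- d$TMS[idx][1]
    slope_lin <- cf["Neur"] +
      ifelse(is.na(cf["Neur:Task"]), 0, cf["Neur:Task"]) * ta +
      ifelse(is.na(cf["Neur:TMS"]), 0, cf["Neur:TMS"]) * tm +
      ifelse(is.na(cf["Neur:Task:TMS"]), 0, cf["Neur:Task:TMS"]) * ta * tm
    if (est$link == "logit") {
      p <- if (inherits(est$models$with, "glm")) {
        est$models$with$fitted.values[idx]
      } else est$models$with$fitted[idx]
      unname(slope_lin * mean(p * (1 - p)))
    } else unname(slope_lin)
  })
  est$marginal_slopes <- slopes
  est
}

#' Subject-level three-way difference-in-differences model
#'
#' Linear model on one row per subject x task x phase cell relating a
#' subject-level outcome `pi` (behavioural summary or posterior-mean latent
#' parameter) to a subject-level neural measure `nu`, with the full
#' `nu x Task x TMS` factorial; phi is the three-way coefficient. Default
#' inference is a fixed-effects fit with subject-clustered CR1 errors; a
#' random-intercept mixed model is available with `method = "lmer"` (needs
#' lme4). Incomplete cells are dropped listwise with a message.
#'
#' @param summaries data.frame with columns `subject_id`, `task`, `phase`,
#'   `nu`, `pi`.
#' @param method `"lm"` (clustered errors) or `"lmer"` (random intercept).
#' @return A `did_estimate` (for `"lm"`) or the fitted `lmerMod` with the
#'   phi row attached (for `"lmer"`).
#' @export
subject_level_did <- function(summaries, method = c("lm", "lmer")) {
  method <- match.arg(method)
  req <- c("subject_id", "task", "phase", "nu", "pi")
  if (!all(req %in% names(summaries))) {
    stop("summaries must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d <- summaries
  ok <- complete.cases(d[, req])
  if (any(!ok)) {
    message("dropping ", sum(!ok), " incomplete subject-cell rows")
    d <- d[ok, ]
  }
  if (sd(d$nu) < 1e-12) {
    stop("`nu` is constant: three-way model is collinear", call. = FALSE)
  }
  d$Task <- as.integer(d$task == "perceptual")
  d$TMS <- as.integer(d$phase == "post")
  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("method 'lmer' needs the lme4 package", call. = FALSE)
    }
    fit <- lme4::lmer(pi ~ nu * Task * TMS + (1 | subject_id), data = d)
    cf <- lme4::fixef(fit)
    return(structure(list(fit = fit, phi = unname(cf["nu:Task:TMS"]),
                          method = "lmer"), class = "subject_did"))
  }
  fit <- lm(pi ~ nu * Task * TMS, data = d)
  V <- sandwich::vcovCL(fit, cluster = d$subject_id, type = "HC1")
  cf <- coef(fit)
  se <- sqrt(diag(V))
  G <- length(unique(d$subject_id))
  tval <- cf / se
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    se_cluster = unname(se), t = unname(tval),
                    p = unname(2 * pt(-abs(tval), G - 1)),
                    ci_lo = unname(cf - qt(0.975, G - 1) * se),
                    ci_hi = unname(cf + qt(0.975, G - 1) * se),
                    stringsAsFactors = FALSE)
  i <- match("nu:Task:TMS", tab$term)
  structure(list(phi = tab$estimate[i], se_cluster = tab$se_cluster[i],
                 p = tab$p[i], ci95 = c(tab$ci_lo[i], tab$ci_hi[i]),
                 phi_term = "nu:Task:TMS", outcome = "pi",
                 link = "identity", n_clusters = G, n_trials = nrow(d),
                 coef_table = tab, corrected_effect = NULL,
                 penalised = FALSE, models = list(with = fit), data = d),
            class = "did_estimate")
}
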