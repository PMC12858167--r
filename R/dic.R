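# index helpers: which columns of the draw array hold the subject-level
# parameters the likelihood depends on
likelihood_param_names <- function(fit) {
  S <- length(fit$subjects)
  grid <- expand.grid(s = seq_len(S), cell = CELLS,
                      stringsAsFactors = FALSE)
  list(kappa = sprintf("kappa[%d,%s]", grid$s, grid$cell),
       alpha = sprintf("alpha[%d,%s]", grid$s, grid$cell),
       tau = sprintf("tau[%d,%s]", grid$s, grid$cell),
       grid = grid)
}

gamma_cols <- function(fit) {
  S <- length(fit$subjects)
  m <- fit$model
  shared <- identical(m$gamma_structure, "shared")
  list(
    ga = if (shared) sprintf("gamma[%d]", seq_len(S))
         else if ("boundary" %in% m$modulates)
           sprintf("gamma_a[%d]", seq_len(S)) else NULL,
    gd = if (shared) sprintf("gamma[%d]", seq_len(S))
         else if ("drift" %in% m$modulates)
           sprintf("gamma_d[%d]", seq_len(S)) else NULL)
}

# deviance (-2 log lik) of the whole trial table at one parameter setting
deviance_at <- function(dat, S, K, A, Tau, Ga, Gd, w, floor_a) {
  ll <- 0
  for (s in seq_len(S)) for (ci in 1:4) {
    r <- cell_ll(dat[[s]][[ci]], K[s, ci], A[s, ci], Tau[s, ci],
                 if (is.null(Ga)) 0 else Ga[s],
                 if (is.null(Gd)) 0 else Gd[s], w, floor_a)
    if (!is.finite(r[1])) return(Inf)
    ll <- ll + r[1]
  }
  -2 * ll
}

#' Deviance information criterion of a fitted diffusion model
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and the
#' effective parameter count `pD = Dbar - D(posterior means)` (Spiegelhalter
#' form; the variance form `pV = var(D) / 2` is available via
#' `pd_method = "variance"`). Lower DIC means better predictive accuracy
#' after the complexity penalty. Non-finite deviance draws are excluded and
#' counted; a negative `pD` is flagged with a warning.
#'
#' @param fit an `hddm_fit`.
#' @param records the trial table the model was fitted to.
#' @param pd_method `"mean"` (default) or `"variance"`.
#' @return A `dic_result`: `dbar`, `pd`, `dic`, `n_excluded`, `model_id`.
#' @export
dic <- function(fit, records, pd_method = c("mean", "variance")) {
  pd_method <- match.arg(pd_method)
  stopifnot(inherits(fit, "hddm_fit"))
  neural <- fit$model$model_id != "baseline"
  prep <- prepare_cells(records, need_theta = neural)
  if (prep$fingerprint != fit$data_fingerprint) {
    stop("records do not match the data this model was fitted to",
         call. = FALSE)
  }
  S <- length(fit$subjects)
  nm <- likelihood_param_names(fit)
  gc <- gamma_cols(fit)
  dr <- fit$draws
  flat <- matrix(dr, nrow = dim(dr)[1] * dim(dr)[2],
                 dimnames = list(NULL, dimnames(dr)[[3]]))
  n <- nrow(flat)
  dev <- numeric(n)
  for (i in seq_len(n)) {
    dev[i] <- deviance_at(
      prep$dat, S,
      matrix(flat[i, nm$kappa], S, 4), matrix(flat[i, nm$alpha], S, 4),
      matrix(flat[i, nm$tau], S, 4),
      if (is.null(gc$ga)) NULL else flat[i, gc$ga],
      if (is.null(gc$gd)) NULL else flat[i, gc$gd],
      fit$w, fit$floor_a)
  }
  keep <- is.finite(dev)
  n_excl <- sum(!keep)
  dev <- dev[keep]
  dbar <- mean(dev)
  pm <- colMeans(flat[keep, , drop = FALSE])
  d_at_mean <- deviance_at(
    prep$dat, S,
    matrix(pm[nm$kappa], S, 4), matrix(pm[nm$alpha], S, 4),
    matrix(pm[nm$tau], S, 4),
    if (is.null(gc$ga)) NULL else pm[gc$ga],
    if (is.null(gc$gd)) NULL else pm[gc$gd],
    fit$w, fit$floor_a)
  pd <- if (pd_method == "mean") dbar - d_at_mean else var(dev) / 2
  if (pd < 0) warning("negative effective parameter count pD = ",
                      signif(pd, 4), call. = FALSE)
  structure(list(model_id = fit$model$model_id, dbar = dbar, pd = pd,
                 dic = dbar + pd, pd_method = pd_method,
                 n_excluded = n_excl,
                 data_fingerprint = fit$data_fingerprint),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("model %s: Dbar = %.2f, pD = %.2f, DIC = %.2f (%d draws excluded)\n",
              x$model_id, x$dbar, x$pd, x$dic, x$n_excluded))
  invisible(x)
}

#' Rank models by DIC
#'
#' @param fits a list of `dic_result` objects for models fitted to the same
#'   data (fingerprints are checked).
#' @param baseline model id against which `relative_dic` is computed
#'   (default `"baseline"`).
#' @return A data.frame `model_id, dbar, pd, dic, relative_dic, rank`,
#'   sorted by ascending DIC.
#' @export
compare_models <- function(fits, baseline = "baseline") {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "dic_result")))
  fp <- vapply(fits, `[[`, "", "data_fingerprint")
  if (length(unique(fp)) != 1) {
    stop("DIC results come from different datasets", call. = FALSE)
  }
  tab <- data.frame(
    model_id = vapply(fits, `[[`, "", "model_id"),
    dbar = vapply(fits, `[[`, 0, "dbar"),
    pd = vapply(fits, `[[`, 0, "pd"),
    dic = vapply(fits, `[[`, 0, "dic"),
    stringsAsFactors = FALSE)
  base <- tab$dic[match(baseline, tab$model_id)]
  if (is.na(base)) stop("baseline model '", baseline, "' not among fits",
                        call. = FALSE)
  tab$relative_dic <- tab$dic - base
  tab <- tab[order(tab$dic), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
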