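#' Fit a binomial GLM (logit link) by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of \eqn{\mathrm{logit}\, P(y=1) = \beta_0 + \beta_1 x}
#' by IRLS. Starting values are \eqn{(\mathrm{logit}(\bar y), 0)}; convergence
#' is declared when the largest absolute coefficient change falls below
#' `tol` (default 1e-8), with at most `max_iter` (50) iterations. Standard
#' errors come from the inverse Fisher information \eqn{(X'WX)^{-1}} at the
#' optimum; Wald z and two-sided normal p-values are attached per
#' coefficient.
#'
#' A single outcome class is complete separation — the MLE diverges — and is
#' an error. Failure to converge within `max_iter` (e.g. quasi-separation)
#' is reported via `converged = FALSE`, not an exception; such coefficients
#' must not be interpreted and [wald_test()] refuses them.
#'
#' @param outcomes Numeric 0/1 vector (here: 1 = ingested, 0 = slimed).
#' @param covariate Numeric vector, same length (here: prey mass in g).
#' @param tol,max_iter IRLS stopping rule.
#' @return A `glm_fit` list: `coefficients`, `standard_errors`, `z_values`,
#'   `p_values` (all named `(Intercept)`, `slope`), `converged`,
#'   `n_iterations`, `log_likelihood`, `n_obs`.
#' @export
fit_logistic <- function(outcomes, covariate, tol = 1e-8, max_iter = 50L) {
  y <- as.numeric(outcomes)
  x <- as.numeric(covariate)
  stopifnot(length(y) == length(x))
  if (length(y) < 3) stop("need at least 3 observations")
  if (anyNA(y) || anyNA(x)) stop("missing values in outcomes or covariate")
  if (!all(y %in% c(0, 1))) stop("outcomes must be coded 0/1")
  if (length(unique(y)) < 2)
    stop("separation: only one outcome class present, MLE does not exist")

  X <- cbind(1, x)
  beta <- c(qlogis(mean(y)), 0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    # Newton step expressed as weighted least squares on the working response
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(XtWX, score),
                     error = function(e) stop("singular information matrix"))
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }

  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  XtWX <- crossprod(X, X * (mu * (1 - mu)))
  se <- z <- p <- rep(NA_real_, 2)
  if (converged) {
    cov_beta <- solve(XtWX)
    se <- sqrt(diag(cov_beta))
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
  }
  nm <- c("(Intercept)", "slope")
  structure(list(
    coefficients = stats::setNames(beta, nm),
    standard_errors = stats::setNames(se, nm),
    z_values = stats::setNames(z, nm),
    p_values = stats::setNames(p, nm),
    converged = converged,
    n_iterations = iter,
    log_likelihood = sum(y * log(mu) + (1 - y) * log1p(-mu)),
    n_obs = length(y)
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Binomial GLM (logit), n = %d, %s in %d iteration(s)\n",
              x$n_obs,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$n_iterations))
  if (x$converged) {
    tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                      z = x$z_values, p = x$p_values)
    print(tab, digits = 4)
  } else {
    cat("  coefficients unusable; no Wald statistics reported\n")
  }
  invisible(x)
}

#' Fit a simple linear model by ordinary least squares
#'
#' Closed-form normal-equation fit of \eqn{y = \beta_0 + \beta_1 x +
#' \varepsilon}, Gaussian errors. The slope standard error uses the residual
#' variance with \eqn{n - 2} degrees of freedom; the Wald t-statistic is
#' referred to a Student-t with the same df.
#'
#' @param x Numeric predictor (not constant), length `n >= 3`.
#' @param y Numeric response, same length.
#' @return An `ols_fit` list: `intercept`, `slope`, `slope_se`, `t_value`,
#'   `p_value`, `df_resid`, `r_squared`, `n_obs`, `converged` (always `TRUE`;
#'   present so [wald_test()] treats both fit types uniformly).
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations (no residual df otherwise)")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: x is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  df <- n - 2L
  s2 <- sum(resid^2) / df
  slope_se <- sqrt(s2 / sxx)
  tval <- slope / slope_se
  syy <- sum((y - mean(y))^2)
  structure(list(
    intercept = intercept,
    slope = slope,
    slope_se = slope_se,
    t_value = tval,
    p_value = 2 * pt(-abs(tval), df),
    df_resid = df,
    r_squared = if (syy == 0) NA_real_ else 1 - sum(resid^2) / syy,
    n_obs = n,
    converged = TRUE
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit, n = %d: y = %.4g + %.4g x  (slope SE %.4g, t = %.3f, p = %.3g, R2 = %.3f)\n",
    x$n_obs, x$intercept, x$slope, x$slope_se, x$t_value, x$p_value,
    x$r_squared))
  invisible(x)
}

#' Wald test for a fitted coefficient
#'
#' For a [fit_logistic()] fit the statistic is z = estimate/SE against the
#' standard normal; for a [fit_ols()] fit it is t against a Student-t with
#' the residual degrees of freedom. Two-sided throughout. Refuses an
#' unconverged fit: its standard errors are meaningless.
#'
#' @param fit A `glm_fit` or `ols_fit`.
#' @param which Coefficient index (1 = intercept, 2 = slope; default 2).
#' @return List with `statistic`, `p`, and `reference` (`"normal"` or
#'   `"t"` with df).
#' @export
wald_test <- function(fit, which = 2L) {
  if (!isTRUE(fit$converged))
    stop("fit did not converge; Wald statistics are unusable")
  if (inherits(fit, "glm_fit")) {
    stopifnot(which %in% 1:2)
    z <- fit$coefficients[[which]] / fit$standard_errors[[which]]
    list(statistic = z, p = 2 * pnorm(-abs(z)), reference = "normal")
  } else if (inherits(fit, "ols_fit")) {
    if (which != 2L)
      stop("only the slope is tested for an OLS fit")
    list(statistic = fit$t_value, p = 2 * pt(-abs(fit$t_value), fit$df_resid),
         reference = sprintf("t(%d)", fit$df_resid))
  } else {
    stop("fit must be a glm_fit or ols_fit")
  }
}

#' Relative prey mass of a successful predation event
#'
#' RPM = prey mass / predator mass. Defined only for successful ingestions
#' with a known predator mass: snakes that failed to ingest were never
#' captured, so their mass (and thus RPM) does not exist. For a double meal
#' (two birds in one event) the prey masses are summed upstream, so
#' `prey_mass_g` is already the total swallowed.
#'
#' @param event One predation event: a list or one-row data.frame with
#'   `outcome`, `prey_mass_g`, `predator_mass_g`.
#' @return RPM as a proportion (0.799 means 79.9% of predator mass).
#' @examples
#' compute_rpm(list(outcome = "INGESTED", prey_mass_g = 71.9,
#'                  predator_mass_g = 90))
#' @export
compute_rpm <- function(event) {
  if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1)
    event <- as.list(event)
  }
  if (!identical(toupper(event$outcome), "INGESTED"))
    stop("RPM is undefined for a ", event$outcome,
         " event: only successful ingestions have a captured predator")
  pred <- event$predator_mass_g
  if (is.null(pred) || is.na(pred))
    stop("predator mass missing; RPM undefined")
  stopifnot(pred > 0, event$prey_mass_g > 0)
  event$prey_mass_g / pred
}

#' Summarise relative prey mass over predation events
#'
#' Computes per-event RPM for all eligible events (outcome `INGESTED` with a
#' predator mass) and returns mean, standard error (sample SD / sqrt(n)),
#' range and n. Multi-prey (double-meal) events are included by default;
#' `exclude_multi_prey = TRUE` drops them, as done for prey-vs-predator
#' scatter plots where a summed prey mass is not one bird.
#'
#' @param events Data.frame of predation events (`bird_ids`, `prey_mass_g`,
#'   `outcome`, `predator_mass_g`).
#' @param exclude_multi_prey Drop events with more than one bird?
#' @return An `rpm_summary` list: `values`, `mean`, `se` (`NA` when n = 1,
#'   flagged by `n`), `min`, `max`, `n`, `n_multi_prey_excluded`.
#' @export
rpm_summary <- function(events, exclude_multi_prey = FALSE) {
  stopifnot(is.data.frame(events))
  eligible <- events[toupper(events$outcome) == "INGESTED" &
                       !is.na(events$predator_mass_g), , drop = FALSE]
  multi <- grepl(";", eligible$bird_ids, fixed = TRUE)
  n_excluded <- 0L
  if (exclude_multi_prey) {
    n_excluded <- sum(multi)
    eligible <- eligible[!multi, , drop = FALSE]
  }
  if (nrow(eligible) == 0) stop("no eligible predation events for RPM")
  values <- eligible$prey_mass_g / eligible$predator_mass_g
  n <- length(values)
  structure(list(
    values = values,
    mean = mean(values),
    se = if (n > 1) sd(values) / sqrt(n) else NA_real_,
    min = min(values),
    max = max(values),
    n = n,
    n_multi_prey_excluded = n_excluded
  ), class = "rpm_summary")
}

#' @export
print.rpm_summary <- function(x, ...) {
  se_txt <- if (is.na(x$se)) "NA (n = 1)" else sprintf("%.1f", 100 * x$se)
  cat(sprintf(
    "RPM over %d event(s): mean %.1f%% +/- %s, range %.1f%% - %.1f%%\n",
    x$n, 100 * x$mean, se_txt, 100 * x$min, 100 * x$max))
  if (x$n_multi_prey_excluded > 0)
    cat(sprintf("  (%d multi-prey event(s) excluded)\n",
                x$n_multi_prey_excluded))
  invisible(x)
}
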