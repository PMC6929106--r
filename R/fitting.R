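# Nonlinear least-squares estimation of the model parameters from
# clonogenic survival curves. All fits minimise the unweighted sum of
# squared residuals in log survival, ln S_model - ln S_obs, using
# Levenberg-Marquardt with box bounds (minpack.lm). Uncertainties are 1-sigma
# from the Jacobian-based covariance at the optimum.

# log mean survival via the closed form; numerically preferable to
# log(analytic_mean_survival()) because the loop-count power is applied in
# log space
.log_analytic <- function(params, dose, rsf = 1) {
  k_iso <- rsf * params$k_idsb
  lam <- params$alpha_dsb * dose * params$loop_size
  p0 <- exp(-lam)
  p1 <- lam * p0
  pc <- pmax(0, 1 - p0 - p1)
  f <- p0 + p1 * (1 - k_iso) + pc * (1 - params$k_cdsb)
  loop_count(params) * log(f)
}

.fit_data <- function(data, min_doses = 3L) {
  data <- as_survival_dataset(data)
  data <- data[data$dose_Gy > 0, , drop = FALSE]
  if (length(unique(data$dose_Gy)) < min_doses)
    stop("fitting requires at least ", min_doses,
         " distinct nonzero doses", call. = FALSE)
  data
}

.log_weights <- function(data, weighted) {
  if (!weighted) return(rep(1, nrow(data)))
  if (is.null(data$sf_sem) || anyNA(data$sf_sem) || any(data$sf_sem <= 0))
    stop("weighted fitting requires positive 'sf_sem' for every record",
         call. = FALSE)
  # delta method: sd of ln SF ~= sf_sem / SF
  data$surviving_fraction / data$sf_sem
}

.ls_engine <- function(resid_fn, starts, lower, upper, par_names) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(list(par = stats::setNames(rep(NA_real_, length(par_names)),
                                      par_names),
                se = rep(NA_real_, length(par_names)),
                objective = NA_real_, converged = FALSE))
  est <- stats::setNames(as.numeric(best$par), par_names)
  np <- length(par_names)
  covm <- tryCatch({
    df <- length(best$fvec) - np
    sigma2 <- if (df > 0) best$deviance / df else 0
    sigma2 * solve(best$hessian)
  }, error = function(e) matrix(NA_real_, np, np))
  dimnames(covm) <- list(par_names, par_names)
  se <- stats::setNames(sqrt(pmax(0, diag(covm))), par_names)
  span <- upper - lower
  at_bound <- est <= lower + 1e-8 * span | est >= upper - 1e-8 * span
  if (any(at_bound))
    warning("estimate(s) pinned at a parameter bound: ",
            paste(par_names[at_bound], collapse = ", "), call. = FALSE)
  list(par = est, se = se, cov = covm, objective = best$deviance,
       converged = best$info %in% 1:4)
}

.new_fit_result <- function(engine, n_points, stage, params) {
  structure(
    list(estimates = engine$par, std_errors = engine$se,
         cov = engine$cov,
         objective_value = engine$objective, converged = engine$converged,
         n_points = n_points, stage = stage, params = params),
    class = "loopsurv_fit"
  )
}

# Propagate the uncertainty of the frozen lethality parameters into a
# one-parameter stage fit (delta method): the sensitivity of the stage
# estimate to each frozen k is obtained by refitting at perturbed k values,
# and the lethality fit's covariance is mapped through it. The reported
# 1-sigma then reflects both the stage's own residual scatter and the
# upstream parameter uncertainty.
.propagate_frozen <- function(se_cond, refit_at, params, lethality_fit) {
  if (is.null(lethality_fit)) return(se_cond)
  stopifnot(inherits(lethality_fit, "loopsurv_fit"))
  cov_k <- lethality_fit$cov
  if (is.null(cov_k) || anyNA(cov_k)) return(se_cond)
  ks <- c(params$k_idsb, params$k_cdsb)
  sens <- numeric(2)
  for (j in 1:2) {
    delta <- max(1e-8, 1e-3 * ks[j])
    up <- dn <- ks
    up[j] <- ks[j] + delta
    dn[j] <- max(0, ks[j] - delta)
    sens[j] <- (refit_at(up[1], up[2]) - refit_at(dn[1], dn[2])) /
      (up[j] - dn[j])
  }
  var_prop <- drop(t(sens) %*% cov_k %*% sens)
  sqrt(se_cond^2 + max(0, var_prop))
}

#' @export
print.loopsurv_fit <- function(x, ...) {
  cat(sprintf("Giant-loop model fit (%s), %d points, objective %.4g%s\n",
              x$stage, x$n_points, x$objective_value,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates, std_error = x$std_errors)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.loopsurv_fit <- function(object, ...) object$estimates

#' @export
vcov.loopsurv_fit <- function(object, ...) {
  if (!is.null(object$cov)) return(object$cov)
  diag(object$std_errors^2, nrow = length(object$std_errors))
}

#' Fit the lesion lethality parameters to a normoxic survival curve
#'
#' Estimates `k_idsb` and `k_cdsb` by least squares on log surviving
#' fraction, with both parameters bounded in \[1e-6, 1\] and 5 deterministic
#' log-spaced multi-starts to guard against local minima. The data must be
#' the normoxic, repair-proficient condition of one cell line (HRF = 1 and
#' RSF = 1 are fixed). Zero-dose records (SF = 1 by normalisation) are
#' excluded.
#'
#' @param data A survival dataset (or data frame) with columns `dose_Gy`
#'   and `surviving_fraction`; at least 3 distinct nonzero doses.
#' @param params A [gl_params()] object supplying the fixed constants
#'   (induction rate, DNA content, loop size); its `k` values are ignored.
#' @param weighted If `TRUE`, residuals are weighted by 1/sigma in log
#'   space using the `sf_sem` column. Default `FALSE` (unweighted).
#' @return An object of class `loopsurv_fit` with elements `estimates`,
#'   `std_errors` (1-sigma), `objective_value`, `converged`, `n_points`.
#' @examples
#' p <- gl_params(4e-3, 0.15)
#' d <- data.frame(cell_line = "X", o2_percent = 20,
#'                 impairment_label = "none", drug_conc_nM = 0,
#'                 dose_Gy = c(1, 2, 4, 8),
#'                 surviving_fraction = analytic_mean_survival(p, c(1, 2, 4, 8)))
#' coef(fit_lethality(d))
#' @export
fit_lethality <- function(data, params = gl_params(), weighted = FALSE) {
  data <- .fit_data(data)
  w <- .log_weights(data, weighted)
  log_obs <- log(data$surviving_fraction)
  resid_fn <- function(p) {
    pp <- params
    pp$k_idsb <- p[[1]]
    pp$k_cdsb <- p[[2]]
    w * (.log_analytic(pp, data$dose_Gy) - log_obs)
  }
  starts <- cbind(10^seq(-4, log10(2e-2), length.out = 5),
                  rev(10^seq(log10(0.02), log10(0.6), length.out = 5)))
  eng <- .ls_engine(resid_fn, starts,
                    lower = c(1e-6, 1e-6), upper = c(1, 1),
                    par_names = c("k_idsb", "k_cdsb"))
  .new_fit_result(eng, nrow(data), "lethality", params)
}

#' Fit the hypoxia reduction factor to a hypoxic survival curve
#'
#' With the cell line's lethality parameters frozen at their normoxic
#' estimates, estimates the single factor `hrf` in \[1, 10\] by which the
#' DSB induction rate is divided under the data's oxygen condition.
#'
#' @param data Hypoxic, repair-proficient survival data of one cell line.
#' @param params A [gl_params()] object carrying the fitted `k_idsb`,
#'   `k_cdsb` (frozen during this fit).
#' @param lethality_fit Optional `loopsurv_fit` from [fit_lethality()].
#'   When supplied, the uncertainty of the frozen lethality parameters is
#'   propagated into the reported standard error by the delta method;
#'   otherwise the standard error is conditional on the frozen values.
#' @inheritParams fit_lethality
#' @return A `loopsurv_fit` with estimate `hrf`.
#' @export
fit_hrf <- function(data, params, weighted = FALSE, lethality_fit = NULL) {
  stopifnot(inherits(params, "gl_params"))
  data <- .fit_data(data)
  w <- .log_weights(data, weighted)
  log_obs <- log(data$surviving_fraction)
  starts <- matrix(c(1.01, 1.5, 2.5, 5, 8), ncol = 1)
  fit_at <- function(ki, kc, st = starts) {
    pp <- params
    pp$k_idsb <- ki
    pp$k_cdsb <- kc
    resid_fn <- function(p) {
      ph <- pp
      ph$alpha_dsb <- params$alpha_dsb / p[[1]]
      w * (.log_analytic(ph, data$dose_Gy) - log_obs)
    }
    .ls_engine(resid_fn, st, lower = 1, upper = 10, par_names = "hrf")
  }
  eng <- fit_at(params$k_idsb, params$k_cdsb)
  eng$se <- .propagate_frozen(
    eng$se,
    function(ki, kc)
      suppressWarnings(fit_at(ki, kc, matrix(eng$par))$par),
    params, lethality_fit)
  .new_fit_result(eng, nrow(data), "hrf", params)
}

#' Fit the radiosensitization factor to a repair-impaired survival curve
#'
#' With the lethality parameters frozen, estimates the factor `rsf` that
#' multiplies the isolated-lesion lethality for a repair-deficient mutant
#' or a DDR-inhibitor concentration, from its normoxic survival data. The
#' complex-lesion lethality is never modified. `rsf` is bounded in
#' \[1, 1/k_idsb\] so the scaled lethality stays a probability; an estimate
#' pinned at the upper bound (saturated lethality) triggers a warning.
#'
#' @param data Normoxic survival data of the repair-impaired condition.
#' @param params A [gl_params()] object carrying the fitted `k_idsb`,
#'   `k_cdsb` (frozen).
#' @inheritParams fit_lethality
#' @inheritParams fit_hrf
#' @return A `loopsurv_fit` with estimate `rsf`.
#' @export
fit_rsf <- function(data, params, weighted = FALSE, lethality_fit = NULL) {
  stopifnot(inherits(params, "gl_params"))
  if (params$k_idsb <= 0)
    stop("'params$k_idsb' must be positive to fit an RSF", call. = FALSE)
  data <- .fit_data(data)
  w <- .log_weights(data, weighted)
  log_obs <- log(data$surviving_fraction)
  fit_at <- function(ki, kc, st = NULL) {
    pp <- params
    pp$k_idsb <- ki
    pp$k_cdsb <- kc
    resid_fn <- function(p) {
      w * (.log_analytic(pp, data$dose_Gy, rsf = p[[1]]) - log_obs)
    }
    upper <- 1 / ki
    if (is.null(st))
      st <- matrix(exp(seq(log(1.01), log(upper * 0.9), length.out = 5)),
                   ncol = 1)
    else
      st <- matrix(pmin(pmax(st, 1), upper))
    .ls_engine(resid_fn, st, lower = 1, upper = upper, par_names = "rsf")
  }
  eng <- fit_at(params$k_idsb, params$k_cdsb)
  eng$se <- .propagate_frozen(
    eng$se,
    function(ki, kc)
      suppressWarnings(fit_at(ki, kc, matrix(eng$par))$par),
    params, lethality_fit)
  .new_fit_result(eng, nrow(data), "rsf", params)
}

#' Predict survival under combined hypoxia and repair impairment
#'
#' Zero-free-parameter prediction: the HRF estimated from untreated
#' hypoxic data and the RSF estimated from normoxic impaired data are
#' applied jointly (they act on disjoint model components, so no
#' interaction term is needed or fitted).
#'
#' @param params A [gl_params()] object with fitted lethality parameters.
#' @param hrf Hypoxia reduction factor for the target oxygen condition.
#' @param rsf Radiosensitization factor for the target impairment.
#' @param doses Dose series in Gy.
#' @return Data frame with columns `dose` and `surviving_fraction`.
#' @export
predict_combined <- function(params, hrf = 1, rsf = 1, doses = c(1, 2, 4, 8)) {
  adj <- condition_adjusted_params(params, hrf = hrf, rsf = rsf)
  data.frame(dose = doses,
             surviving_fraction =
               analytic_mean_survival(adj$params, doses, rsf = adj$rsf))
}

#' Linear-quadratic coefficients by low-dose Taylor expansion
#'
#' Expands the closed-form log survival around zero dose to recover the
#' coefficients of the linear-quadratic (LQ) parameterization
#' \eqn{S = e^{-\alpha D - \beta D^2}}. With per-loop DSB yield per Gy
#' \eqn{\lambda_1 = \alpha_{DSB} \cdot loop\_size} and effective
#' isolated-lesion lethality \eqn{k' = RSF \cdot K_{iDSB}}:
#' \deqn{\alpha = k' \alpha_{DSB} DNA_c, \qquad
#'   \beta = N_{gl} \lambda_1^2 (K_{cDSB}/2 - k' + k'^2/2)}
#' Useful to translate fitted model parameters to LQ form, or to seed the
#' model from published alpha/beta values when raw survival data are
#' unavailable.
#'
#' @param params A [gl_params()] object.
#' @param rsf Radiosensitization factor, default 1.
#' @return Named numeric vector `c(alpha = , beta = )` in 1/Gy and 1/Gy^2.
#' @examples
#' lq_taylor_coefficients(gl_params(4.83e-3, 0.169))
#' @export
lq_taylor_coefficients <- function(params, rsf = 1) {
  k_iso <- .check_rsf(params, rsf)
  lam1 <- params$alpha_dsb * params$loop_size
  ngl <- loop_count(params)
  alpha <- k_iso * params$alpha_dsb * params$dna_content
  beta <- ngl * lam1^2 * (params$k_cdsb / 2 - k_iso + k_iso^2 / 2)
  c(alpha = alpha, beta = beta)
}
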