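#' Hypoxia reduction factor as a function of oxygen concentration
#'
#' Parameterization of the hypoxia reduction factor (HRF) on DSB induction,
#' \deqn{HRF([O_2]) = \frac{m K + [O_2]}{K + [O_2]}}
#' with `m` the maximal HRF at zero oxygen and `k_half` the oxygen scale
#' constant in percent. The function is strictly decreasing in oxygen,
#' equals `m` at 0% and tends to 1 at full oxygenation. Defaults are the
#' literature-fitted values m = 2.94 and K = 0.129%.
#'
#' @param o2_percent Oxygen concentration in percent (vectorised,
#'   non-negative; normoxia is ~20).
#' @param m Maximal HRF at zero oxygen (> 1).
#' @param k_half Oxygen scale constant, percent (> 0).
#' @return HRF value(s), in (1, m\].
#' @examples
#' hrf_from_oxygen(c(0, 0.5, 1, 20))
#' @export
hrf_from_oxygen <- function(o2_percent, m = 2.94, k_half = 0.129) {
  stopifnot(is.numeric(o2_percent), is.numeric(m), is.numeric(k_half))
  if (any(!is.finite(o2_percent)) || any(o2_percent < 0))
    stop("'o2_percent' must be non-negative and finite", call. = FALSE)
  if (m <= 1) stop("'m' must exceed 1", call. = FALSE)
  if (k_half <= 0) stop("'k_half' must be positive", call. = FALSE)
  (m * k_half + o2_percent) / (k_half + o2_percent)
}

#' Oxygen-modified DSB induction rate
#'
#' Under reduced oxygen, damage fixation is less efficient and the initial
#' DSB yield drops: the induction rate becomes `alpha_dsb / hrf`. Lethality
#' parameters are unaffected by oxygenation (oxygen acts on induction, not
#' on repair).
#'
#' @param params A [gl_params()] object.
#' @param hrf Hypoxia reduction factor (>= 1; 1 is the normoxic reference).
#' @param allow_hyperoxia If `TRUE`, `hrf < 1` is permitted (not modelled
#'   by default).
#' @return Induction rate in DSB/(Mbp*Gy).
#' @export
effective_induction_rate <- function(params, hrf, allow_hyperoxia = FALSE) {
  stopifnot(inherits(params, "gl_params"),
            is.numeric(hrf), length(hrf) == 1L, is.finite(hrf))
  if (hrf <= 0) stop("'hrf' must be positive", call. = FALSE)
  if (hrf < 1 && !allow_hyperoxia)
    stop("'hrf' < 1 (hyperoxia) is not modelled; ",
         "set allow_hyperoxia = TRUE to override", call. = FALSE)
  params$alpha_dsb / hrf
}

#' Apply oxygenation and repair-impairment modifiers to model parameters
#'
#' Returns the parameter set under a treatment context: the DSB induction
#' rate is divided by the hypoxia reduction factor `hrf`, and the
#' radiosensitization factor `rsf` is carried along to multiply the
#' isolated-lesion lethality at evaluation time. The two modifiers act on
#' disjoint parts of the model (induction vs. lethality), so they compose
#' in either order, and dividing the induction rate by `hrf` is exactly
#' equivalent to dividing the dose by `hrf`.
#'
#' @param params A [gl_params()] object.
#' @param hrf Hypoxia reduction factor (>= 1 unless `allow_hyperoxia`).
#' @param rsf Radiosensitization factor (>= 1, with `rsf * k_idsb <= 1`).
#' @param allow_hyperoxia Passed to [effective_induction_rate()].
#' @return A list with elements `params` (modified [gl_params()]) and
#'   `rsf`, ready for [analytic_mean_survival()] or [mc_mean_survival()].
#' @examples
#' p <- gl_params(4.83e-3, 0.169)
#' adj <- condition_adjusted_params(p, hrf = 1.6, rsf = 2)
#' analytic_mean_survival(adj$params, dose = 4, rsf = adj$rsf)
#' @export
condition_adjusted_params <- function(params, hrf = 1, rsf = 1,
                                      allow_hyperoxia = FALSE) {
  alpha <- effective_induction_rate(params, hrf, allow_hyperoxia)
  .check_rsf(params, rsf)
  adj <- params
  adj$alpha_dsb <- alpha
  list(params = adj, rsf = rsf)
}
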