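#' Sample one nuclear damage configuration
#'
#' Draws the total DSB count from a Poisson distribution with mean
#' [expected_total_dsb()], assigns each DSB to a giant loop uniformly at
#' random, and scores the loops without DSB, with exactly one DSB (isolated
#' lesion) and with two or more DSBs (complex lesion). Uses R's global RNG;
#' call [set.seed()] for reproducibility.
#'
#' @param params A [gl_params()] object.
#' @param dose Absorbed dose in Gy (scalar, non-negative).
#' @return An object of class `gl_damage`: a list with `n_total`,
#'   `n_empty`, `n_isolated`, `n_complex`, `n_loops`.
#' @examples
#' set.seed(1)
#' sample_damage(gl_params(4.83e-3, 0.169), dose = 2)
#' @export
sample_damage <- function(params, dose) {
  stopifnot(inherits(params, "gl_params"),
            is.numeric(dose), length(dose) == 1L)
  mu <- expected_total_dsb(params, dose)
  ngl <- loop_count(params)
  n_total <- stats::rpois(1L, mu)
  if (n_total == 0L) {
    occ <- integer(0)
  } else {
    occ <- tabulate(sample.int(ngl, n_total, replace = TRUE), nbins = ngl)
    occ <- occ[occ > 0L]
  }
  n_isolated <- sum(occ == 1L)
  n_complex <- length(occ) - n_isolated
  structure(
    list(n_total = n_total,
         n_empty = ngl - length(occ),
         n_isolated = n_isolated,
         n_complex = n_complex,
         n_loops = ngl),
    class = "gl_damage"
  )
}

#' @export
print.gl_damage <- function(x, ...) {
  cat(sprintf(
    "Damage configuration: %d DSB over %d loops (%d empty, %d isolated, %d complex)\n",
    x$n_total, x$n_loops, x$n_empty, x$n_isolated, x$n_complex))
  invisible(x)
}

#' Survival probability of a cell with a given damage configuration
#'
#' Each isolated lesion is lethal with probability `rsf * k_idsb`, each
#' complex lesion with probability `k_cdsb`; lesions act independently, so
#' the cell survives with probability
#' `(1 - rsf*k_idsb)^n_isolated * (1 - k_cdsb)^n_complex`. `rsf = 1` is the
#' repair-proficient case; `rsf > 1` encodes DNA-repair impairment
#' (genetic deficiency or DDR-inhibitor treatment), which raises the
#' lethality of isolated lesions only.
#'
#' @param params A [gl_params()] object.
#' @param damage A `gl_damage` configuration from [sample_damage()].
#' @param rsf Radiosensitization factor (>= 1); `rsf * k_idsb` must not
#'   exceed 1.
#' @return Survival probability in \[0, 1\].
#' @export
survival_given_damage <- function(params, damage, rsf = 1) {
  stopifnot(inherits(params, "gl_params"), inherits(damage, "gl_damage"))
  k_iso <- .check_rsf(params, rsf)
  (1 - k_iso)^damage$n_isolated * (1 - params$k_cdsb)^damage$n_complex
}

.check_rsf <- function(params, rsf) {
  if (!is.numeric(rsf) || length(rsf) != 1L || !is.finite(rsf) || rsf < 1)
    stop("'rsf' must be a single finite number >= 1", call. = FALSE)
  k_iso <- rsf * params$k_idsb
  if (k_iso > 1)
    stop("rsf * k_idsb = ", format(k_iso),
         " exceeds 1: the isolated-lesion lethality is a probability",
         call. = FALSE)
  k_iso
}
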