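#' Monte Carlo estimate of mean clonogenic survival
#'
#' Repeats the per-cell simulation — Poisson total DSB count, uniform
#' assignment of DSBs over giant loops, lesion scoring, per-cell survival
#' probability — and returns the arithmetic mean over cells together with
#' its Monte Carlo standard error. The population surviving fraction is the
#' mean of per-cell survival probabilities in linear space.
#'
#' The sampling scheme is identical to [sample_damage()] +
#' [survival_given_damage()] applied `n_iter` times, but is executed in
#' vectorised chunks for speed: loop occupancies are scored by sorting
#' (cell, loop) assignment keys, which changes the RNG stream but not the
#' sampled distribution.
#'
#' @param params A [gl_params()] object.
#' @param dose Absorbed dose in Gy (scalar).
#' @param rsf Radiosensitization factor, default 1.
#' @param n_iter Number of simulated cells, default 1e5.
#' @param seed Optional integer seed, forwarded to [set.seed()].
#' @param chunk_size Cells simulated per vectorised chunk.
#' @return An object of class `survival_estimate`: list with
#'   `mean_survival`, `std_error`, `n_iterations`.
#' @examples
#' p <- gl_params(4.83e-3, 0.169)
#' mc_mean_survival(p, dose = 2, n_iter = 1e4, seed = 1)
#' analytic_mean_survival(p, dose = 2)
#' @export
mc_mean_survival <- function(params, dose, rsf = 1, n_iter = 1e5,
                             seed = NULL, chunk_size = 20000L) {
  stopifnot(inherits(params, "gl_params"),
            is.numeric(dose), length(dose) == 1L,
            is.numeric(n_iter), length(n_iter) == 1L, n_iter >= 1)
  k_iso <- .check_rsf(params, rsf)
  mu <- expected_total_dsb(params, dose)
  ngl <- loop_count(params)
  n_iter <- as.integer(n_iter)
  if (!is.null(seed)) set.seed(seed)

  if (mu == 0) {
    return(.survival_estimate(1, 0, n_iter))
  }

  base_iso <- 1 - k_iso
  base_cplx <- 1 - params$k_cdsb
  sum_s <- 0
  sum_s2 <- 0
  done <- 0L
  while (done < n_iter) {
    m <- min(as.integer(chunk_size), n_iter - done)
    n_total <- stats::rpois(m, mu)
    tot <- sum(n_total)
    if (tot == 0) {
      s <- rep(1, m)
    } else {
      loops <- sample.int(ngl, tot, replace = TRUE)
      cell <- rep.int(seq_len(m), n_total)
      key <- (cell - 1) * as.double(ngl) + loops   # unique per (cell, loop)
      if (m * as.double(ngl) < .Machine$integer.max) {
        key <- sort.int(as.integer(key), method = "radix")
      } else {
        key <- sort.int(key)
      }
      runs <- rle(key)
      run_cell <- (runs$values - 1) %/% ngl + 1
      n_iso <- tabulate(run_cell[runs$lengths == 1L], nbins = m)
      n_cplx <- tabulate(run_cell[runs$lengths >= 2L], nbins = m)
      s <- base_iso^n_iso * base_cplx^n_cplx
    }
    sum_s <- sum_s + sum(s)
    sum_s2 <- sum_s2 + sum(s^2)
    done <- done + m
  }

  mean_s <- sum_s / n_iter
  var_s <- max(0, (sum_s2 - n_iter * mean_s^2) / (n_iter - 1))
  .survival_estimate(mean_s, sqrt(var_s / n_iter), n_iter)
}

.survival_estimate <- function(mean_survival, std_error, n_iterations) {
  structure(
    list(mean_survival = mean_survival, std_error = std_error,
         n_iterations = n_iterations),
    class = "survival_estimate"
  )
}

#' @export
print.survival_estimate <- function(x, ...) {
  if (x$n_iterations > 0) {
    cat(sprintf("Mean survival %.6g (MC SE %.3g, %d cells)\n",
                x$mean_survival, x$std_error, x$n_iterations))
  } else {
    cat(sprintf("Mean survival %.6g (analytic)\n", x$mean_survival))
  }
  invisible(x)
}

#' Exact mean clonogenic survival (closed form)
#'
#' Because the total DSB count is Poisson and DSBs are assigned to loops
#' uniformly and independently, the per-loop DSB counts are i.i.d.
#' Poisson(`lambda`) with `lambda = expected_total_dsb / n_loops`. The
#' expected survival therefore factorises over loops:
#' \deqn{S(D) = [e^{-\lambda} + \lambda e^{-\lambda}(1 - RSF\,K_{iDSB})
#'   + (1 - e^{-\lambda} - \lambda e^{-\lambda})(1 - K_{cDSB})]^{N_{gl}}}
#' This is the exact expectation of [mc_mean_survival()] and is the
#' deterministic evaluator used throughout fitting.
#'
#' @param params A [gl_params()] object.
#' @param dose Absorbed dose in Gy (vectorised, non-negative).
#' @param rsf Radiosensitization factor, default 1.
#' @return Survival probabilities, same length as `dose`.
#' @export
analytic_mean_survival <- function(params, dose, rsf = 1) {
  stopifnot(inherits(params, "gl_params"), is.numeric(dose))
  k_iso <- .check_rsf(params, rsf)
  lam <- expected_total_dsb(params, dose) / loop_count(params)
  p0 <- exp(-lam)
  p1 <- lam * p0
  pc <- pmax(0, 1 - p0 - p1)
  f <- p0 + p1 * (1 - k_iso) + pc * (1 - params$k_cdsb)
  f^loop_count(params)
}

#' Survival curve over a dose series
#'
#' Evaluates mean survival at each dose, either with the exact closed form
#' (`mode = "analytic"`, deterministic) or by Monte Carlo simulation
#' (`mode = "mc"`).
#'
#' @param params A [gl_params()] object.
#' @param doses Vector of doses in Gy.
#' @param rsf Radiosensitization factor, default 1.
#' @param mode `"analytic"` or `"mc"`.
#' @param n_iter Cells per dose in MC mode.
#' @param seed Optional seed for MC mode.
#' @return A data frame with columns `dose`, `surviving_fraction`,
#'   `std_error`, `n_iterations` (the latter two are 0 in analytic mode).
#' @export
survival_curve <- function(params, doses, rsf = 1,
                           mode = c("analytic", "mc"),
                           n_iter = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(doses))
  if (any(doses < 0)) stop("'doses' must be non-negative", call. = FALSE)
  if (mode == "analytic") {
    data.frame(dose = doses,
               surviving_fraction = analytic_mean_survival(params, doses, rsf),
               std_error = 0, n_iterations = 0L)
  } else {
    if (!is.null(seed)) set.seed(seed)
    est <- lapply(doses, function(d)
      mc_mean_survival(params, d, rsf = rsf, n_iter = n_iter))
    data.frame(dose = doses,
               surviving_fraction = vapply(est, `[[`, 0, "mean_survival"),
               std_error = vapply(est, `[[`, 0, "std_error"),
               n_iterations = vapply(est, `[[`, 0L, "n_iterations"))
  }
}
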