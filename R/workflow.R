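#' Fit the giant-loop survival model to a clonogenic survival dataset
#'
#' Runs the full three-stage estimation workflow for every cell line in
#' the dataset:
#' \enumerate{
#'   \item lethality parameters `k_idsb`, `k_cdsb` are fitted to the
#'     normoxic, repair-proficient curve ([fit_lethality()]);
#'   \item with the lethality parameters frozen, one hypoxia reduction
#'     factor (HRF) is fitted per hypoxic oxygen level from the untreated
#'     data ([fit_hrf()]);
#'   \item with the lethality parameters frozen, one radiosensitization
#'     factor (RSF) is fitted per repair-impaired condition (mutant or
#'     drug concentration) from its normoxic data ([fit_rsf()]).
#' }
#' Survival under combined hypoxia and repair impairment is then a
#' zero-free-parameter prediction ([predict()][predict.loopsurv]), because
#' HRF (acting on DSB induction) and RSF (acting on isolated-lesion
#' lethality) modify disjoint parts of the model and are each invariant
#' under change of the other condition.
#'
#' @param data A `survival_dataset` (or compatible data frame), see
#'   [as_survival_dataset()].
#' @param params A [gl_params()] object supplying the fixed model
#'   constants; defaults to the standard photon constants.
#' @param normoxia_o2 Oxygen percentage at or above which a record counts
#'   as normoxic (HRF = 1 reference). Default 20.
#' @param weighted Passed to the stage fitters.
#' @return An object of class `loopsurv` with methods `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' camp <- synthetic_campaign(seed = 1, noise_sigma_log = 0.05)
#' fit <- loopsurv(camp[camp$cell_line == "SYN-OX1", ])
#' coef(fit)
#' @export
loopsurv <- function(data, params = gl_params(), normoxia_o2 = 20,
                     weighted = FALSE) {
  data <- as_survival_dataset(data)
  stopifnot(inherits(params, "gl_params"))

  fits <- list()
  for (cl in unique(data$cell_line)) {
    d <- data[data$cell_line == cl, , drop = FALSE]
    normoxic <- d$o2_percent >= normoxia_o2
    untreated <- d$impairment_label == "none"

    base <- d[normoxic & untreated, , drop = FALSE]
    if (nrow(base) == 0L)
      stop("cell line '", cl, "' has no normoxic untreated records; ",
           "the lethality stage cannot run", call. = FALSE)
    leth <- fit_lethality(base, params = params, weighted = weighted)
    line_params <- params
    line_params$k_idsb <- unname(leth$estimates["k_idsb"])
    line_params$k_cdsb <- unname(leth$estimates["k_cdsb"])

    hrf_fits <- list()
    for (o2 in sort(unique(d$o2_percent[!normoxic & untreated]),
                    decreasing = TRUE)) {
      sub <- d[untreated & d$o2_percent == o2, , drop = FALSE]
      hrf_fits[[as.character(o2)]] <-
        fit_hrf(sub, params = line_params, weighted = weighted,
                lethality_fit = leth)
    }

    rsf_fits <- list()
    imp <- d[!untreated & normoxic, , drop = FALSE]
    if (nrow(imp)) {
      keys <- unique(.impairment_key(imp))
      for (k in keys) {
        sub <- imp[.impairment_key(imp) == k, , drop = FALSE]
        rsf_fits[[k]] <-
          fit_rsf(sub, params = line_params, weighted = weighted,
                  lethality_fit = leth)
      }
    }

    fits[[cl]] <- list(lethality = leth, params = line_params,
                       hrf = hrf_fits, rsf = rsf_fits)
  }

  structure(
    list(fits = fits, data = data, base_params = params,
         normoxia_o2 = normoxia_o2),
    class = "loopsurv"
  )
}

.impairment_key <- function(d) {
  ifelse(d$drug_conc_nM > 0,
         paste0(d$impairment_label, "@", d$drug_conc_nM, "nM"),
         d$impairment_label)
}

#' @export
print.loopsurv <- function(x, ...) {
  cat("Giant-loop survival model fit\n")
  cat(sprintf("  %d cell line(s), %d records, normoxia threshold %g%% O2\n",
              length(x$fits), nrow(x$data), x$normoxia_o2))
  print(coef(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted workflow
#'
#' @param object A `loopsurv` object.
#' @param ... Unused.
#' @return Data frame with one row per fitted parameter: `cell_line`,
#'   `stage`, `condition`, `parameter`, `estimate`, `std_error`.
#' @export
coef.loopsurv <- function(object, ...) {
  rows <- list()
  add <- function(cl, stage, condition, fit) {
    for (p in names(fit$estimates))
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_line = cl, stage = stage, condition = condition,
        parameter = p, estimate = unname(fit$estimates[p]),
        std_error = unname(fit$std_errors[p]))
  }
  for (cl in names(object$fits)) {
    f <- object$fits[[cl]]
    add(cl, "lethality", "normoxic untreated", f$lethality)
    for (o2 in names(f$hrf))
      add(cl, "hrf", paste0(o2, "% O2"), f$hrf[[o2]])
    for (k in names(f$rsf))
      add(cl, "rsf", k, f$rsf[[k]])
  }
  do.call(rbind, rows)
}

#' @export
summary.loopsurv <- function(object, ...) {
  res <- residuals(object)
  structure(list(coefficients = coef(object),
                 n_records = nrow(object$data),
                 rms_log_residual = sqrt(mean(res^2))),
            class = "summary.loopsurv")
}

#' @export
print.summary.loopsurv <- function(x, ...) {
  cat("Giant-loop survival model: fitted parameters\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("\n%d records; RMS log-survival residual %.4f\n",
              x$n_records, x$rms_log_residual))
  invisible(x)
}

.lookup_condition <- function(object, cl, o2, key) {
  f <- object$fits[[cl]]
  if (is.null(f)) stop("unknown cell line '", cl, "'", call. = FALSE)
  hrf <- if (o2 >= object$normoxia_o2) {
    1
  } else if (!is.null(f$hrf[[as.character(o2)]])) {
    unname(f$hrf[[as.character(o2)]]$estimates["hrf"])
  } else {
    # no fitted HRF at this oxygen level: fall back to the parameterization
    hrf_from_oxygen(o2)
  }
  rsf <- if (key == "none") {
    1
  } else if (!is.null(f$rsf[[key]])) {
    unname(f$rsf[[key]]$estimates["rsf"])
  } else {
    stop("no fitted RSF for condition '", key, "' of cell line '", cl,
         "'", call. = FALSE)
  }
  list(params = f$params, hrf = hrf, rsf = rsf)
}

#' Predict surviving fractions from a fitted workflow
#'
#' Evaluates the fitted model at new condition/dose combinations. For
#' hypoxic records the HRF fitted at that oxygen level is used (falling
#' back to the oxygen parameterization [hrf_from_oxygen()] if that level
#' was never fitted); for impaired records the RSF fitted for that
#' condition under normoxia is used. Combined hypoxia + impairment
#' records are genuine predictions with no parameters fitted to them.
#'
#' @param object A `loopsurv` object.
#' @param newdata Data frame with columns `cell_line`, `o2_percent`,
#'   `impairment_label`, `drug_conc_nM`, `dose_Gy`. Default: the training
#'   data.
#' @param ... Unused.
#' @return Numeric vector of predicted surviving fractions.
#' @export
predict.loopsurv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  newdata <- as.data.frame(newdata)
  if (is.null(newdata$impairment_label)) newdata$impairment_label <- "none"
  if (is.null(newdata$drug_conc_nM)) newdata$drug_conc_nM <- 0
  keys <- .impairment_key(newdata)
  out <- numeric(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    ctx <- .lookup_condition(object, newdata$cell_line[i],
                             newdata$o2_percent[i], keys[i])
    adj <- condition_adjusted_params(ctx$params, hrf = ctx$hrf,
                                     rsf = ctx$rsf)
    out[i] <- analytic_mean_survival(adj$params, newdata$dose_Gy[i],
                                     rsf = adj$rsf)
  }
  out
}

#' @export
residuals.loopsurv <- function(object, ...) {
  log(object$data$surviving_fraction) - log(predict(object))
}

#' Simulate survival datasets from a fitted workflow
#'
#' Draws synthetic datasets at the fitted parameters over the observed
#' conditions of each cell line, using the log-normal measurement noise
#' model of [generate_dataset()].
#'
#' @param object A `loopsurv` object.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param noise_sigma_log Noise SD in log space; default 0.1.
#' @param n_replicates Replicates per condition and dose; default 3.
#' @param ... Unused.
#' @return A list of `nsim` `survival_dataset` objects.
#' @export
simulate.loopsurv <- function(object, nsim = 1, seed = NULL,
                              noise_sigma_log = 0.1, n_replicates = 3, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  keys <- .impairment_key(d)
  cond_tab <- unique(data.frame(cell_line = d$cell_line,
                                o2_percent = d$o2_percent,
                                impairment_label = d$impairment_label,
                                drug_conc_nM = d$drug_conc_nM,
                                key = keys))
  lapply(seq_len(nsim), function(s) {
    pieces <- lapply(unique(cond_tab$cell_line), function(cl) {
      ct <- cond_tab[cond_tab$cell_line == cl, , drop = FALSE]
      ctx <- lapply(seq_len(nrow(ct)), function(i)
        .lookup_condition(object, cl, ct$o2_percent[i], ct$key[i]))
      conditions <- data.frame(
        o2_percent = ct$o2_percent,
        hrf = vapply(ctx, `[[`, 0, "hrf"),
        rsf = vapply(ctx, `[[`, 0, "rsf"),
        impairment_label = ct$impairment_label,
        drug_conc_nM = ct$drug_conc_nM)
      generate_dataset(object$fits[[cl]]$params, conditions = conditions,
                       doses = sort(unique(d$dose_Gy[d$cell_line == cl &
                                                       d$dose_Gy > 0])),
                       noise_sigma_log = noise_sigma_log,
                       n_replicates = n_replicates, cell_line = cl)
    })
    out <- as_survival_dataset(do.call(rbind, pieces))
    attr(out, "truth") <- NULL
    out
  })
}

#' Plot observed and fitted survival curves
#'
#' One panel per cell line: observed surviving fractions (points, log
#' scale) and fitted/predicted model curves per condition.
#'
#' @param x A `loopsurv` object.
#' @param cell_lines Cell lines to plot; default all.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.loopsurv <- function(x, cell_lines = NULL, ...) {
  d <- x$data
  if (is.null(cell_lines)) cell_lines <- names(x$fits)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(cell_lines)))
  on.exit(graphics::par(old))
  for (cl in cell_lines) {
    dc <- d[d$cell_line == cl & d$dose_Gy > 0, , drop = FALSE]
    keys <- .impairment_key(dc)
    cond <- unique(data.frame(o2 = dc$o2_percent, key = keys))
    cols <- grDevices::hcl.colors(max(2L, nrow(cond)), "Dark 3")
    graphics::plot(dc$dose_Gy, dc$surviving_fraction, log = "y",
                   xlab = "Dose [Gy]", ylab = "Surviving fraction",
                   main = cl, type = "n", ...)
    dd <- seq(0.01, max(dc$dose_Gy), length.out = 100)
    for (i in seq_len(nrow(cond))) {
      sel <- dc$o2_percent == cond$o2[i] & keys == cond$key[i]
      graphics::points(dc$dose_Gy[sel], dc$surviving_fraction[sel],
                       col = cols[i], pch = 16)
      ctx <- .lookup_condition(x, cl, cond$o2[i], cond$key[i])
      adj <- condition_adjusted_params(ctx$params, hrf = ctx$hrf,
                                       rsf = ctx$rsf)
      graphics::lines(dd, analytic_mean_survival(adj$params, dd,
                                                 rsf = adj$rsf),
                      col = cols[i])
    }
    graphics::legend("bottomleft", bty = "n", cex = 0.7,
                     legend = paste0(cond$o2, "% O2, ", cond$key),
                     col = cols[seq_len(nrow(cond))], pch = 16, lty = 1)
  }
  invisible(x)
}
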