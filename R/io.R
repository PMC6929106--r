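#' Validate and classify a clonogenic survival dataset
#'
#' Checks a data frame of clonogenic survival records and returns it with
#' class `survival_dataset`. Required columns: `cell_line`, `o2_percent`,
#' `impairment_label`, `drug_conc_nM`, `dose_Gy`, `surviving_fraction`;
#' optional: `sf_sem` (standard error of the surviving fraction) and
#' `replicate`. Validation errors name the offending row. Surviving
#' fractions must lie in (0, 1\]: an SF of exactly 0 has an undefined log
#' and cannot enter the fit objective.
#'
#' @param data A data frame of survival records.
#' @return The validated data frame, classed `survival_dataset`.
#' @export
as_survival_dataset <- function(data) {
  if (inherits(data, "survival_dataset")) return(data)
  data <- as.data.frame(data)
  required <- c("cell_line", "o2_percent", "impairment_label",
                "drug_conc_nM", "dose_Gy", "surviving_fraction")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("survival dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  .row_check <- function(bad, what) {
    if (any(bad))
      stop("invalid survival record(s) at row(s) ",
           paste(which(bad), collapse = ", "), ": ", what, call. = FALSE)
  }
  .row_check(!is.finite(data$dose_Gy) | data$dose_Gy < 0,
             "dose_Gy must be numeric and >= 0")
  .row_check(!is.finite(data$surviving_fraction) |
               data$surviving_fraction <= 0 | data$surviving_fraction > 1,
             "surviving_fraction must lie in (0, 1]")
  .row_check(!is.finite(data$o2_percent) | data$o2_percent < 0,
             "o2_percent must be numeric and >= 0")
  if (!is.null(data$sf_sem)) {
    data$sf_sem <- as.numeric(data$sf_sem)
    .row_check(!is.na(data$sf_sem) & data$sf_sem < 0,
               "sf_sem must be >= 0 when present")
  }
  data$impairment_label <- as.character(data$impairment_label)
  data$impairment_label[is.na(data$impairment_label) |
                          data$impairment_label == ""] <- "none"
  class(data) <- c("survival_dataset", "data.frame")
  data
}

#' Read a clonogenic survival CSV file
#'
#' Reads comma-separated survival data (dot decimal, UTF-8, header row)
#' and validates it via [as_survival_dataset()].
#'
#' @param path Path to the CSV file.
#' @return A `survival_dataset`.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_survival_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a survival dataset to CSV
#'
#' Writes the same dialect [read_survival_csv()] consumes, so generated
#' datasets round-trip losslessly.
#'
#' @param data A `survival_dataset` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(data, path) {
  data <- as_survival_dataset(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Compare fitted HRF values with the oxygen parameterization
#'
#' Summarises how a set of per-cell-line fitted hypoxia reduction factors
#' at one oxygen level compares to the closed-form oxygen
#' parameterization [hrf_from_oxygen()]: reports the arithmetic mean of
#' the supplied HRFs, the parameterized HRF at that oxygen level, and
#' their absolute deviation, both raw and rounded to two decimals (the
#' conventional reporting precision for HRF values).
#'
#' @param hrf_values Numeric vector of fitted HRF values (>= 1 each).
#' @param o2_percent The oxygen concentration the values were fitted at.
#' @param m,k_half Parameterization constants, see [hrf_from_oxygen()].
#' @return An object of class `hrf_deviation`: list with `mean_hrf`,
#'   `parameterized_hrf`, `abs_deviation`, `abs_deviation_rounded`,
#'   `n_values`, `o2_percent`.
#' @examples
#' hrf_deviation_report(c(1.60, 1.24, 1.09, 1.29, 1.28), o2_percent = 1)
#' @export
hrf_deviation_report <- function(hrf_values, o2_percent,
                                 m = 2.94, k_half = 0.129) {
  if (length(hrf_values) < 1L || !is.numeric(hrf_values))
    stop("'hrf_values' must contain at least one numeric value",
         call. = FALSE)
  mean_hrf <- mean(hrf_values)
  par_hrf <- hrf_from_oxygen(o2_percent, m = m, k_half = k_half)
  dev <- abs(mean_hrf - par_hrf)
  structure(
    list(mean_hrf = mean_hrf, parameterized_hrf = par_hrf,
         abs_deviation = dev, abs_deviation_rounded = round(dev, 2),
         n_values = length(hrf_values), o2_percent = o2_percent),
    class = "hrf_deviation"
  )
}

#' @export
print.hrf_deviation <- function(x, ...) {
  cat(sprintf("HRF deviation report at %g%% O2 (%d fitted values)\n",
              x$o2_percent, x$n_values))
  cat(sprintf("  mean fitted HRF:    %.4f\n", x$mean_hrf))
  cat(sprintf("  parameterized HRF:  %.4f\n", x$parameterized_hrf))
  cat(sprintf("  abs deviation:      %.4f (%.2f at 2 decimals)\n",
              x$abs_deviation, x$abs_deviation_rounded))
  invisible(x)
}

#' Published reference HRF estimates
#'
#' Fitted hypoxia reduction factors for five cell lines (A549, H460,
#' H1437, B16F10, Renca) at 1% and 0.5% oxygen, from a published
#' experimental characterisation. Used by the consistency check comparing
#' fitted HRFs against the oxygen parameterization.
#'
#' @return A data frame with columns `cell_line`, `o2_percent`, `hrf`.
#' @examples
#' ref <- hrf_reference()
#' hrf_deviation_report(ref$hrf[ref$o2_percent == 1], o2_percent = 1)
#' @export
hrf_reference <- function() {
  path <- system.file("extdata", "hrf_reference.csv", package = "loopsurv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
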