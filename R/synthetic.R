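#' Generate a synthetic clonogenic survival dataset
#'
#' Simulates a clonogenic assay from known ground-truth model parameters:
#' for each condition, dose and replicate, the surviving fraction is the
#' exact model curve multiplied by log-normal measurement noise,
#' `SF = S(D) * exp(eps)`, `eps ~ N(0, noise_sigma_log^2)`, truncated at
#' SF = 1. Clonogenic SF errors are approximately proportional to the SF,
#' which the multiplicative log-normal model captures. With
#' `noise_sigma_log = 0` the output equals the closed-form curve exactly.
#'
#' @param params A [gl_params()] object: the ground-truth cell line.
#' @param conditions Data frame describing the treatment contexts; columns
#'   (all optional): `o2_percent` (default 20), `hrf` (derived from
#'   `o2_percent` via [hrf_from_oxygen()] when absent; 1 under normoxia),
#'   `rsf` (default 1), `impairment_label` (default `"none"` when
#'   `rsf == 1`, else `"impaired"`), `drug_conc_nM` (default 0). One row
#'   per condition. Default: a single normoxic untreated condition.
#' @param doses Dose series in Gy; default `c(1, 2, 4, 8)`.
#' @param noise_sigma_log SD of the log-normal multiplicative noise;
#'   default 0.1.
#' @param n_replicates Replicate measurements per condition and dose;
#'   default 3 (the conventional clonogenic triplicate).
#' @param seed Optional integer seed.
#' @param cell_line Label written into the dataset.
#' @param collapse_replicates If `TRUE`, emit one record per condition and
#'   dose holding the replicate mean SF and its SEM (`sf_sem`); if `FALSE`
#'   (default), emit one record per replicate.
#' @return A `survival_dataset`. The generating parameters are attached as
#'   attribute `"truth"` (a list with `params` and the completed
#'   `conditions` table).
#' @examples
#' p <- gl_params(4e-3, 0.15)
#' d <- generate_dataset(p, noise_sigma_log = 0, seed = 1)
#' d$surviving_fraction
#' @export
generate_dataset <- function(params,
                             conditions = data.frame(o2_percent = 20),
                             doses = c(1, 2, 4, 8),
                             noise_sigma_log = 0.1,
                             n_replicates = 3,
                             seed = NULL,
                             cell_line = "SYN1",
                             collapse_replicates = FALSE) {
  stopifnot(inherits(params, "gl_params"), is.numeric(doses),
            noise_sigma_log >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  conditions <- .complete_conditions(conditions)

  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cnd <- conditions[i, ]
    adj <- condition_adjusted_params(params, hrf = cnd$hrf, rsf = cnd$rsf)
    s_true <- analytic_mean_survival(adj$params, doses, rsf = adj$rsf)
    for (j in seq_along(doses)) {
      eps <- if (noise_sigma_log > 0)
        stats::rnorm(n_replicates, 0, noise_sigma_log) else rep(0, n_replicates)
      sf <- pmin(1, s_true[j] * exp(eps))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line,
        o2_percent = cnd$o2_percent,
        impairment_label = cnd$impairment_label,
        drug_conc_nM = cnd$drug_conc_nM,
        dose_Gy = doses[j],
        replicate = seq_len(n_replicates),
        surviving_fraction = sf,
        sf_sem = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (collapse_replicates) {
    key <- interaction(out$o2_percent, out$impairment_label,
                       out$drug_conc_nM, out$dose_Gy, drop = TRUE)
    agg <- lapply(split(out, key), function(g) {
      g1 <- g[1, ]
      g1$replicate <- NA_integer_
      g1$surviving_fraction <- mean(g$surviving_fraction)
      g1$sf_sem <- if (nrow(g) > 1)
        stats::sd(g$surviving_fraction) / sqrt(nrow(g)) else NA_real_
      g1
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
  }
  out <- as_survival_dataset(out)
  attr(out, "truth") <- list(params = params, conditions = conditions)
  out
}

.complete_conditions <- function(conditions) {
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0L) stop("'conditions' is empty", call. = FALSE)
  if (is.null(conditions$o2_percent)) conditions$o2_percent <- 20
  if (is.null(conditions$hrf))
    conditions$hrf <- ifelse(conditions$o2_percent >= 20, 1,
                             hrf_from_oxygen(conditions$o2_percent))
  if (is.null(conditions$rsf)) conditions$rsf <- 1
  if (is.null(conditions$impairment_label))
    conditions$impairment_label <- ifelse(conditions$rsf == 1,
                                          "none", "impaired")
  if (is.null(conditions$drug_conc_nM)) conditions$drug_conc_nM <- 0
  stopifnot(all(conditions$hrf >= 1), all(conditions$rsf >= 1))
  conditions
}

#' Generate a full synthetic study campaign
#'
#' Emits one bundled synthetic dataset shaped like a complete experimental
#' campaign for the model: (a) five cell lines measured untreated at
#' normoxia and at 1% and 0.5% oxygen; (b) a wild-type line plus two
#' repair-deficient mutants, each at normoxia and deep hypoxia; (c) two
#' cell lines at three DDR-inhibitor concentrations under normoxia and 1%
#' oxygen, including the combined drug + hypoxia conditions. Ground-truth
#' parameters are drawn from realistic ranges for photon survival of
#' mammalian lines (`k_idsb` 1.5-5e-3, `k_cdsb` 0.13-0.26, HRF 1.1-2.5,
#' RSF 1.7-15), so the full three-stage workflow can be demonstrated and
#' audited end to end.
#'
#' @param seed Integer seed; identical seeds give identical campaigns.
#' @param noise_sigma_log Measurement noise SD in log space; default 0.1.
#' @param n_replicates Replicates per condition and dose; default 3.
#' @return A `survival_dataset` covering all panels; attribute `"truth"`
#'   is a data frame of the generating parameters, one row per cell line
#'   and condition.
#' @examples
#' camp <- synthetic_campaign(seed = 1)
#' head(attr(camp, "truth"))
#' @export
synthetic_campaign <- function(seed = 1, noise_sigma_log = 0.1,
                               n_replicates = 3) {
  set.seed(seed)
  pieces <- list()
  truth <- list()

  add_line <- function(name, conditions) {
    ki <- stats::runif(1, 1.5e-3, 5e-3)
    kc <- stats::runif(1, 0.13, 0.26)
    p <- gl_params(k_idsb = ki, k_cdsb = kc)
    d <- generate_dataset(p, conditions = conditions,
                          noise_sigma_log = noise_sigma_log,
                          n_replicates = n_replicates,
                          cell_line = name)
    pieces[[length(pieces) + 1L]] <<- d
    tr <- .complete_conditions(conditions)
    tr$cell_line <- name
    tr$k_idsb <- ki
    tr$k_cdsb <- kc
    truth[[length(truth) + 1L]] <<- tr
  }

  # (a) five lines x three oxygen levels, untreated
  for (nm in paste0("SYN-OX", 1:5)) {
    hrf1 <- stats::runif(1, 1.1, 1.7)
    hrf05 <- min(2.5, hrf1 + stats::runif(1, 0.1, 0.8))
    add_line(nm, data.frame(o2_percent = c(20, 1, 0.5),
                            hrf = c(1, hrf1, hrf05)))
  }

  # (b) wild type + two repair-deficient mutants, normoxia and deep hypoxia
  hrf_wt <- stats::runif(1, 2.0, 2.5)
  rsf_mut <- sort(stats::runif(2, 8, 15))
  add_line("SYN-WT", data.frame(
    o2_percent = c(20, 0.5, 20, 0.5, 20, 0.5),
    hrf = rep(c(1, hrf_wt), 3),
    rsf = rep(c(1, rsf_mut), each = 2),
    impairment_label = rep(c("none", "mutantA", "mutantB"), each = 2)))

  # (c) two lines x three inhibitor concentrations, normoxia and 1% O2
  for (nm in c("SYN-DRUG1", "SYN-DRUG2")) {
    hrf1 <- stats::runif(1, 1.1, 1.4)
    rsf_drug <- sort(stats::runif(3, 1.7, 4.5))
    conc <- c(100, 200, 500)
    add_line(nm, data.frame(
      o2_percent = rep(c(20, 1), 4),
      hrf = rep(c(1, hrf1), 4),
      rsf = rep(c(1, rsf_drug), each = 2),
      impairment_label = rep(c("none", rep("ATMi", 3)), each = 2),
      drug_conc_nM = rep(c(0, conc), each = 2)))
  }

  out <- do.call(rbind, pieces)
  out <- as_survival_dataset(out)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
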