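#' Model parameters of the giant-loop survival model
#'
#' Constructs the intrinsic parameter set of the giant-loop clustering model
#' of cell survival: the DSB induction rate, the nuclear DNA content, the
#' giant-loop size, and the two lesion-class lethality probabilities.
#'
#' The nucleus is divided into `dna_content / loop_size` equally sized
#' chromatin giant loops. A loop carrying exactly one double-strand break
#' (DSB) is an isolated lesion, lethal with probability `k_idsb`; a loop
#' carrying two or more DSBs is a complex lesion, lethal with probability
#' `k_cdsb`. `dna_content` must be an integer multiple of `loop_size`
#' (within a relative tolerance of 1e-6).
#'
#' @param k_idsb Lethality probability of an isolated DSB, in \[0, 1\].
#' @param k_cdsb Lethality probability of a complex DSB, in \[0, 1\].
#' @param alpha_dsb DSB induction rate, DSB/(Mbp\eqn{\cdot}Gy). Default
#'   5e-3, the accepted low-LET photon value.
#' @param dna_content Nuclear DNA content in Mbp. Default 6000 (6 Gbp).
#' @param loop_size Giant-loop DNA content in Mbp. Default 2.
#'
#' @return An object of class `gl_params`.
#' @examples
#' p <- gl_params(k_idsb = 4.83e-3, k_cdsb = 0.169)
#' loop_count(p)
#' expected_total_dsb(p, dose = 2)
#' @export
gl_params <- function(k_idsb = 0, k_cdsb = 0, alpha_dsb = 5e-3,
                      dna_content = 6000, loop_size = 2) {
  stopifnot(is.numeric(k_idsb), length(k_idsb) == 1L,
            is.numeric(k_cdsb), length(k_cdsb) == 1L,
            is.numeric(alpha_dsb), length(alpha_dsb) == 1L,
            is.numeric(dna_content), length(dna_content) == 1L,
            is.numeric(loop_size), length(loop_size) == 1L)
  if (!is.finite(alpha_dsb) || alpha_dsb <= 0)
    stop("'alpha_dsb' must be a positive finite number", call. = FALSE)
  if (!is.finite(dna_content) || dna_content <= 0)
    stop("'dna_content' must be a positive finite number", call. = FALSE)
  if (!is.finite(loop_size) || loop_size <= 0)
    stop("'loop_size' must be a positive finite number", call. = FALSE)
  if (k_idsb < 0 || k_idsb > 1)
    stop("'k_idsb' must be a probability in [0, 1]", call. = FALSE)
  if (k_cdsb < 0 || k_cdsb > 1)
    stop("'k_cdsb' must be a probability in [0, 1]", call. = FALSE)

  ratio <- dna_content / loop_size
  if (abs(ratio - round(ratio)) > 1e-6 * ratio)
    stop("'dna_content' must be an integer multiple of 'loop_size' ",
         "(got ratio ", format(ratio), ")", call. = FALSE)

  structure(
    list(alpha_dsb = alpha_dsb, dna_content = dna_content,
         loop_size = loop_size, k_idsb = k_idsb, k_cdsb = k_cdsb),
    class = "gl_params"
  )
}

#' @export
print.gl_params <- function(x, ...) {
  cat("Giant-loop survival model parameters\n")
  cat(sprintf("  alpha_dsb:   %g DSB/(Mbp*Gy)\n", x$alpha_dsb))
  cat(sprintf("  dna_content: %g Mbp (%d loops of %g Mbp)\n",
              x$dna_content, loop_count(x), x$loop_size))
  cat(sprintf("  k_idsb:      %g   k_cdsb: %g\n", x$k_idsb, x$k_cdsb))
  invisible(x)
}

#' Number of giant loops in the nucleus
#'
#' @param params A [gl_params()] object.
#' @return Integer count `dna_content / loop_size`.
#' @export
loop_count <- function(params) {
  stopifnot(inherits(params, "gl_params"))
  as.integer(round(params$dna_content / params$loop_size))
}

#' Expected total number of DSBs induced by a dose
#'
#' Mean DSB yield in the whole nucleus, `alpha_dsb * dose * dna_content`,
#' assuming homogeneous dose deposition (low-LET photons).
#'
#' @param params A [gl_params()] object.
#' @param dose Absorbed dose in Gy (vectorised, non-negative).
#' @return Expected DSB count(s), same length as `dose`.
#' @export
expected_total_dsb <- function(params, dose) {
  stopifnot(inherits(params, "gl_params"), is.numeric(dose))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("'dose' must be non-negative and finite", call. = FALSE)
  params$alpha_dsb * dose * params$dna_content
}
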