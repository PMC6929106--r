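# Reference parameter sets: realistic lethality / HRF / RSF values for
# photon survival of mammalian cell lines, spanning the range reported in
# experimental characterisations. Used as ground truth in recovery and
# correspondence tests.
ref_lines <- function() {
  list(
    lungA  = list(params = gl_params(4.83e-3, 0.169),
                  hrf = c(`1` = 1.60, `0.5` = 2.04), rsf = 1),
    lungB  = list(params = gl_params(3.28e-3, 0.241),
                  hrf = c(`1` = 1.24, `0.5` = 1.44),
                  rsf = c(1.73, 2.56, 4.21)),
    lungC  = list(params = gl_params(3.11e-3, 0.150),
                  hrf = c(`1` = 1.10), rsf = c(1.77, 2.52, 3.77)),
    melano = list(params = gl_params(4.05e-3, 0.134),
                  hrf = c(`1` = 1.29, `0.5` = 1.44), rsf = 1),
    renal  = list(params = gl_params(1.67e-3, 0.204),
                  hrf = c(`1` = 1.28, `0.5` = 1.67), rsf = 1),
    hamster = list(params = gl_params(4.38e-3, 0.233),
                   hrf = c(`0.5` = 2.44), rsf = c(9.60, 14.85))
  )
}

# small four-condition design used by several fitting tests
basic_conditions <- function(hrf = 1.6, rsf = 2.5) {
  data.frame(o2_percent = c(20, 1, 20, 1),
             hrf = c(1, hrf, 1, hrf),
             rsf = c(1, 1, rsf, rsf),
             impairment_label = c("none", "none", "drug", "drug"))
}
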