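Package: loopsurv
Title: Giant-Loop Clustering Model of Clonogenic Cell Survival under
    Hypoxia and DNA Repair Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic dose-response modelling of clonogenic cell survival
    after photon irradiation. DNA double-strand breaks (DSBs) induced in the
    nucleus are distributed over ~2 Mbp chromatin giant loops; loops carrying
    exactly one DSB (isolated lesions) or two and more DSBs (complex lesions)
    kill the cell with class-specific lethality probabilities. Hypoxia is
    modelled as a hypoxia reduction factor (HRF) dividing the DSB induction
    rate, and impaired DNA damage repair (mutants or DDR-inhibitor treatment)
    as a radiosensitization factor (RSF) multiplying the isolated-lesion
    lethality. The package provides Monte Carlo and exact closed-form
    evaluators of mean survival, a three-stage nonlinear least-squares
    workflow that estimates lethality parameters, HRF and RSF from survival
    curves and predicts their combined effect with no free parameters, a
    linear-quadratic low-dose correspondence, and a synthetic-data generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
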