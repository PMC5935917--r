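Package: rhpav
Title: Reactive Hyperemia Peripheral Arterial Volume Analysis from Finger Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of the reactive-hyperemia peripheral
    arterial volume (RH-PAV) index of endothelial function. Provides a
    Beer-Lambert optical simulator for two-channel finger
    photoplethysmography (PPG) sessions with a suprasystolic cuff-occlusion
    protocol, per-beat pulse-wave-amplitude extraction, the
    contralaterally-normalized RH-PAV and nitroglycerin-PAV indices,
    flow-mediated dilation (FMD) percent-change arithmetic, a binormal
    mixture cohort generator, and the statistics used to evaluate the
    index against FMD: Pearson and Spearman correlation, Welch t-test,
    empirical ROC curves with Youden-optimal cutoffs, and DeLong paired
    AUC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
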