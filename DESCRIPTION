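Package: binocmatch
Title: Binocular Matching Analysis of Thalamic and Intracortical Orientation Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for in vivo whole-cell recordings of visual
    cortical layer-4 neurons probed with drifting gratings through each eye.
    Preprocesses current-clamp (membrane potential) and voltage-clamp (EPSC)
    sweeps (spike removal, smoothing, cycle averaging, blank-stimulus
    baselines), decomposes total excitation into thalamic and intracortical
    components using optogenetic-silencing (LED-on) sweeps, computes
    vector-sum orientation statistics (gOSI, preferred orientation) and
    circular inter-ocular differences, and aggregates cohorts with a
    Kolmogorov-Smirnov, paired t and Pearson test battery. Includes a
    synthetic-recording generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
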