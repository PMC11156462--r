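Package: fesfatigue
Title: Muscle Fatigue Analysis for Voluntary and FES-Evoked Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise muscle fatigue from single-channel surface
    electromyography (sEMG) recorded during voluntary contraction and during
    functional electrical stimulation (FES). Implements Butterworth band-pass
    preprocessing, single-scale continuous wavelet separation of the evoked
    sEMG from the stimulation artifact, windowed root-mean-square (RMS)
    fatigue characteristic curves with min-max normalisation, power-law and
    polynomial curve fitting, segmentation of the FES response into the four
    M-wave stages, extraction of the maximum stimulation time, and fitting of
    the inverse-proportional relationship between stimulation current and
    maximum stimulation time. A synthetic-signal module generates voluntary
    and FES trials with planted, recoverable ground truth so that every stage
    of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
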