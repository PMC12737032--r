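Package: actisig
Title: Actigraphic Signal-Processing Pipelines and Their Effect on
    Sleep-Wake Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how manufacturer-dependent actigraphic
    signal processing alters sleep-wake-cycle analytics. Converts raw
    triaxial wrist acceleration into the generalized family of activity
    signals (preprocessing schemes UFM, UFNM, ENMO, FMpre, FMpost, HFMpre
    and per-axis variants; activity metrics PIM, ZCM, TAT, MAD, AI, HFEN)
    plus device-specific emulations (MotionWatch peak-sum, ActiGraph-style
    activity counts), derives nonparametric circadian rhythm indicators
    (L5, M10, RA, IS, IV) and sleep-wake scores (trend-threshold and
    z-angle algorithms), and compares pipelines through SMAPE, window
    overlap and Jaccard similarity matrices with complete-linkage
    dendrograms. A synthetic-recording generator with ground-truth sleep
    annotations makes every stage testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
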