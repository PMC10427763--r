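Package: twitchkit
Title: Optogenetic Myotube Contractility and Maturation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of light-paced skeletal myotube cultures.
    Computes displacement fields from time-lapse movies by multipass FFT
    cross-correlation particle image velocimetry (PIV) with window
    deformation, tracks nuclear reference points to single-cell displacement
    traces, and extracts twitch kinetics (amplitude, acceleration and
    relaxation phases, dominant frequency, contraction velocity, fatigue
    time). From fluorescence images it derives structural maturation
    metrics (myotube width by skeleton-normalized area, myonuclei density
    and spacing uniformity), classifies acetylcholine-receptor-positive
    nuclei from bungarotoxin intensity, measures receptor cluster shape,
    and counts single-molecule FISH spots in perinuclear regions. Includes
    a synthetic-data generator with exact ground truth for every assay and
    the accompanying statistical layer (ROUT outlier identification,
    unpaired t tests, Pearson correlation, 2^-ddCt fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
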