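Package: meioquant
Title: Quantification of Sperm-Content Dynamics in C. elegans Meiotic Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the movement of sperm contents, the
    scatter of paternal mitochondria, and capture of the sperm DNA by the
    meiotic spindle in C. elegans zygote imaging. Provides phase-segmented
    trajectory metrics for the sperm ER ring (maximum axis displacement,
    net displacement, path length, moving-average maximum velocity, phase
    duration), ROI-based fluorescence measurement with background
    correction and chromosome-to-cytoplasm ratios, an intensity-normalized
    multiplicity rule converting amorphous mitochondrial masses into
    weighted punctum-to-DNA distance distributions, a distance-threshold
    classifier for sperm/spindle capture events, and a normality-gated
    statistics layer (Shapiro-Wilk gate; Welch t / Welch ANOVA versus
    Mann-Whitney / Kruskal-Wallis; Brown-Forsythe; Fisher's exact test).
    A seeded synthetic-zygote generator produces ground-truthed image
    stacks and streaming trajectories so the whole pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    yaml,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
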