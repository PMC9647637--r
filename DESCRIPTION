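Package: tmefib
Title: Tumor Microenvironment Quantification of Tertiary Lymphoid
    Structures, TILs and Peritumoral Fibrillary Matrix in Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for quantifying tertiary lymphoid structures
    (TLS), tumor-infiltrating lymphocytes (TILs) and peritumoral fibrillary
    extracellular-matrix morphology from calibrated brightfield histology.
    Provides optical-density stain deconvolution, trainable pixel
    classification of the eosin channel, mask algebra for peritumoral
    stromal bands and TLS proximity classes, thirteen fibrillary
    morphometrics computed from skeletonized fiber masks (endpoints,
    branchpoints, hyphal growth unit, lacunarity, alignment coherence,
    fractal dimension and related measures), positive-pixel dual-chromogen
    IHC scoring, classical inference (Wald odds ratios, Fisher exact tests,
    Box-Cox transforms, random-intercept mixed models, Spearman screens,
    Mann-Whitney U), and hierarchical clustering on principal components
    with cluster characterization. A synthetic histology and cohort
    generator with ground truth makes every stage testable without slide
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    grDevices,
    utils,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
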