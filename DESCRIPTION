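Package: conemosaic
Title: Cone Photoreceptor Mosaic Metrics and Inter-Modality Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of the cone photoreceptor mosaic from retinal
    image coordinates, and agreement analysis between imaging modalities and
    graders. Implements bound Voronoi cone density, nearest-neighbor distance
    and intercell distance over co-localized regions of interest, linear image
    scale calculation from ocular biometry (retinal magnification factor and
    axial length), frame registration/averaging and semi-automated cone
    detection, a synthetic mosaic and two-modality image generator for
    end-to-end validation, and the statistical agreement layer (one-way
    intraclass correlation with F-based confidence intervals, Bland-Altman
    bias and limits of agreement, difference-versus-covariate regression,
    and minimum detectable difference power calculations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
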