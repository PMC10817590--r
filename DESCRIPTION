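Package: oculotex
Title: Interocular Retinal Texture Asymmetry Analysis from Layered OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates segmented optical coherence tomography (OCT) macular
    volumes with controllable per-layer reflectivity texture, projects each
    neuroretinal layer to a mean value fundus (MVF) image, extracts grey-level
    co-occurrence matrix (GLCM) texture features on a blockwise grid with
    foveal exclusion, and tests right-versus-left-eye feature differences per
    sex group using correlation-based feature decorrelation, normality-gated
    paired tests, and Bonferroni, Benjamini-Hochberg and Storey q-value
    corrections for multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
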