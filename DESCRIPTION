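Package: embad
Title: Distance Saturation, Horseshoe Diagnostics, and a Nonsaturating
    Earth Mover Distance for Ecological Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the horseshoe (Guttman) effect in
    ordinations of microbiome and other ecological gradient data. Simulates
    idealized band tables and Gaussian niche-gradient count tables, computes
    Euclidean, chi-squared, unweighted UniFrac and the nonsaturating Earth
    Mover Band Aware Distance (EMBAD) between samples, quantifies distance
    saturation along a gradient, estimates per-feature niche optima by
    abundance-weighted mean gradient and sorts tables into band form,
    performs PCA, principal-coordinate and correspondence analysis with an
    arch-curvature diagnostic, and compares metrics by single-factor
    PERMANOVA. Includes the centered log-ratio transform and plain-text
    readers and writers for feature tables, gradient metadata and Newick
    trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
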