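Package: ramansen
Title: Raman Spectral Fingerprinting of Autumnal Leaf Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Raman spectra of senescing deciduous
    leaves: a seeded synthetic-data generator for six senescence classes,
    spectral preprocessing (cosmic-ray removal, iterative polynomial
    baseline subtraction, range truncation, reference-peak normalisation),
    derived analytics (Simpson's-rule region areas, peak ratios, the
    cellulose crystallinity index, trend fits, RGB channel statistics),
    nonparametric group comparisons (Kruskal-Wallis with Dunn's post hoc),
    self-organising-map classification with a discriminant-index readout,
    comparator multivariate classifiers (PLS-DA with VIP scores, PCA plus
    k-means, random forests with out-of-bag error, permutation importance
    and proximity outliers), and filtering/matching of simulated
    chlorophyll-catabolite vibrational line lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
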