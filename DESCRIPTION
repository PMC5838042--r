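Package: stemspat
Title: Spatial Point-Pattern Analysis of Forest Stem Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the spatial structure of co-occurring tree
    species in mapped forest plots. Implements Ripley's K and the pair
    correlation function g(r) (univariate and bivariate) with isotropic
    edge correction, three null models (complete spatial randomness,
    heterogeneous Poisson with a kernel-estimated intensity surface, and
    random labeling in a case-control design), pointwise Monte-Carlo
    simulation envelopes with a squared-deviation goodness-of-fit test,
    difference statistics for comparing how two congeneric species relate
    to a shared heterospecific, neighborhood richness analysis, and
    basal-area Shannon and Simpson diversity indices. A synthetic stem-map
    generator (Thomas cluster processes, habitat gradients, shared-parent
    and thinning association links) emulates two-congener and
    three-congener study plots so the whole workflow is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
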