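Package: bnstrat
Title: Patient Stratification with Boolean Network Families Learned from
    Proteomics and Prior Knowledge Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates two treatment-response classes of patients (complete
    remission versus primary resistance) from continuous proteomics
    measurements and a signed prior knowledge network. Inputs are binarized by
    exact one-dimensional 2-means clustering and readouts are min-max
    normalized; an exact combinatorial search selects the protein set that
    maximizes the number of non-redundant cross-class patient couples with
    identical binarized input profiles (tie-broken by maximal readout
    divergence); per class, the family of all co-optimal Boolean networks
    (minimal mean squared error, then minimal size) is enumerated from the
    AND/OR hypergraph induced by the prior network; new patients are classified
    to the class whose family predictions best match their readouts. Includes
    a synthetic-data generator with planted class-specific ground-truth
    networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
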