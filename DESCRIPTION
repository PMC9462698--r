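Package: xcevo
Title: Symbolic Evolutionary Search for Exchange-Correlation Enhancement Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary symbolic regression of semilocal exchange-correlation
    density-functional forms. Enhancement factors (exchange, same-spin and
    opposite-spin correlation) are represented as short instruction programs
    operating on a workspace of features, parameters and variables; programs are
    mutated under regularized (aging) evolution with tournament selection, their
    scalar parameters are fitted by multi-restart CMA-ES against a weighted
    root-mean-square-deviation objective, and equivalent functional forms are
    deduplicated with a numeric fingerprint cache. Ships executable encodings of
    the B97, omegaB97M-V (semilocal part) and GAS22 enhancement factors, plus a
    synthetic-data generator so every stage of the search runs end-to-end
    without external datasets.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
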