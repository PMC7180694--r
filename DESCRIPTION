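Package: micfifld
Title: Concentration-Independent Subspace Learning and Iterative Fisher
    Discriminants for Electronic-Nose Drift Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transductive transfer learning for metal-oxide
    semiconductor (MOS) sensor arrays (electronic noses) whose signal
    distribution drifts with analyte concentration and with time.
    Implements MICF, a kernel subspace maximally independent of per-sample
    concentration-level features under the Hilbert-Schmidt Independence
    Criterion (HSIC), and IFLD, an EM-like iterative Fisher linear
    discriminant that refines pseudo-labels on unlabeled target batches.
    Includes readers for delimited feature tables and the libsvm-like
    dialect used by public gas-sensor drift archives, per-batch feature
    standardization, a configurable multi-batch drift simulator, and the
    train-on-first-batch evaluation protocol with per-batch accuracy
    accounting.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
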