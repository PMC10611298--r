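Package: fhecare
Title: Federated Homomorphic-Encryption Inference Simulator for Remote Healthcare
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A desk-scale simulator for privacy-preserving remote cardiac
    monitoring. Implements a torus fully homomorphic encryption (TFHE) core
    from first principles (TLWE/TGSW ciphertexts, gadget decomposition, key
    switching, accumulator bootstrapping with sample extraction), quantized
    encrypted inference for linear and shallow tree classifiers, the plaintext
    clinical modelling stack (UCI heart-disease schema preprocessing, balanced
    class weights, four standard classifiers, metric suite), seeded synthetic
    data generators, and a discrete-event simulation of a federated
    hospital network with three severity-driven job-scheduling modes.
    The cryptographic core is educational: no security level is claimed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    e1071,
    rpart,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
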