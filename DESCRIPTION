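Package: locspectra
Title: Subcellular Location Spectra of Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and comparing the subcellular location
    spectrum of a proteome: the composition vector giving the fraction of an
    organism's proteins native to each location class. Reads multi-source
    protein location annotation tables, projects heterogeneous label
    vocabularies onto a common seven-class scheme, quantifies multi-label
    agreement between annotation sources (including an analytic model of the
    apparent agreement when proteins occupy several locations), corrects
    predicted spectra for class-specific predictor error with row-normalized
    confusion matrices, compares organisms by Euclidean spectrum distance
    (UPGMA trees, PCA), clusters proteins into sequence families with the
    HSSP-curve distance (HVAL), transfers annotations by best-hit homology,
    and ships a fully seeded synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
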