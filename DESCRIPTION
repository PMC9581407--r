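Package: loopcallr
Title: Chromatin Loop Calling from Hi-C Contact Maps and Accessible
    Chromatin Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts chromatin loops genome-wide from an intra-chromosomal
    Hi-C contact matrix combined with a one-dimensional accessible-chromatin
    signal track. Labeled two-channel 23x23 windows (a contact sub-matrix and
    an accessibility outer-product matrix) centred on candidate bin pairs are
    classified by a compact convolutional network trained against orthogonal
    interaction evidence (ChIA-PET, HiChIP, Capture Hi-C anchors in BEDPE);
    candidate pixels are then filtered by contact frequency and classifier
    probability and pooled into representative loop calls. Includes
    distance-matched negative sampling, leave-one-chromosome-out training,
    aggregate peak analysis (APA), loop-set matching, distance profiling,
    binomial downsampling for robustness studies, and a synthetic-data
    generator so the full pipeline runs without external downloads. Readers
    and writers cover cool-dialect HDF5 containers, plain sparse-triplet
    text, bedGraph, bigWig and BEDPE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    GenomeInfoDb,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
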