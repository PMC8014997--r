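Package: tmtbridge
Title: Multi-Batch TMT Proteome Quantification with Reference-Pool Bridging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for multi-batch TMT10plex isobaric
    proteomics experiments that bridge batches with pooled reference
    channels. Implements peptide-spectrum-match filtering, sum scaling,
    reference-pool normalization, geometric-mean protein roll-up,
    parametric empirical-Bayes (ComBat-style) batch correction, a
    pool-normalized per-batch PCA distance statistic for comparing
    samples across batches without protein intersection, x-means/k-means
    clustering, differential abundance calling, and GO over-representation.
    Ships a synthetic-data generator emulating a 6-batch, 10-channel,
    two-participant saliva stimulation design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    sva
Config/testthat/edition: 3
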