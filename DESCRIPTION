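Package: cnsig
Title: Allele-Specific Copy Number Signatures of Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes allele-specific copy-number segment profiles into a
    48-channel catalogue defined by heterozygosity state, total copy number
    and segment size; extracts copy-number signatures by Poisson-resampled
    non-negative matrix factorization with replicate clustering and model
    selection; consolidates signatures across extractions and prunes linear
    combinations; attributes reference signatures to samples by penalized
    non-negative least squares; classifies whole-genome doubling from ploidy
    and loss-of-heterozygosity fraction and models doubling as a transform on
    signatures; maps attributed signatures back onto the genome with
    window-enrichment and region-association tests; and ships a
    copy-number-evolution simulator (segmental CIN, whole-genome doubling,
    chromothripsis, focal amplification) with ground-truth event logs for
    recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    pracma,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
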