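Package: ampdenoise
Title: Validation-Based Denoising of Multiplexed Amplicon Pyrosequencing Reads
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Removes PCR and pyrosequencing errors (substitutions,
    homopolymer indels and chimeras) from multiplexed amplicon read sets
    by validating sequences rather than correcting reads. Raw FASTA reads
    are demultiplexed by exact primer/MID match, binned into a unique
    sequence by sample abundance table, grouped by best-hit accession or
    single-linkage preclustering, and then validated in two passes: a
    cross-sample pass exploiting abundance distributions over replicates,
    and a within-sample pass applying explicit per-error-type read
    abundance thresholds derived from three-way alignments. A final
    replication-design threshold decides which sequences are retained.
    Includes a mock-community read simulator with ground truth for
    end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    yaml,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
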