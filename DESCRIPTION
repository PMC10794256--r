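Package: bdalign
Title: Biosynthetic Domain Architecture Alignment and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for comparing biosynthetic gene clusters (BGCs) by their
    biosynthetic domain architecture (BDA), the ordered sequence of
    biosynthetic domain labels extracted from a cluster's proteins. Reads
    antiSMASH-dialect GenBank regions and MIBiG-style JSON metadata into BGC
    records; applies contig-length filtering, region trimming, contig-edge
    flagging, and class mapping; builds a domain-to-domain scoring matrix
    from profile-HMM co-emission comparison; performs exact global alignment
    of domain-label sequences with zero gap penalties and computes M/N
    similarity; clusters BGCs by single-linkage at a similarity threshold and
    assigns hit/clustered/orphan status against characterized references;
    summarizes domain composition per class; and profiles transporter-gene
    enrichment in cluster-proximate regions with rank-sum tests. Includes a
    seeded synthetic-data generator (module-grammar BDAs, profile-HMM
    families with known homology structure, toy GenBank/JSON records,
    transporter layouts) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
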