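Package: oudphylo
Title: Alignment-Free k-mer Phylogenies from Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers phylogenies of assembled transcriptomes without
    alignments, using oligonucleotide usage deviation (OUD) signatures:
    observed k-mer counts compared to an i.i.d. mononucleotide null and
    normalized by the uniform expectation. Signatures are compared by
    Euclidean distance, trees built by UPGMA with bootstrap bipartition
    support obtained by resampling signature components. Supports three
    input modes (all transcripts, longest ORF per gene component, ORFs of
    genes shared across all strains), includes a six-frame stop-to-stop
    ORF extractor, assembly and read-retention statistics, gene-content
    partitioning across trophic groups, hypergeometric pathway enrichment
    with Benjamini-Hochberg adjustment, KEGG-style module completeness
    classification, and a synthetic-transcriptome simulator with a known
    tree for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    phangorn,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
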