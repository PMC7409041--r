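Package: viromics
Title: Viral Metagenome Abundance, Diversity and Contig-Sharing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico stages of two-site viral metagenome
    comparisons: per-ORF abundance by the transcripts-per-million (TPM)
    calculation, aggregation of gene abundances into taxonomic and functional
    profiles, alpha-diversity estimation (observed richness, Shannon, Chao1,
    evenness) on a TPM-derived surrogate count table, a 31-mer Jaccard
    procedure quantifying the sharing of taxonomically unassigned contig
    populations between sites, and virus-to-picoplankton summary statistics.
    Includes a synthetic two-site community generator with known ground truth
    so every stage is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
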