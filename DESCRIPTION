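Package: orthup
Title: Clustered Upstream Sequences of Orthologous Genes in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prepares input for phylogenetic footprinting of prokaryotic
    genomes. From a target genome and a set of reference genomes supplied as
    legacy NCBI bundles (protein FASTA, genome FASTA and PTT gene-coordinate
    tables), the package identifies orthologs by the bidirectional best hit
    criterion using a built-in Smith-Waterman protein aligner with
    Karlin-Altschul E-values (or externally computed tabular hits), predicts
    transcriptional units from intergenic distances, extracts length-bounded
    upstream regions, and writes one clustered-upstream FASTA file per target
    gene suitable for motif discovery tools. A deterministic synthetic-genome
    generator with planted ortholog families, operon structures and IUPAC
    motifs makes the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
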