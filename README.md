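# orthup

Prepares phylogenetic-footprinting input for prokaryotic genomes: from a
target genome and a set of reference genomes it identifies orthologs, infers
transcriptional units, and writes one FASTA file of clustered upstream DNA
sequences per target gene — the exact input that motif-discovery tools
(MEME, Gibbs samplers, MDScan, BioProspector) expect when hunting
cis-regulatory elements conserved across species.

The package is for microbial genomicists who have the classic NCBI genome
bundles (`.faa` protein FASTA, `.fna` genome FASTA, `.ptt` gene-coordinate
table) and want the whole ortholog-to-upstream pipeline in one deterministic,
scriptable step.

## Method in brief

For every protein *t* of the target genome and each reference genome, the
pipeline finds bidirectional best hits (BDBH): *t* and *r* are orthologs iff
each is the other's top-scoring hit. Scoring is full Smith–Waterman under
BLOSUM62 (gap open 11, extend 1) with Karlin–Altschul statistics

    bits = (λS − ln K) / ln 2,   E = m·n·2^(−bits)     (λ = 0.267, K = 0.041)

and a default cutoff E ≤ 1e−3; 12-column tabular hit files from an external
search tool can be substituted for the built-in aligner. Target genes with at
least `min_orthologs` (default 4) BDBH partners form ortholog groups
(tgCoGs). Each genome's gene list is then segmented into transcriptional
units — maximal same-strand runs whose internal intergenic gaps are below a
threshold (default 50 bp) — and for every group member with an upstream
intergenic gap of at least `min_up_length` (50 bp) the pipeline extracts up
to `max_up_length` (350 bp) immediately 5′ of the start codon,
reverse-complemented on the minus strand. Surviving sequences are clustered
per target gene into the `tu_upstreams/` output directory; group protein
sequences go to `tgCoG_protein_sequences/`.

A built-in synthetic-genome generator plants ortholog families, operon
structures and IUPAC motifs with full truth tables, so the entire pipeline is
testable without downloading anything.

## Worked example

```r
library(orthup)

# a seeded synthetic study set: 1 target + 4 references, 6 planted families
fx  <- generate_genome_set(default_fixture_spec(seed = 42L), "demo-genomes")
rep <- run_pipeline(
  target_dir     = fx$bundle_dirs[["target"]],
  reference_dirs = fx$bundle_dirs[names(fx$bundle_dirs) != "target"],
  settings       = default_settings(),
  outdir         = "demo-out"
)
rep
#> <run_report> target target vs 4 references
#>   target genes:       14
#>   ortholog groups:    3
#>   clusters written:   2
#>   below threshold:    3
#>   without orthologs:  8
#>   upstream exclusions: short_upstream=5
```

Fourteen target genes; the three families planted in all four references
pass the 4-ortholog threshold (3 ortholog groups); one of those is
operon-internal, so all five of its upstreams are excluded as too short and
two cluster files are written. Each file in `demo-out/tu_upstreams/` is named
by its target locus tag and holds one upstream per genome:

```r
up <- read_fasta(file.path("demo-out/tu_upstreams",
                           list.files("demo-out/tu_upstreams")[2]))
names(up)
#> [1] "target|tg0004|len=350" "ref1|r10002|len=350" "ref2|r20003|len=350"
#> [4] "ref3|r30001|len=326"   "ref4|r40004|len=350"
iupac_scan(up[[1]], "TTAGCACTCNNNNNNNNNGAGTGCTAA")
#> [1] 263
```

— every member of this family's cluster carries the planted HrcA-type
inverted repeat, which is what a motif-discovery tool pointed at this file
would find.

The same run is available from a shell:

```sh
Rscript inst/scripts/orthup-run.R --target demo-genomes/target \
    --refs demo-genomes/ref1,demo-genomes/ref2,demo-genomes/ref3,demo-genomes/ref4 \
    --settings inst/extdata/settings.txt --out demo-out
```

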