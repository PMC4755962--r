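---
title: "Methods: ortholog detection, transcription units and upstream clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog detection, transcription units and upstream clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthup)
```

## The problem

Phylogenetic footprinting finds cis-regulatory DNA elements as motifs
conserved among the upstream regions of orthologous genes in related
species. Motif discovery tools (MEME, Gibbs samplers, MDScan,
BioProspector) handle the second half of that task well; the first half —
calling orthologs for every gene of a target prokaryotic genome, deciding
which genes even have their own promoter region, and extracting comparable
upstream windows across a dozen genomes — is a tedious multi-step
procedure. `orthup` automates exactly that first half. Its input is the
legacy NCBI genome bundle (protein FASTA `.faa`, genome FASTA `.fna`,
gene-coordinate table `.ptt`) for a target genome and any number of
reference genomes; its output is one FASTA file of clustered upstream
sequences per qualifying target gene, ready to submit to any motif tool.

## Ortholog calling by bidirectional best hit

Two proteins t (target genome) and r (reference genome) are called
orthologs when each is the other's highest-scoring similarity hit — the
bidirectional best hit (BDBH) criterion. Hits come from an all-against-all
protein comparison per genome pair, in both directions.

The built-in comparator is a full Smith–Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $L$ costs
$11 + L$). No heuristic seeding is used: for the desk-scale genome sets
this package targets, exact alignment is affordable, and for real genome
scale the pipeline ingests precomputed 12-column tabular hit files from any
external search tool instead. The amino-acid alphabet is the 20 standard
residues plus `X`, which scores 0 against everything, so masked residues
can neither help nor hurt an alignment.

Raw scores $S$ are converted with the Karlin–Altschul parameters of gapped
BLOSUM62 ($\lambda = 0.267$, $K = 0.041$):

$$\text{bits} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-\text{bits}} = K\,m\,n\,e^{-\lambda S},$$

with $m$, $n$ the two sequence lengths. $K$ enters only once, through the
bit score; the search space is the raw product $m \cdot n$ with no
effective-length correction. That deliberately makes E-values slightly
conservative for short sequences, which is harmless here: BDBH uses only
the ranking and a coarse cutoff (default $E \le 10^{-3}$). The best hit is
ranked by bit score, with ties broken by ascending E-value and then
lexicographic subject identifier, so the top-hit map is deterministic
across platforms.

Per target gene, the BDBH partners across all references form an ortholog
group (a tgCoG). Groups with fewer than `min_orthologs` partners (default
4) are dropped; the target gene itself does not count toward the
threshold, so a passing group has at least five members. A reference gene
can be the partner of only one target gene by construction of the
reciprocal-best criterion; no further paralog resolution is attempted.

## Transcription units from intergenic distance

Prokaryotic operons are transcribed from the leader gene's promoter, so
the biologically meaningful upstream region of an operon-internal gene is
tiny or absent. The pipeline segments each genome's gene list (sorted by
start coordinate) into transcription units: a gene joins the unit of its
predecessor when both lie on the same strand and the intergenic gap
(`start − previous end − 1`, negative for overlapping genes) is below the
threshold. An opposite-strand gene always breaks a unit, because an
intervening divergently transcribed gene implies its own promoter region.
Every gene belongs to exactly one unit; the leader is the first member in
transcription direction (genomically last for minus-strand units).

The gap threshold defaults to `min_up_length` (50 bp). The reasoning: the
same 50 bp bound that excludes a gene's upstream from motif prediction as
too short is the natural bound below which a gene is operating as
operon-internal. The two values remain independently configurable
(`tu_gap_threshold`) for users who disagree.

Note one documented asymmetry: unit joining considers only the
*same-strand predecessor's* end, while the upstream gap used for
extraction (below) measures to the nearest gene boundary on *either*
strand. A gene squeezed against an opposite-strand neighbour starts its
own unit but can still be excluded for lack of upstream space.

## Upstream extraction and clustering

For every retained group, the pipeline resolves a representative gene per
member and extracts its upstream window:

* A member whose upstream intergenic gap is shorter than `min_up_length`
  (default 50 bp — published practice excludes upstreams under 40–50 bp
  from motif prediction) is excluded with reason `short_upstream`.
* Otherwise `fixed-window` mode (the default) takes the `max_up_length`
  (default 350 bp) bases immediately 5′ of the start codon, truncated at
  the contig edge; the window may overlap the upstream gene's coding
  sequence. `intergenic-only` mode instead takes
  `min(gap, max_up_length)` bases and never enters a neighbouring gene.
* Minus-strand windows are reverse-complemented so every emitted sequence
  reads 5′→3′ relative to its gene.

Under the default `representative_mode = "gene-self"` each member
contributes (or loses) its own upstream. The alternative `"tu-leader"`
maps operon-internal genes to their unit leader's upstream, which rescues
whole operons whose members would otherwise all be excluded; it is not the
default because the gene-self reading is the more literal interpretation
of the original procedure, but the comparison is one flag away.

Surviving members form one cluster per target gene, written as a FASTA
file named by the target locus tag (headers
`<genome_id>|<locus_tag>|len=<L>`) into `tu_upstreams/`, target first and
references in sorted genome order. Clusters with fewer than `min_members`
(default 2) members are not written — a single sequence is useless for
motif discovery — but every drop and every exclusion is recorded in
`manifest.tsv`, so the file counts always reconcile with the run report.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (the PTT convention);
  string slicing converts explicitly and is checked against an
  independent slicer in the tests.
* Genomes are treated as linear: windows truncate at position 1 and at
  the genome end, and wrap-around gene records (start > end) are rejected
  at parse time. Circular wrap-around extraction is deliberately not
  modelled; truncation is reproducible and affects at most the two genes
  nearest the origin.
* Biostrings' local aligner reports the best single-residue alignment
  even when negative; raw scores are clamped at 0 so the empty local
  alignment is always admissible.
* Non-ACGT nucleotides are folded to `N` on input, and a pattern position
  `N` in the IUPAC scanner matches A/C/G/T but never a subject `N`, so
  masked sequence cannot produce motif matches.
* All cross-genome iteration is in sorted (genome id, locus tag) order and
  the pipeline proper consumes no randomness, so repeated runs are
  byte-identical. The run report's `timings` field is the single
  exception (wall-clock), and determinism checks compare reports with
  timings stripped.

## The synthetic study set

`generate_genome_set()` builds a fully specified test bed from a seed: one
target plus `n_references` genomes, each populated with planted ortholog
families (a random 120-residue protein per family, copied into references
with independent per-site substitutions at the family's divergence),
per-genome random decoy proteins with no homolog anywhere, and an operon
layout whose intra-operon gaps (5–30 bp) and between-unit gaps
(100–400 bp) straddle the 50 bp threshold from opposite sides. Unit
strands are drawn at random so both extraction branches are always
exercised. Optionally a family plants an IUPAC motif — by default the
HrcA-type 9 bp inverted repeat `TTAGCACTC‑N9‑GAGTGCTAA` — at a random
offset inside every copy's upstream window, oriented with the gene.
Nucleotide coding sequences are back-generated from the proteins with one
fixed codon per residue: the pipeline never translates, so only the
reading-frame arithmetic has to be honest.

The default study set (`default_fixture_spec()`) is 4 references and 6
families at divergences 0.10–0.20 with presence counts {1, 2, 3, 4, 4, 4},
two of them operon-internal, plus 8 decoys per genome (~14 genes and
~9 kb per genome). These sizes keep the full suite — including exact
Smith–Waterman in both directions for every genome pair, run several
times — around twenty seconds on one CPU while still planting every
behaviour the pipeline must distinguish: families below and above the
ortholog threshold, leaders and internals, both strands, both window
modes and a recoverable motif.

What the generator does **not** emulate: indels and rearrangements (only
point substitutions), paralogs and gene families within a genome, codon
usage and GC bias, overlapping genes, multi-replicon genomes, or
annotation errors. Passing the planted-recovery tests therefore shows the
pipeline's logic is correct under its own assumptions, not that BDBH at
$E \le 10^{-3}$ is a good ortholog caller on hard real genomes — at
divergences far beyond 0.2, or among in-paralogs, reciprocal best hit has
well-known failure modes. Random decoy pairs can occasionally slip under
the E-value cutoff (the cutoff is, after all, an expectation of about
$10^{-3}$ false hits per pair and the decoy comparisons number in the
hundreds); such a pair can only ever form a one-reference group and is
removed by any ortholog-count threshold above 1.

## Worked example

```{r example}
fixture_dir <- file.path(tempdir(), "demo-genomes")
fx <- generate_genome_set(default_fixture_spec(seed = 42L), fixture_dir)

out <- file.path(tempdir(), "demo-out")
report <- run_pipeline(
  target_dir = fx$bundle_dirs[["target"]],
  reference_dirs = fx$bundle_dirs[names(fx$bundle_dirs) != "target"],
  settings = default_settings(),
  outdir = out, verbose = FALSE
)
report

# the motif family's cluster file, and the planted element inside it
motif_target <- unique(fx$truth$orthologs$target_locus[
  fx$truth$orthologs$family_id == "fam4"])
upstreams <- read_fasta(file.path(out, "tu_upstreams", motif_target))
vapply(upstreams, iupac_scan, integer(1),
       pattern = "TTAGCACTCNNNNNNNNNGAGTGCTAA")
```

Three of the six families are present in all four references and survive
`min_orthologs = 4`; of those, the operon-internal family loses all its
members to `short_upstream` exclusion under gene-self mode, so two cluster
files are written and the manifest accounts for the third.

## Known limitations

* The exact aligner is quadratic per pair; real bacterial proteomes
  (thousands of proteins) should use the external hit-table route.
* One replicon per genome; plasmids would need separate bundles and are
  not merged.
* The ortholog-count threshold is applied before upstream extraction, so
  a group can pass the threshold yet yield no cluster file once short
  upstreams are excluded; the manifest records why.
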