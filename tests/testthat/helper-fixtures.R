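# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# the default synthetic study set (seed fixed up front)
default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    td <- file.path(tempdir(), "orthup-fixture-default")
    .fixture_cache$fx <- generate_genome_set(default_fixture_spec(42L), td)
  }
  .fixture_cache$fx
}

fixture_genomes <- function() {
  if (is.null(.fixture_cache$genomes)) {
    fx <- default_fixture()
    .fixture_cache$genomes <- lapply(fx$bundle_dirs, read_genome_bundle)
  }
  .fixture_cache$genomes
}

# one full pipeline run on the default fixture at default settings
default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    fx <- default_fixture()
    out <- file.path(tempdir(), "orthup-run-default")
    report <- run_pipeline(
      fx$bundle_dirs[["target"]],
      fx$bundle_dirs[names(fx$bundle_dirs) != "target"],
      default_settings(), out, verbose = FALSE
    )
    .fixture_cache$run <- list(report = report, outdir = out)
  }
  .fixture_cache$run
}

# a bare annotated genome built in memory (no files, no proteins needed)
toy_genome <- function(genes, length_bp, genome_id = "toy",
                       residues = NULL) {
  if (is.null(residues)) {
    residues <- paste(rep("A", length_bp), collapse = "")
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(genome = genome_sequence(genome_id, residues),
         genes = genes,
         proteins = stats::setNames(character(), character()),
         link_stats = list()),
    class = "annotated_genome"
  )
}

toy_genes <- function(start, end, strand, locus_tag = NULL) {
  if (is.null(locus_tag)) locus_tag <- sprintf("g%02d", seq_along(start))
  data.frame(locus_tag = locus_tag, pid = as.character(seq_along(start)),
             start = as.integer(start), end = as.integer(end),
             strand = strand, product = "toy", stringsAsFactors = FALSE)
}

# random gene layout on a random genome, for property tests
random_layout <- function(n_genes, seed_len = 60L) {
  pos <- 1L
  start <- integer(n_genes); end <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    pos <- pos + sample(0:120, 1L)            # gaps incl. 0 (abutting)
    glen <- 3L * sample(10:40, 1L)
    start[i] <- pos + 1L; end[i] <- pos + glen
    pos <- end[i]
  }
  L <- end[n_genes] + sample(30:200, 1L)
  residues <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
  toy_genome(toy_genes(start, end,
                       sample(c("+", "-"), n_genes, replace = TRUE)),
             L, residues = residues)
}
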