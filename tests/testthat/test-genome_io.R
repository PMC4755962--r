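test_that("read_genome_fasta folds case, takes the first token as id, and rejects empty input", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(">chr1 some description", f)
  cat("acgt\n", file = f, append = TRUE)
  g <- read_genome_fasta(f)
  expect_s3_class(g, "genome_sequence")
  expect_identical(g$genome_id, "chr1")
  expect_identical(g$residues, "ACGT")
  expect_identical(g$length, 4L)

  empty <- withr::local_tempfile(fileext = ".fna")
  file.create(empty)
  expect_error(read_genome_fasta(empty))

  multi <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), multi)
  expect_warning(g2 <- read_genome_fasta(multi), "first")
  expect_identical(g2$residues, "ACGT")
})

test_that("non-ACGT residues are folded to N", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">x", "ACGRYTN"), f)
  expect_identical(read_genome_fasta(f)$residues, "ACGNNTN")
})

test_that("fixture genomes round-trip byte-identically through write_fasta + read", {
  fx <- default_fixture()
  for (gid in c("target", "ref1")) {
    g <- read_genome_fasta(file.path(fx$bundle_dirs[[gid]],
                                     paste0(gid, ".fna")))
    f <- withr::local_tempfile(fileext = ".fna")
    write_fasta(stats::setNames(g$residues, g$genome_id), f)
    expect_identical(read_fasta(f)[[1L]], g$residues)
  }
})

test_that("read_ptt parses well-formed rows and sorts by start", {
  f <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c(
    "Toy genome - 1..1000", "2 proteins",
    "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct",
    "400..500\t-\t33\t99\t-\tsll0002\t-\t-\tanother",
    "190..255\t+\t21\t1652342\t-\tsll0001\t-\t-\thypothetical"
  ), f)
  g <- read_ptt(f)
  expect_identical(g$locus_tag, c("sll0001", "sll0002"))
  expect_identical(g$start, c(190L, 400L))
  expect_identical(g$end, c(255L, 500L))
  expect_identical(g$strand, c("+", "-"))
  expect_identical(g$pid[1L], "1652342")
})

test_that("header-only PTT yields an empty gene table", {
  f <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c("desc", "0 proteins", "Location\tStrand\t..."), f)
  expect_identical(nrow(read_ptt(f)), 0L)
})

test_that("malformed PTT rows are dropped with a line-numbered warning", {
  f <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c(
    "desc", "3 proteins",
    "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct",
    "10..60\t+\t16\t1\t-\tok1\t-\t-\tp",
    "oops\t+\t5\t2\t-\tbad1\t-\t-\tp",
    "900..100\t-\t5\t3\t-\tbad2\t-\t-\tp"
  ), f)
  expect_warning(expect_warning(g <- read_ptt(f), "line 5"), "line 6")
  expect_identical(g$locus_tag, "ok1")
})

test_that("PTT round-trip preserves Location, Strand and Synonym exactly", {
  fx <- default_fixture()
  src <- file.path(fx$bundle_dirs[["ref2"]], "ref2.ptt")
  genes <- read_ptt(src)
  g <- read_genome_fasta(file.path(fx$bundle_dirs[["ref2"]], "ref2.fna"))
  f <- withr::local_tempfile(fileext = ".ptt")
  write_ptt(genes, g, f)
  back <- read_ptt(f)
  expect_identical(back$start, genes$start)
  expect_identical(back$end, genes$end)
  expect_identical(back$strand, genes$strand)
  expect_identical(back$locus_tag, genes$locus_tag)
})

test_that("link_annotations matches by PID first, then locus-tag fallback", {
  seq <- genome_sequence("g", paste(rep("A", 1000), collapse = ""))
  genes <- toy_genes(190, 255, "+", "sll0001")
  genes$pid <- "17228"
  prot <- data.frame(protein_id = "17228",
                     header = "gi|17228|ref|NP_1.1| hypothetical",
                     sequence = "MKL", stringsAsFactors = FALSE)
  ag <- link_annotations(seq, genes, prot)
  expect_identical(unname(ag$proteins["sll0001"]), "MKL")

  prot2 <- data.frame(protein_id = "lcl|sll0001",
                      header = "lcl|sll0001 hypothetical",
                      sequence = "MVV", stringsAsFactors = FALSE)
  genes2 <- toy_genes(190, 255, "+", "sll0001")   # pid does not match
  ag2 <- link_annotations(seq, genes2, prot2)
  expect_identical(unname(ag2$proteins["sll0001"]), "MVV")
})

test_that("link_annotations rejects out-of-bounds genes and mismatched bundles", {
  seq <- genome_sequence("g", "ACGTACGT")
  genes <- toy_genes(c(1, 4), c(3, 2000), c("+", "+"), c("a", "b"))
  genes$pid <- c("1", "2")
  prot <- data.frame(protein_id = c("1", "2"), header = c("gi|1|", "gi|2|"),
                     sequence = c("M", "K"), stringsAsFactors = FALSE)
  expect_warning(ag <- link_annotations(seq, genes, prot), "past the genome end")
  expect_identical(nrow(ag$genes), 1L)

  wrong <- data.frame(protein_id = "999", header = "gi|999| unrelated",
                      sequence = "W", stringsAsFactors = FALSE)
  expect_error(
    suppressWarnings(link_annotations(seq, toy_genes(1, 3, "+", "a"), wrong)),
    "same genome")
})

test_that("fixture bundles link completely: every protein to exactly one gene", {
  for (g in fixture_genomes()) {
    expect_identical(g$link_stats$n_orphan_genes, 0L)
    expect_identical(g$link_stats$n_orphan_proteins, 0L)
    expect_identical(length(g$proteins), nrow(g$genes))
    # planted CDS lengths are whole codons
    expect_true(all((g$genes$end - g$genes$start + 1L) %% 3L == 0L))
  }
})

test_that("write_fasta emits exact 70-column FASTA and rejects duplicate headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(a = "ACGT"), f)
  expect_identical(readLines(f), c(">a", "ACGT"))

  long <- paste(rep("A", 150), collapse = "")
  write_fasta(c(x = long), f)
  expect_identical(nchar(readLines(f))[2:3], c(70L, 70L))

  empty <- withr::local_tempfile(fileext = ".fa")
  write_fasta(stats::setNames(character(), character()), empty)
  expect_identical(file.size(empty), 0)

  expect_error(write_fasta(c(a = "AC", a = "GT"), f), "duplicate")
})

test_that("reverse complement is an involution on random nucleotide strings", {
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1L),
                      replace = TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_identical(revcomp("ACGTN"), "NACGT")
})
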