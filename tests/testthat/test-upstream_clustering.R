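test_that("extract_upstream slices forward and reverse-complement windows", {
  g <- toy_genome(toy_genes(7, 10, "+"), 10, residues = "AAAACGTTTT")
  u <- extract_upstream("g01", g, min_up = 1L, max_up = 6L)
  expect_identical(u$sequence, "AAAACG")
  expect_identical(u$span, c(1L, 6L))

  g2 <- toy_genome(toy_genes(1, 4, "-"), 10, residues = "AAAACGTTTT")
  u2 <- extract_upstream("g01", g2, min_up = 1L, max_up = 6L)
  expect_identical(u2$sequence, "AAAACG")   # revcomp of "CGTTTT"
  expect_identical(u2$span, c(5L, 10L))
})

test_that("genes with upstream gaps below min_up are excluded as short_upstream", {
  g <- toy_genome(toy_genes(c(10, 101), c(60, 160), c("+", "+")), 300)
  expect_identical(extract_upstream("g02", g, min_up = 50L, max_up = 350L),
                   "short_upstream")
  # gap of exactly min_up qualifies
  g2 <- toy_genome(toy_genes(c(10, 111), c(60, 170), c("+", "+")), 300)
  expect_s3_class(extract_upstream("g02", g2, min_up = 50L, max_up = 350L),
                  "upstream_sequence")
})

test_that("fixed windows may overlap the upstream gene; intergenic-only windows never do", {
  g <- toy_genome(toy_genes(c(10, 201), c(120, 290), c("+", "+")), 400)
  fixed <- extract_upstream("g02", g, min_up = 50L, max_up = 350L,
                            mode = "fixed-window")
  expect_identical(fixed$span, c(1L, 200L))   # truncated at contig edge
  expect_identical(fixed$length, 200L)
  inter <- extract_upstream("g02", g, min_up = 50L, max_up = 350L,
                            mode = "intergenic-only")
  expect_identical(inter$span, c(121L, 200L)) # gap of 80 only
  expect_identical(inter$length, 80L)
})

test_that("every emitted length obeys min_UP <= L <= max_UP and matches an independent slicer", {
  set.seed(47)
  for (i in 1:15) {
    g <- random_layout(sample(4:10, 1L))
    for (mode in c("fixed-window", "intergenic-only")) {
      for (locus in g$genes$locus_tag) {
        u <- extract_upstream(locus, g, min_up = 50L, max_up = 350L,
                              mode = mode)
        if (is.character(u)) {
          expect_true(u %in% c("short_upstream", "contig_edge"))
          next
        }
        expect_gte(u$length, 50L)
        expect_lte(u$length, 350L)
        expect_identical(nchar(u$sequence), u$length)
        expect_identical(u$sequence,
                         oracle_slice(g$genome$residues, u$span[1L],
                                      u$span[2L], u$strand))
      }
    }
  }
})

test_that("cluster_upstreams keeps one member per genome and records exclusions", {
  run <- default_run()
  fx <- default_fixture()
  genomes <- fixture_genomes()
  settings <- default_settings()
  tus <- lapply(genomes, predict_tus,
                gap_threshold = settings$tu_gap_threshold)
  per_ref <- list()
  tr <- fx$truth$orthologs
  for (r in unique(tr$reference_genome)) {
    sub <- tr[tr$reference_genome == r, ]
    per_ref[[r]] <- data.frame(target_locus = sub$target_locus,
                               reference_locus = sub$reference_locus,
                               stringsAsFactors = FALSE)
  }
  cogs <- build_cogs(per_ref, min_orthologs = 4L)
  clusters <- cluster_upstreams(cogs, genomes, "target", tus, settings)
  for (cl in clusters) {
    gids <- vapply(cl$members, `[[`, character(1), "genome_id")
    expect_identical(anyDuplicated(gids), 0L)
    expect_identical(length(cl$members) + length(cl$exclusions), 5L)
  }
  # the operon-internal family is excluded everywhere under gene-self
  internal_t <- unique(tr$target_locus[tr$family_id == "fam6"])
  cl6 <- clusters[[which(vapply(clusters, `[[`, character(1),
                                "target_locus") == internal_t)]]
  expect_length(cl6$members, 0L)
  expect_true(all(cl6$exclusions == "short_upstream"))
})

test_that("tu-leader mode rescues operon-internal genes via their leader's upstream", {
  fx <- default_fixture()
  genomes <- fixture_genomes()
  settings <- default_settings(representative_mode = "tu-leader")
  tus <- lapply(genomes, predict_tus,
                gap_threshold = settings$tu_gap_threshold)
  tr <- fx$truth$orthologs
  per_ref <- list()
  for (r in unique(tr$reference_genome)) {
    sub <- tr[tr$reference_genome == r, ]
    per_ref[[r]] <- data.frame(target_locus = sub$target_locus,
                               reference_locus = sub$reference_locus,
                               stringsAsFactors = FALSE)
  }
  cogs <- build_cogs(per_ref, min_orthologs = 4L)
  clusters <- cluster_upstreams(cogs, genomes, "target", tus, settings)
  internal_t <- unique(tr$target_locus[tr$family_id == "fam6"])
  cl6 <- clusters[[which(vapply(clusters, `[[`, character(1),
                                "target_locus") == internal_t)]]
  expect_identical(length(cl6$members), 5L)
})

test_that("write_clusters drops singleton clusters into the manifest, not onto disk", {
  u <- structure(list(genome_id = "target", locus_tag = "x1",
                      sequence = "ACGT", span = c(1L, 4L), strand = "+",
                      length = 4L), class = "upstream_sequence")
  clusters <- list(
    structure(list(target_locus = "x1", members = list(u),
                   exclusions = c("ref1|y1" = "short_upstream")),
              class = "cot_cluster"))
  out <- withr::local_tempdir()
  manifest <- write_clusters(clusters, out, min_members = 2L)
  expect_identical(manifest$status, "below_min_members")
  expect_false(file.exists(file.path(out, "x1")))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
})

test_that("cluster files carry genome|locus|len headers and in-bounds lengths", {
  run <- default_run()
  up_dir <- file.path(run$outdir, "tu_upstreams")
  files <- setdiff(list.files(up_dir), "manifest.tsv")
  expect_identical(length(files), run$report$n_clusters_written)
  for (f in files) {
    recs <- read_fasta(file.path(up_dir, f))
    parts <- strsplit(names(recs), "|", fixed = TRUE)
    lens <- as.integer(sub("^len=", "", vapply(parts, `[[`, character(1), 3L)))
    expect_identical(unname(nchar(recs)), lens)
    expect_true(all(lens >= 50L & lens <= 350L))
    gids <- vapply(parts, `[[`, character(1), 1L)
    expect_identical(anyDuplicated(gids), 0L)
    expect_identical(gids[1L], "target")
  }
})
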