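#' Run the full upstream-clustering pipeline
#'
#' Orchestrates the whole workflow: read the target and reference genome
#' bundles, score both search directions per reference (built-in aligner, or
#' precomputed 12-column tabular hit files), call bidirectional best hits,
#' assemble ortholog groups, predict transcription units, extract and
#' cluster upstream sequences. Creates `tgCoG_protein_sequences` and
#' `tu_upstreams` under `outdir` plus a machine-readable `report.json`. The
#' run is a pure function of the inputs and settings: all cross-genome
#' iteration is in sorted (genome id, locus tag) order and no randomness is
#' involved, so repeated runs produce byte-identical output trees.
#'
#' @param target_dir Directory with the target genome's `.faa`/`.fna`/`.ptt`.
#' @param reference_dirs Character vector of reference bundle directories.
#' @param settings A `pipeline_settings` object.
#' @param outdir Output directory (created if missing).
#' @param hit_tables_dir Optional directory of precomputed hit files named
#'   `<query_genome>__vs__<subject_genome>.tsv` (12-column tabular); when
#'   given, the built-in aligner is skipped.
#' @param verbose Emit one progress line per stage.
#' @return An object of class `run_report` (see Details), invisibly written
#'   to `<outdir>/report.json` as well.
#' @details The report carries `n_target_genes` (protein-coding genes in the
#'   target), `n_cogs` (ortholog groups passing the threshold),
#'   `n_clusters_written`, the reconciliation counts `n_below_threshold` and
#'   `n_no_orthologs` (so the four counts conserve:
#'   `n_target_genes = n_cogs + n_below_threshold + n_no_orthologs`),
#'   per-reason exclusion tallies from upstream extraction, the settings
#'   echo, and per-stage wall times under `timings` (the only
#'   non-deterministic field).
#' @export
run_pipeline <- function(target_dir, reference_dirs,
                         settings = default_settings(), outdir,
                         hit_tables_dir = NULL, verbose = TRUE) {
  if (length(reference_dirs) == 0L) stop("at least one reference genome is required")
  say <- function(...) if (verbose) message("[orthup] ", ...)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()

  target <- read_genome_bundle(target_dir)
  refs <- lapply(reference_dirs, read_genome_bundle)
  ref_ids <- vapply(refs, function(g) g$genome$genome_id, character(1))
  if (anyDuplicated(c(target$genome$genome_id, ref_ids))) {
    stop("duplicate genome ids across bundles")
  }
  names(refs) <- ref_ids
  refs <- refs[order(ref_ids, method = "radix")]
  target_id <- target$genome$genome_id
  genomes <- c(stats::setNames(list(target), target_id), refs)
  timings["read"] <- tic() - t0
  say("read ", length(genomes), " genome bundles; target '", target_id,
      "' has ", length(target$proteins), " proteins")

  t0 <- tic()
  get_hits <- function(q, s) {
    if (is.null(hit_tables_dir)) {
      search_proteomes(q, s, evalue_cutoff = settings$evalue_cutoff)
    } else {
      qid <- q$genome$genome_id; sid <- s$genome$genome_id
      f <- file.path(hit_tables_dir, paste0(qid, "__vs__", sid, ".tsv"))
      if (!file.exists(f)) stop("missing hit table '", f, "'")
      tab <- load_hit_table(f, qid, sid)
      tab$hits <- tab$hits[tab$hits$evalue <= settings$evalue_cutoff, ,
                           drop = FALSE]
      tab
    }
  }
  per_reference <- list()
  for (rid in names(refs)) {
    fwd <- get_hits(target, refs[[rid]])
    rev <- get_hits(refs[[rid]], target)
    per_reference[[rid]] <- bdbh_pairs(fwd, rev)
    say("reference ", rid, ": ", nrow(per_reference[[rid]]), " BDBH pairs")
  }
  timings["search_bdbh"] <- tic() - t0

  t0 <- tic()
  cogs <- build_cogs(per_reference, min_orthologs = settings$min_orthologs)
  cog_dir <- file.path(outdir, "tgCoG_protein_sequences")
  dir.create(cog_dir, recursive = TRUE, showWarnings = FALSE)
  write_cog_sequences(cogs, genomes, target_id, cog_dir)
  timings["cogs"] <- tic() - t0
  say(length(cogs), " ortholog groups with >= ", settings$min_orthologs,
      " orthologs (of ", attr(cogs, "n_candidates"), " candidates)")

  t0 <- tic()
  tus <- lapply(genomes, predict_tus, gap_threshold = settings$tu_gap_threshold)
  timings["tus"] <- tic() - t0
  say("predicted transcription units: ",
      paste(vapply(tus, length, integer(1)), collapse = "/"))

  t0 <- tic()
  clusters <- cluster_upstreams(cogs, genomes, target_id, tus, settings)
  up_dir <- file.path(outdir, "tu_upstreams")
  manifest <- write_clusters(clusters, up_dir,
                             min_members = settings$min_members)
  timings["upstreams"] <- tic() - t0

  excl <- unlist(lapply(clusters, `[[`, "exclusions"), use.names = FALSE)
  tallies <- if (length(excl) > 0L) {
    tab <- table(excl)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())

  n_target_genes <- length(target$proteins)
  n_candidates <- attr(cogs, "n_candidates")
  report <- structure(
    list(
      target_genome = target_id,
      reference_genomes = names(refs),
      n_target_genes = n_target_genes,
      n_cogs = length(cogs),
      n_clusters_written = sum(manifest$status == "written"),
      n_below_threshold = n_candidates - length(cogs),
      n_no_orthologs = n_target_genes - n_candidates,
      exclusion_tallies = as.list(tallies),
      settings = unclass(settings),
      timings = as.list(round(timings, 3))
    ),
    class = "run_report"
  )
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote ", report$n_clusters_written, " cluster files to ", up_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> target ", x$target_genome, " vs ",
      length(x$reference_genomes), " references\n", sep = "")
  cat("  target genes:      ", x$n_target_genes, "\n")
  cat("  ortholog groups:   ", x$n_cogs, "\n")
  cat("  clusters written:  ", x$n_clusters_written, "\n")
  cat("  below threshold:   ", x$n_below_threshold, "\n")
  cat("  without orthologs: ", x$n_no_orthologs, "\n")
  if (length(x$exclusion_tallies) > 0L) {
    cat("  upstream exclusions:",
        paste(names(x$exclusion_tallies), unlist(x$exclusion_tallies),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
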