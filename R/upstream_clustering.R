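#' Extract the upstream region of one gene
#'
#' Takes the sequence immediately 5' of the start codon in the gene's
#' transcription direction, reverse-complemented for minus-strand genes. A
#' gene whose upstream intergenic gap (see [upstream_gap()]) is shorter than
#' `min_up` is excluded with reason `"short_upstream"`.
#'
#' Two window modes are supported. `"fixed-window"` takes the `max_up` bases
#' immediately upstream regardless of the gap, so the window may run into the
#' neighbouring gene's coding sequence; it is truncated at the contig edge
#' and excluded with reason `"contig_edge"` if fewer than `min_up` bases
#' remain. `"intergenic-only"` takes `min(gap, max_up)` bases, never entering
#' a neighbouring gene.
#'
#' @param locus Locus tag.
#' @param genome An `annotated_genome`.
#' @param min_up Minimum acceptable upstream length (bp).
#' @param max_up Maximum extracted length (bp).
#' @param mode `"fixed-window"` or `"intergenic-only"`.
#' @return An `upstream_sequence` (list with `genome_id`, `locus_tag`,
#'   `sequence` 5'->3' relative to the gene, `span` = c(start, end) 1-based
#'   inclusive on the forward strand, `strand`, `length`), or a character
#'   scalar exclusion reason.
#' @export
extract_upstream <- function(locus, genome, min_up = 50L, max_up = 350L,
                             mode = c("fixed-window", "intergenic-only")) {
  mode <- match.arg(mode)
  stopifnot(min_up <= max_up, min_up > 0L)
  genes <- genome$genes
  i <- match(locus, genes$locus_tag)
  if (is.na(i)) stop("unknown locus '", locus, "'")
  gap <- upstream_gap(locus, genome)
  if (gap < min_up) return("short_upstream")
  L <- genome$genome$length
  w <- if (mode == "fixed-window") max_up else min(gap, max_up)
  if (genes$strand[i] == "+") {
    lo <- max(1L, genes$start[i] - w)
    hi <- genes$start[i] - 1L
  } else {
    lo <- genes$end[i] + 1L
    hi <- min(L, genes$end[i] + w)
  }
  len <- hi - lo + 1L
  if (len < min_up) return("contig_edge")
  s <- substr(genome$genome$residues, lo, hi)
  if (genes$strand[i] == "-") s <- revcomp(s)
  structure(
    list(genome_id = genome$genome$genome_id, locus_tag = locus,
         sequence = s, span = c(lo, hi), strand = genes$strand[i],
         length = len),
    class = "upstream_sequence"
  )
}

#' Cluster upstream sequences across ortholog groups (tgCoTs)
#'
#' For every ortholog group, resolves a representative gene per member (the
#' gene itself, or its transcription unit's leader under
#' `representative_mode = "tu-leader"`), extracts its upstream region and
#' assembles the surviving sequences into one cluster per target gene.
#' Per-member extraction failures become recorded exclusions, never errors.
#'
#' @param groups A `cog_list` from [build_cogs()].
#' @param genomes Named list of `annotated_genome` objects (by genome id).
#' @param target_genome_id Genome id of the target.
#' @param tus Named list (by genome id) of transcription-unit lists from
#'   [predict_tus()]; only consulted under `"tu-leader"`.
#' @param settings A [default_settings()] object (uses `min_up_length`,
#'   `max_up_length`, `representative_mode`, `window_mode`).
#' @return List of `cot_cluster` objects sorted by target locus, each with
#'   `target_locus`, `members` (list of `upstream_sequence`, target first
#'   then references in sorted genome order) and `exclusions` (named
#'   character, `"genome|locus"` -> reason).
#' @export
cluster_upstreams <- function(groups, genomes, target_genome_id, tus,
                              settings = default_settings()) {
  lapply(groups, function(grp) {
    genome_ids <- c(target_genome_id, names(grp$orthologs))
    loci <- c(grp$target_locus, unname(grp$orthologs))
    members <- list()
    exclusions <- character()
    for (k in seq_along(genome_ids)) {
      gid <- genome_ids[k]
      locus <- loci[k]
      rep_locus <- if (settings$representative_mode == "tu-leader") {
        tu_leader_of(locus, tus[[gid]])
      } else locus
      res <- extract_upstream(rep_locus, genomes[[gid]],
                              min_up = settings$min_up_length,
                              max_up = settings$max_up_length,
                              mode = settings$window_mode)
      if (is.character(res)) {
        exclusions[paste0(gid, "|", locus)] <- res
      } else {
        members[[length(members) + 1L]] <- res
      }
    }
    structure(
      list(target_locus = grp$target_locus, members = members,
           exclusions = exclusions),
      class = "cot_cluster"
    )
  })
}

#' Write clustered upstream sequences and a manifest
#'
#' Creates the `tu_upstreams` layout: one FASTA file per cluster with at
#' least `min_members` members, named after the target locus tag, with
#' record headers `<genome_id>|<locus_tag>|len=<L>`. A `manifest.tsv` in the
#' same directory accounts for every cluster (written or dropped) and its
#' exclusions, so totals reconcile.
#'
#' @param clusters List from [cluster_upstreams()].
#' @param outdir Output directory (created if missing).
#' @param min_members Minimum members for a cluster file to be written.
#' @return Invisibly, the manifest data frame.
#' @export
write_clusters <- function(clusters, outdir, min_members = 2L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  targets <- vapply(clusters, `[[`, character(1), "target_locus")
  if (anyDuplicated(targets)) {
    stop("duplicate cluster file names: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  rows <- lapply(clusters, function(cl) {
    n <- length(cl$members)
    status <- if (n >= min_members) "written" else "below_min_members"
    if (status == "written") {
      recs <- vapply(cl$members, function(u) u$sequence, character(1))
      names(recs) <- vapply(cl$members, function(u) {
        paste0(u$genome_id, "|", u$locus_tag, "|len=", u$length)
      }, character(1))
      write_fasta(recs, file.path(outdir, cl$target_locus))
    }
    data.frame(
      target_locus = cl$target_locus, n_members = n,
      n_excluded = length(cl$exclusions),
      reasons = paste(paste0(names(cl$exclusions), ":", cl$exclusions),
                      collapse = ";"),
      status = status, stringsAsFactors = FALSE
    )
  })
  manifest <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(target_locus = character(), n_members = integer(),
               n_excluded = integer(), reasons = character(),
               status = character(), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
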