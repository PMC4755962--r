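#' Upstream intergenic length of one gene
#'
#' Distance, in bp, between a gene's 5' boundary (in its transcription
#' direction) and the nearest annotated gene boundary upstream, on either
#' strand. For a plus-strand gene this is `start - 1 - max(end of genes
#' ending before start)`, or `start - 1` if no gene ends before it; for a
#' minus-strand gene, `min(start of genes starting after end) - end - 1`, or
#' `genome_length - end` if none. Overlapping neighbours clamp the result
#' at 0.
#'
#' @param locus Locus tag of a gene in `genome`.
#' @param genome An `annotated_genome`.
#' @return Non-negative integer gap in bp.
#' @export
upstream_gap <- function(locus, genome) {
  genes <- genome$genes
  i <- match(locus, genes$locus_tag)
  if (is.na(i)) stop("unknown locus '", locus, "' in ", genome$genome$genome_id)
  if (genes$strand[i] == "+") {
    prev_ends <- genes$end[genes$end < genes$start[i]]
    gap <- if (length(prev_ends) == 0L) genes$start[i] - 1L
           else genes$start[i] - 1L - max(prev_ends)
  } else {
    next_starts <- genes$start[genes$start > genes$end[i]]
    gap <- if (length(next_starts) == 0L) genome$genome$length - genes$end[i]
           else min(next_starts) - genes$end[i] - 1L
  }
  max(gap, 0L)
}

#' Predict transcriptional units from intergenic distance
#'
#' Segments the gene list (in genomic order) into maximal runs of consecutive
#' same-strand genes in which every internal intergenic gap is below
#' `gap_threshold`. An opposite-strand gene always breaks a run, and every
#' gene belongs to exactly one unit. The gap between consecutive run members
#' is `start - previous end - 1` (negative for overlapping genes, which
#' therefore always join).
#'
#' @param genome An `annotated_genome`.
#' @param gap_threshold Intergenic distance (bp) at or above which adjacent
#'   same-strand genes are split into separate units.
#' @return List of `transcription_unit` objects, each a list with
#'   `genome_id`, `member_loci` (5'->3' in transcription direction),
#'   `strand` and `leader_locus` (first member in transcription direction:
#'   first genomic member on `+`, last on `-`).
#' @export
predict_tus <- function(genome, gap_threshold = 50L) {
  stopifnot(gap_threshold >= 0L)
  genes <- genome$genes
  n <- nrow(genes)
  if (n == 0L) return(list())
  tu_id <- integer(n)
  tu_id[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    joins <- genes$strand[i] == genes$strand[i - 1L] &&
      (genes$start[i] - genes$end[i - 1L] - 1L) < gap_threshold
    tu_id[i] <- if (joins) tu_id[i - 1L] else tu_id[i - 1L] + 1L
  }
  lapply(split(seq_len(n), tu_id), function(idx) {
    strand <- genes$strand[idx[1L]]
    loci <- genes$locus_tag[idx]               # genomic order
    members <- if (strand == "+") loci else rev(loci)
    structure(
      list(genome_id = genome$genome$genome_id, member_loci = members,
           strand = strand, leader_locus = members[1L]),
      class = "transcription_unit"
    )
  })
}

#' Leader gene of the transcriptional unit containing a locus
#'
#' @param locus Locus tag.
#' @param tus Transcription-unit list from [predict_tus()].
#' @return The leader locus tag of the unit containing `locus`.
#' @export
tu_leader_of <- function(locus, tus) {
  for (tu in tus) {
    if (locus %in% tu$member_loci) return(tu$leader_locus)
  }
  stop("locus '", locus, "' is not a member of any transcription unit")
}

#' Flatten a transcription-unit list to a table
#'
#' One row per unit, suitable for TSV export.
#'
#' @param tus List from [predict_tus()].
#' @return Data frame with columns `genome_id`, `leader_locus`, `strand`,
#'   `n_members`, `members` (comma-joined, 5'->3').
#' @export
tus_to_table <- function(tus) {
  if (length(tus) == 0L) {
    return(data.frame(genome_id = character(), leader_locus = character(),
                      strand = character(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    genome_id = vapply(tus, `[[`, character(1), "genome_id"),
    leader_locus = vapply(tus, `[[`, character(1), "leader_locus"),
    strand = vapply(tus, `[[`, character(1), "strand"),
    n_members = vapply(tus, function(t) length(t$member_loci), integer(1)),
    members = vapply(tus, function(t) paste(t$member_loci, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
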