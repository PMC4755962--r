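#' Bidirectional best hits between a target and one reference genome
#'
#' A pair (t, r) is a bidirectional best hit (BDBH) when t's best hit in the
#' reference proteome is r and r's best hit in the target proteome is t. The
#' result is one-to-one in both coordinates: a reference gene can be the
#' partner of at most one target gene.
#'
#' @param forward `hit_table`, target -> reference, already E-value filtered.
#' @param reverse `hit_table`, reference -> target, same filtering.
#' @return Data frame with columns `target_locus`, `reference_locus`, sorted
#'   by `target_locus`.
#' @export
bdbh_pairs <- function(forward, reverse) {
  if (!identical(forward$query_genome, reverse$subject_genome) ||
      !identical(forward$subject_genome, reverse$query_genome)) {
    stop("hit tables are not a forward/reverse pair: ",
         forward$query_genome, "->", forward$subject_genome, " vs ",
         reverse$query_genome, "->", reverse$subject_genome)
  }
  f <- top_hit_per_query(forward)
  r <- top_hit_per_query(reverse)
  recip <- names(f)[!is.na(r[f]) & r[f] == names(f)]
  out <- data.frame(target_locus = recip,
                    reference_locus = unname(f[recip]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_locus, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-target-gene ortholog groups (tgCoGs)
#'
#' Collects, for every target gene, its BDBH partner in each reference genome
#' and keeps the genes with at least `min_orthologs` partners. The target
#' gene itself does not count toward the threshold: a group passing
#' `min_orthologs = 4` has at least five members including the target.
#'
#' @param per_reference Named list (name = reference genome id) of BDBH pair
#'   data frames as returned by [bdbh_pairs()].
#' @param min_orthologs Minimum number of reference genomes with an ortholog.
#' @return An object of class `cog_list`: a list of groups sorted by target
#'   locus, each a list with `target_locus`, `orthologs` (named character
#'   vector, reference genome id -> locus tag) and `count`. The attribute
#'   `n_candidates` records how many target genes had at least one partner.
#' @export
build_cogs <- function(per_reference, min_orthologs = 4L) {
  stopifnot(min_orthologs >= 1L)
  if (is.null(names(per_reference)) || any(!nzchar(names(per_reference)))) {
    stop("'per_reference' must be named by reference genome id")
  }
  by_target <- list()
  for (ref in sort(names(per_reference))) {
    p <- per_reference[[ref]]
    for (i in seq_len(nrow(p))) {
      t <- p$target_locus[i]
      by_target[[t]] <- c(by_target[[t]],
                          stats::setNames(p$reference_locus[i], ref))
    }
  }
  targets <- sort(names(by_target), method = "radix")
  groups <- lapply(targets, function(t) {
    orth <- by_target[[t]]
    orth <- orth[order(names(orth), method = "radix")]
    list(target_locus = t, orthologs = orth, count = length(orth))
  })
  keep <- vapply(groups, function(g) g$count >= min_orthologs, logical(1))
  structure(groups[keep], class = "cog_list",
            n_candidates = length(groups))
}

#' @export
print.cog_list <- function(x, ...) {
  cat("<cog_list> ", length(x), " ortholog groups (of ",
      attr(x, "n_candidates"), " target genes with >=1 ortholog)\n", sep = "")
  invisible(x)
}

#' Write one protein FASTA per ortholog group
#'
#' Creates the `tgCoG_protein_sequences` directory layout: one file per
#' group, named after the target locus tag, holding the target protein first
#' and then the orthologs in sorted reference-genome order, with headers
#' `<genome_id>|<locus_tag>`.
#'
#' @param groups A `cog_list`.
#' @param genomes Named list of `annotated_genome` objects (by genome id),
#'   including the target genome.
#' @param target_genome_id Genome id of the target.
#' @param outdir Directory to create files in (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cog_sequences <- function(groups, genomes, target_genome_id, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  resolve <- function(genome_id, locus) {
    g <- genomes[[genome_id]]
    if (is.null(g) || is.na(g$proteins[locus])) {
      stop("cannot resolve protein for ", genome_id, "|", locus,
           ": inconsistent pipeline state")
    }
    g$proteins[[locus]]
  }
  paths <- character(length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[[i]]
    ids <- c(paste0(target_genome_id, "|", grp$target_locus),
             paste0(names(grp$orthologs), "|", grp$orthologs))
    seqs <- c(resolve(target_genome_id, grp$target_locus),
              mapply(resolve, names(grp$orthologs), grp$orthologs))
    paths[i] <- file.path(outdir, grp$target_locus)
    write_fasta(stats::setNames(seqs, ids), paths[i])
  }
  invisible(paths)
}
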