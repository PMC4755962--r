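#' Scoring scheme for the built-in protein aligner
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' parameters used to turn raw Smith-Waterman scores into bit scores and
#' E-values. Defaults are the standard gapped BLOSUM62 values (gap open 11,
#' gap extend 1, lambda 0.267, K 0.041). A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix_name Substitution matrix name; only `"BLOSUM62"` is shipped.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty (positive, `<= gap_open`).
#' @param lambda Karlin-Altschul scale parameter.
#' @param k Karlin-Altschul prefactor.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, k = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0, lambda > 0, k > 0)
  structure(
    list(matrix_name = matrix_name, gap_open = gap_open,
         gap_extend = gap_extend, lambda = lambda, k = k,
         matrix = substitution_matrix(matrix_name)),
    class = "scoring_scheme"
  )
}

# 20 amino acids; X scores 0 against everything (including itself).
PROTEIN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V")

substitution_matrix <- function(name) {
  if (!identical(name, "BLOSUM62")) {
    stop("unknown substitution matrix '", name, "'")
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(PROTEIN_ALPHABET, "X")
  m <- m[keep, keep]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

check_protein <- function(s, what = "sequence") {
  if (!nzchar(s)) stop(what, " is empty")
  bad <- setdiff(strsplit(toupper(s), "")[[1L]], c(PROTEIN_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop(what, " contains characters outside the amino-acid alphabet: ",
         paste(unique(bad), collapse = ", "))
  }
  toupper(s)
}

bit_score_of <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$k)) / log(2)
}

evalue_of <- function(bit, m, n, scheme) {
  # raw m*n search space, no effective-length correction; K enters only
  # through the bit score (E = K m n exp(-lambda S) = m n 2^(-bits))
  m * n * 2^(-bit)
}

#' Score one pair of protein sequences
#'
#' Full Smith-Waterman local alignment under `scheme`; the raw score is
#' converted to a bit score `(lambda * S - ln K) / ln 2` and an E-value
#' `m * n * 2^(-bits)` where `m`, `n` are the two sequence lengths (no
#' effective-length correction; K is already absorbed in the bit score). An alignment in which no residue pair scores
#' positively has raw score 0 (the empty local alignment).
#'
#' @param a,b Amino-acid sequences (20-letter alphabet plus X).
#' @param scheme A [scoring_scheme()].
#' @return A one-row data frame with columns `raw_score`, `bit_score`,
#'   `evalue`.
#' @export
score_pair <- function(a, b, scheme = scoring_scheme()) {
  a <- check_protein(a, "sequence 'a'")
  b <- check_protein(b, "sequence 'b'")
  raw <- sw_scores(a, b, scheme)
  bit <- bit_score_of(raw, scheme)
  data.frame(raw_score = raw, bit_score = bit,
             evalue = evalue_of(bit, nchar(a), nchar(b), scheme))
}

# vectorised over `queries`; scores clamped at 0 so the empty local
# alignment is always admissible
sw_scores <- function(queries, subject, scheme) {
  s <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend,
    scoreOnly = TRUE
  )
  pmax(s, 0)
}

hit_table <- function(query_genome, subject_genome, hits) {
  if (identical(query_genome, subject_genome)) {
    stop("self-genome hit tables are not allowed (", query_genome, ")")
  }
  structure(
    list(query_genome = query_genome, subject_genome = subject_genome,
         hits = sort_hits(hits)),
    class = "hit_table"
  )
}

#' @export
print.hit_table <- function(x, ...) {
  cat("<hit_table> ", x$query_genome, " -> ", x$subject_genome, ": ",
      nrow(x$hits), " hits\n", sep = "")
  invisible(x)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             raw_score = numeric(), bit_score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# contract ordering: within each query, bit_score desc, evalue asc,
# subject_id lexicographic (C locale via a plain character sort key)
sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$bit_score, hits$evalue, hits$subject_id,
             method = "radix")
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' All-against-all similarity search between two proteomes
#'
#' Scores every query x subject protein pair with [score_pair()] and keeps the
#' hits with E-value at or below `evalue_cutoff`. Within each query, hits are
#' ordered by descending bit score, ties broken by ascending E-value then
#' lexicographic subject id.
#'
#' @param query,subject `annotated_genome` objects (their linked proteins are
#'   the proteomes; names are locus tags).
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff Retain hits with `evalue <= evalue_cutoff`.
#' @return A `hit_table`.
#' @export
search_proteomes <- function(query, subject, scheme = scoring_scheme(),
                             evalue_cutoff = 1e-3) {
  qseq <- query$proteins
  sseq <- subject$proteins
  if (length(qseq) == 0L || length(sseq) == 0L) {
    stop("both proteomes must be non-empty")
  }
  qlen <- nchar(qseq)
  out <- vector("list", length(sseq))
  for (j in seq_along(sseq)) {
    raw <- sw_scores(unname(qseq), sseq[[j]], scheme)
    bit <- bit_score_of(raw, scheme)
    ev <- evalue_of(bit, qlen, nchar(sseq[[j]]), scheme)
    keep <- ev <= evalue_cutoff
    if (any(keep)) {
      out[[j]] <- data.frame(
        query_id = names(qseq)[keep], subject_id = names(sseq)[j],
        raw_score = raw[keep], bit_score = bit[keep], evalue = ev[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  hits <- if (length(out) > 0L) do.call(rbind, out) else empty_hits()
  hit_table(query$genome$genome_id, subject$genome$genome_id, hits)
}

#' Read a 12-column tabular hit file
#'
#' Ingests the de-facto standard tabular layout (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore) as written by external search tools. Only columns 1, 2,
#' 11 and 12 are consumed; `raw_score` is left `NA`.
#'
#' @param path Path to the tabular file.
#' @param query_genome,subject_genome Genome ids for the two proteomes.
#' @return A `hit_table` with the same ordering contract as
#'   [search_proteomes()].
#' @export
load_hit_table <- function(path, query_genome, subject_genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(hit_table(query_genome, subject_genome, empty_hits()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("'", path, "' line ", which(nf != 12L)[1L],
         ": expected 12 tab-separated columns, got ", nf[nf != 12L][1L])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    raw_score = NA_real_,
    bit_score = as.numeric(m[, 12L]),
    evalue = as.numeric(m[, 11L]),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$bit_score) || anyNA(hits$evalue)) {
    stop("'", path, "': non-numeric evalue/bitscore field")
  }
  hit_table(query_genome, subject_genome, hits)
}

#' Write a hit table in the 12-column tabular layout
#'
#' Columns 3-10 (identity and alignment coordinates) are not tracked by the
#' built-in aligner and are written as zeros; only query, subject, evalue and
#' bitscore carry information.
#'
#' @param table A `hit_table`.
#' @param path Output path.
#' @export
write_hit_table <- function(table, path) {
  h <- table$hits
  lines <- if (nrow(h) == 0L) character() else paste(
    h$query_id, h$subject_id, "0.0", 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    format(h$evalue, scientific = TRUE, digits = 6),
    format(round(h$bit_score, 1), nsmall = 1, trim = TRUE),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Best subject per query
#'
#' Under the documented ordering (bit score desc, E-value asc, subject id
#' lexicographic) returns the first subject for every query with at least one
#' hit; queries without hits are absent from the map.
#'
#' @param table A `hit_table`.
#' @return Named character vector: query locus tag -> best subject locus tag.
#' @export
top_hit_per_query <- function(table) {
  h <- sort_hits(table$hits)
  if (nrow(h) == 0L) return(stats::setNames(character(), character()))
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}
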