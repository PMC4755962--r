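#' Read a genome nucleotide FASTA (.fna)
#'
#' Reads a single-record nucleotide FASTA file as used in legacy NCBI genome
#' bundles. Only the first record is used; a file with more than one record
#' raises a warning (concatenation of replicons is refused).
#'
#' @param path Path to a `.fna` file.
#' @return An object of class `genome_sequence`: a list with elements
#'   `genome_id` (first whitespace-delimited token of the header), `residues`
#'   (uppercase nucleotide string over A/C/G/T/N; any other letter is folded
#'   to N), `length` (bp) and `circular` (always `FALSE`; genomes are treated
#'   as linear).
#' @export
read_genome_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("no FASTA records in '", path, "'")
  }
  if (length(recs) > 1L) {
    warning("'", path, "' contains ", length(recs),
            " records; using the first only (multi-replicon bundles are not supported)")
  }
  header <- names(recs)[1L]
  residues <- toupper(as.character(recs[[1L]]))
  if (nchar(residues) == 0L) {
    stop("empty genome sequence in '", path, "'")
  }
  # ambiguity codes and anything non-ACGT are preserved as N
  residues <- gsub("[^ACGT]", "N", residues)
  genome_sequence(strsplit(header, "\\s+")[[1L]][1L], residues)
}

#' @rdname read_genome_fasta
#' @param genome_id Text label for the replicon.
#' @param residues Nucleotide string.
#' @export
genome_sequence <- function(genome_id, residues) {
  residues <- toupper(residues)
  stopifnot(nchar(residues) > 0L, grepl("^[ACGTN]+$", residues))
  structure(
    list(genome_id = genome_id, residues = residues,
         length = nchar(residues), circular = FALSE),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$genome_id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read a legacy NCBI PTT gene-coordinate table
#'
#' Parses the tab-separated PTT dialect: line 1 is the genome description,
#' line 2 "N proteins", line 3 the column header
#' (`Location Strand Length PID Gene Synonym Code COG Product`), then one row
#' per protein-coding gene with `Location` formatted `start..end` (1-based
#' inclusive coordinates).
#'
#' Malformed rows (bad `Location`, `start > end`, wrong field count) are
#' dropped with a warning that carries the line number; the `Length` column is
#' ignored and recomputed from the coordinates where needed. Wrap-around genes
#' crossing the origin are rejected.
#'
#' @param path Path to a `.ptt` file.
#' @return A data frame with columns `locus_tag` (PTT Synonym), `pid`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and `product`, sorted by `start`
#'   (ties broken by `end`).
#' @export
read_ptt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    stop("'", path, "' is not a PTT file (fewer than 3 header lines)")
  }
  body <- lines[-(1:3)]
  body_lineno <- seq_along(body) + 3L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_lineno <- body_lineno[keep]
  if (length(body) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_row <- function(f, lineno) {
    if (length(f) < 9L) {
      warning("PTT line ", lineno, ": expected 9 tab-separated fields, got ",
              length(f), "; row dropped")
      return(NULL)
    }
    loc <- regmatches(f[1L], regexec("^(\\d+)\\.\\.(\\d+)$", f[1L]))[[1L]]
    if (length(loc) != 3L) {
      warning("PTT line ", lineno, ": malformed Location '", f[1L], "'; row dropped")
      return(NULL)
    }
    start <- as.integer(loc[2L]); end <- as.integer(loc[3L])
    if (start > end) {
      warning("PTT line ", lineno, ": start > end (wrap-around genes are not supported); row dropped")
      return(NULL)
    }
    if (!f[2L] %in% c("+", "-")) {
      warning("PTT line ", lineno, ": bad strand '", f[2L], "'; row dropped")
      return(NULL)
    }
    data.frame(locus_tag = f[6L], pid = f[4L], start = start, end = end,
               strand = f[2L], product = f[9L], stringsAsFactors = FALSE)
  }
  rows <- mapply(parse_row, fields, body_lineno, SIMPLIFY = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(empty_gene_table())
  }
  genes <- do.call(rbind, rows)
  if (anyDuplicated(genes$locus_tag)) {
    stop("'", path, "': duplicated Synonym (locus_tag) entries")
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

empty_gene_table <- function() {
  data.frame(locus_tag = character(), pid = character(),
             start = integer(), end = integer(),
             strand = character(), product = character(),
             stringsAsFactors = FALSE)
}

#' Write a gene table in legacy NCBI PTT layout
#'
#' Inverse of [read_ptt()]: the `Location`, `Strand` and `Synonym` fields
#' round-trip exactly. The `Length` column is written as the conventional
#' amino-acid length `(end - start + 1) / 3 - 1`.
#'
#' @param genes Gene table as returned by [read_ptt()].
#' @param genome A `genome_sequence` (used for the description line).
#' @param path Output path.
#' @export
write_ptt <- function(genes, genome, path) {
  hdr <- c(
    paste0(genome$genome_id, " - 1..", genome$length),
    paste0(nrow(genes), " proteins"),
    paste("Location", "Strand", "Length", "PID", "Gene", "Synonym",
          "Code", "COG", "Product", sep = "\t")
  )
  rows <- if (nrow(genes) == 0L) character() else paste(
    paste0(genes$start, "..", genes$end), genes$strand,
    as.integer((genes$end - genes$start + 1L) / 3L) - 1L,
    genes$pid, "-", genes$locus_tag, "-", "-", genes$product,
    sep = "\t"
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a protein FASTA (.faa)
#'
#' @param path Path to a `.faa` file.
#' @return A data frame with columns `protein_id` (the `gi` number when the
#'   header follows the legacy `gi|NNN|ref|...|` layout, otherwise the first
#'   header token), `header` (full header) and `sequence` (uppercase amino
#'   acids).
#' @export
read_protein_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  seqs <- toupper(as.character(recs))
  gi <- regmatches(headers, regexec("gi\\|(\\d+)", headers))
  protein_id <- vapply(seq_along(headers), function(i) {
    if (length(gi[[i]]) == 2L) gi[[i]][2L] else strsplit(headers[i], "\\s+")[[1L]][1L]
  }, character(1))
  data.frame(protein_id = protein_id, header = headers, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Cross-link a genome sequence, gene table and proteome into one bundle
#'
#' Each protein is matched to a gene first by PID (the `gi` number of legacy
#' `.faa` headers against the PTT PID column), then by the gene's locus tag
#' occurring as a token in the FASTA header. Unmatched proteins and
#' protein-less genes are tallied; genes extending past the genome end are
#' rejected. Zero successful matches is treated as a mismatched bundle and is
#' fatal.
#'
#' @param seq A `genome_sequence`.
#' @param genes Gene table from [read_ptt()].
#' @param proteins Protein table from [read_protein_fasta()].
#' @return An `annotated_genome`: list with `genome` (the sequence), `genes`
#'   (gene table sorted by start), `proteins` (named character vector,
#'   locus_tag -> amino-acid sequence) and `link_stats` (match tallies).
#' @export
link_annotations <- function(seq, genes, proteins) {
  bad <- genes$end > seq$length
  if (any(bad)) {
    warning(sum(bad), " gene(s) extend past the genome end in '",
            seq$genome_id, "'; rejected")
    genes <- genes[!bad, , drop = FALSE]
  }
  prot_of <- rep(NA_character_, nrow(genes))
  names(prot_of) <- genes$locus_tag
  used <- logical(nrow(proteins))

  # pass 1: PID
  idx <- match(genes$pid, proteins$protein_id)
  hit <- !is.na(idx) & nzchar(genes$pid) & genes$pid != "-"
  prot_of[hit] <- proteins$sequence[idx[hit]]
  used[idx[hit]] <- TRUE

  # pass 2: locus_tag token in header, for still-unmatched genes
  open <- which(is.na(prot_of))
  if (length(open) > 0L && any(!used)) {
    free <- which(!used)
    for (i in open) {
      tag <- genes$locus_tag[i]
      m <- free[grepl(paste0("(^|[|[:space:]])", tag, "([|[:space:]]|$)"),
                      proteins$header[free], perl = TRUE)]
      if (length(m) >= 1L) {
        prot_of[i] <- proteins$sequence[m[1L]]
        used[m[1L]] <- TRUE
        free <- setdiff(free, m[1L])
      }
    }
  }

  n_linked <- sum(!is.na(prot_of))
  if (n_linked == 0L && (nrow(genes) > 0L || nrow(proteins) > 0L)) {
    stop("no protein could be linked to any gene in '", seq$genome_id,
         "': the .faa and .ptt files do not appear to describe the same genome")
  }
  stats <- list(n_genes = nrow(genes), n_proteins = nrow(proteins),
                n_linked = n_linked,
                n_orphan_genes = sum(is.na(prot_of)),
                n_orphan_proteins = sum(!used))
  if (stats$n_orphan_genes > 0L || stats$n_orphan_proteins > 0L) {
    message(seq$genome_id, ": ", stats$n_orphan_genes, " gene(s) without protein, ",
            stats$n_orphan_proteins, " protein(s) without gene")
  }
  structure(
    list(genome = seq, genes = genes,
         proteins = prot_of[!is.na(prot_of)],
         link_stats = stats),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$genome$genome_id, ": ", x$genome$length,
      " bp, ", nrow(x$genes), " genes, ", length(x$proteins),
      " linked proteins\n", sep = "")
  invisible(x)
}

#' Read one genome bundle directory
#'
#' The directory must hold exactly one `.faa`, one `.fna` and one `.ptt` file.
#'
#' @param dir Bundle directory.
#' @return An `annotated_genome` (see [link_annotations()]).
#' @export
read_genome_bundle <- function(dir) {
  one <- function(ext) {
    f <- list.files(dir, pattern = paste0("\\.", ext, "$"), full.names = TRUE)
    if (length(f) != 1L) {
      stop("directory '", dir, "' must contain exactly one .", ext,
           " file (found ", length(f), ")")
    }
    f
  }
  link_annotations(read_genome_fasta(one("fna")),
                   read_ptt(one("ptt")),
                   read_protein_fasta(one("faa")))
}

#' Write sequences as FASTA with 70-column wrapping
#'
#' @param records Named character vector: names are headers, values sequences.
#'   Record order is preserved; duplicate headers are an error.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all FASTA records must have a header")
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA headers: ",
         paste(unique(names(records)[duplicated(names(records))]), collapse = ", "))
  }
  x <- Biostrings::BStringSet(unname(as.character(records)))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read any FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector (header -> uppercase sequence).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(), character()))
  recs <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(recs)), names(recs))
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware (delegates to Biostrings); an involution on any nucleotide
#' string: `revcomp(revcomp(s)) == s`.
#'
#' @param s Nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}
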