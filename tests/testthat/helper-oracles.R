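# Independent oracles, deliberately implemented without touching the code
# paths they check.

# Quadratic-time Smith-Waterman with affine (Gotoh) gaps; a gap of length L
# costs open + L * ext. Pure R, no alignment library.
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
  A <- match(strsplit(a, "")[[1L]], rownames(mat))
  B <- match(strsplit(b, "")[[1L]], colnames(mat))
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force best subject per query under the documented tie chain:
# bit desc, evalue asc, subject_id lexicographic
oracle_top_hits <- function(hits) {
  out <- character()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    best <- h[1L, ]
    if (nrow(h) > 1L) {
      for (i in 2:nrow(h)) {
        better <- h$bit_score[i] > best$bit_score ||
          (h$bit_score[i] == best$bit_score && h$evalue[i] < best$evalue) ||
          (h$bit_score[i] == best$bit_score && h$evalue[i] == best$evalue &&
             h$subject_id[i] < best$subject_id)
        if (better) best <- h[i, ]
      }
    }
    out[q] <- best$subject_id
  }
  out
}

# brute-force reciprocity over all (query, subject) pairs
oracle_bdbh <- function(fwd_hits, rev_hits) {
  f <- oracle_top_hits(fwd_hits)
  r <- oracle_top_hits(rev_hits)
  pairs <- list()
  for (t in names(f)) {
    s <- f[[t]]
    if (s %in% names(r) && r[[s]] == t) {
      pairs[[length(pairs) + 1L]] <- c(t, s)
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(target_locus = character(),
                      reference_locus = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  out <- data.frame(target_locus = m[, 1L], reference_locus = m[, 2L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_locus, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force upstream intergenic gap by scanning every other gene
oracle_upstream_gap <- function(locus, genes, genome_length) {
  i <- which(genes$locus_tag == locus)
  if (genes$strand[i] == "+") {
    bound <- 0L
    for (j in seq_len(nrow(genes))) {
      if (genes$end[j] < genes$start[i] && genes$end[j] > bound) {
        bound <- genes$end[j]
      }
    }
    gap <- genes$start[i] - 1L - bound
  } else {
    bound <- genome_length + 1L
    for (j in seq_len(nrow(genes))) {
      if (genes$start[j] > genes$end[i] && genes$start[j] < bound) {
        bound <- genes$start[j]
      }
    }
    gap <- bound - genes$end[i] - 1L
  }
  max(gap, 0L)
}

# independent sequence slicer: substring plus a chartr-based reverse
# complement (no Biostrings)
oracle_slice <- function(residues, lo, hi, strand) {
  s <- substr(residues, lo, hi)
  if (strand == "-") {
    s <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
               collapse = "")
  }
  s
}

# random hit tables with deliberate bit-score ties to exercise the tie chain
random_hits <- function(n_q, n_s, qprefix = "q", sprefix = "s",
                        density = 0.5) {
  qs <- sprintf("%s%02d", qprefix, seq_len(n_q))
  ss <- sprintf("%s%02d", sprefix, seq_len(n_s))
  grid <- expand.grid(query_id = qs, subject_id = ss,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  n <- nrow(grid)
  if (n == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = grid$query_id, subject_id = grid$subject_id,
    raw_score = NA_real_,
    bit_score = sample(seq(20, 30, by = 2), n, replace = TRUE),
    evalue = sample(c(1e-8, 1e-6, 1e-4), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

make_hit_table <- function(query_genome, subject_genome, hits) {
  orthup:::hit_table(query_genome, subject_genome, hits)
}
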