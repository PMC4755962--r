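#' Specification of one planted ortholog family
#'
#' A family is a protein invented once (the target genome's copy) and planted
#' in the first `n_genomes_present` reference genomes as a point-mutated
#' homolog. Optionally, every copy carries an IUPAC motif planted in its
#' upstream region, and the gene can be placed as an operon leader or as an
#' operon-internal gene (which then has only a short upstream gap).
#'
#' @param family_id Short label.
#' @param n_genomes_present Number of reference genomes carrying the family
#'   (the target always carries it).
#' @param protein_length Length of the family protein in residues.
#' @param divergence Per-site substitution probability in the reference
#'   copies, in `[0, 0.5]`.
#' @param motif IUPAC pattern planted upstream of every copy, or `NULL`.
#' @param operon_position `"leader"` or `"internal"`.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, n_genomes_present, protein_length = 120L,
                        divergence = 0.1, motif = NULL,
                        operon_position = c("leader", "internal")) {
  operon_position <- match.arg(operon_position)
  stopifnot(n_genomes_present >= 0L, protein_length >= 10L,
            divergence >= 0, divergence <= 0.5)
  if (!is.null(motif)) check_iupac(motif)
  structure(
    list(family_id = family_id, n_genomes_present = as.integer(n_genomes_present),
         protein_length = as.integer(protein_length), divergence = divergence,
         motif = motif, operon_position = operon_position),
    class = "family_spec"
  )
}

#' Specification of a synthetic genome set
#'
#' Describes one target plus `n_references` reference genomes populated with
#' the planted families of [family_spec()], per-genome random decoy proteins
#' with no homolog anywhere, and an operon layout whose intra-operon gaps and
#' between-unit gaps are drawn from two disjoint ranges. Everything is
#' reproducible from `seed`.
#'
#' @param n_references Number of reference genomes.
#' @param families List of [family_spec()] objects.
#' @param n_decoys Random decoy proteins per genome.
#' @param decoy_protein_length Decoy length in residues.
#' @param intra_operon_gap_range Two-element bp range for gaps inside an
#'   operon (keep entirely below the TU gap threshold under test).
#' @param inter_tu_gap_range Two-element bp range for gaps between units
#'   (keep entirely above the minimum upstream length under test).
#' @param seed Integer seed driving all randomness.
#' @return A `genome_set_spec` list.
#' @export
genome_set_spec <- function(n_references, families, n_decoys = 8L,
                            decoy_protein_length = 120L,
                            intra_operon_gap_range = c(5L, 30L),
                            inter_tu_gap_range = c(100L, 400L),
                            seed = 42L) {
  stopifnot(n_references >= 1L, length(families) >= 1L,
            length(intra_operon_gap_range) == 2L,
            length(inter_tu_gap_range) == 2L,
            intra_operon_gap_range[1L] <= intra_operon_gap_range[2L],
            inter_tu_gap_range[1L] <= inter_tu_gap_range[2L],
            intra_operon_gap_range[2L] < inter_tu_gap_range[1L])
  for (f in families) {
    stopifnot(inherits(f, "family_spec"), f$n_genomes_present <= n_references)
    if (!is.null(f$motif) &&
        nchar(f$motif) > floor(inter_tu_gap_range[1L] / 2)) {
      stop("motif of family '", f$family_id,
           "' is longer than half the minimum between-unit gap; ",
           "it could not be planted inside every upstream window")
    }
  }
  n_internal <- sum(vapply(families, function(f)
    f$operon_position == "internal", logical(1)))
  if (n_decoys < n_internal) {
    stop("need at least ", n_internal,
         " decoys to serve as leaders of operon-internal families")
  }
  structure(
    list(n_references = as.integer(n_references), families = families,
         n_decoys = as.integer(n_decoys),
         decoy_protein_length = as.integer(decoy_protein_length),
         intra_operon_gap_range = as.integer(intra_operon_gap_range),
         inter_tu_gap_range = as.integer(inter_tu_gap_range),
         seed = as.integer(seed)),
    class = "genome_set_spec"
  )
}

#' Default synthetic study set
#'
#' The package's reference test bed: one target and four reference genomes
#' with six planted families whose presence counts are 1, 2, 3, 4, 4 and 4
#' references, divergences between 0.10 and 0.20, one family carrying the
#' HrcA-type inverted repeat `TTAGCACTC-N9-GAGTGCTAA` upstream of every copy
#' and two families placed operon-internally, plus eight random decoys per
#' genome. At the default threshold of four orthologs, exactly the three
#' families present in all four references form retained groups.
#'
#' @param seed Integer seed.
#' @return A `genome_set_spec`.
#' @export
default_fixture_spec <- function(seed = 42L) {
  genome_set_spec(
    n_references = 4L,
    families = list(
      family_spec("fam1", 1L, divergence = 0.10, operon_position = "leader"),
      family_spec("fam2", 2L, divergence = 0.15, operon_position = "leader"),
      family_spec("fam3", 3L, divergence = 0.10, operon_position = "internal"),
      family_spec("fam4", 4L, divergence = 0.20,
                  motif = "TTAGCACTCNNNNNNNNNGAGTGCTAA",
                  operon_position = "leader"),
      family_spec("fam5", 4L, divergence = 0.10, operon_position = "leader"),
      family_spec("fam6", 4L, divergence = 0.15, operon_position = "internal")
    ),
    seed = seed
  )
}

random_protein <- function(n) {
  paste(sample(PROTEIN_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Point-mutate a protein sequence
#'
#' Each site is independently substituted with probability `divergence` by a
#' residue drawn uniformly from the 19 other amino acids; length is
#' preserved. Uses R's global random number generator; seed beforehand for
#' reproducibility.
#'
#' @param sequence Amino-acid string.
#' @param divergence Per-site substitution probability in `[0, 0.5]`.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(sequence, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  chars <- strsplit(sequence, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < divergence)
  for (i in hit) {
    chars[i] <- sample(setdiff(PROTEIN_ALPHABET, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# one arbitrary fixed codon per amino acid; the pipeline never translates,
# so only the reading-frame arithmetic (length divisible by 3) matters
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

back_translate <- function(protein) {
  paste0("ATG", paste(CODON_OF[strsplit(protein, "")[[1L]]], collapse = ""), "TAA")
}

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

check_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in pattern: ", paste(unique(bad), collapse = ", "))
  }
  chars
}

#' Scan a nucleotide sequence for an IUPAC pattern
#'
#' Reports every (possibly overlapping) 1-based position at which the
#' degenerate pattern matches. A pattern `N` matches any of A/C/G/T but not
#' an ambiguity letter `N` in the subject, so masked regions are never
#' matched.
#'
#' @param sequence Nucleotide string.
#' @param pattern IUPAC pattern, e.g. `"TTAGCACTCNNNNNNNNNGAGTGCTAA"`.
#' @return Integer vector of 1-based match start positions.
#' @export
iupac_scan <- function(sequence, pattern) {
  chars <- check_iupac(pattern)
  if (nchar(sequence) < length(chars)) return(integer())
  rx <- paste0("(?=", paste(IUPAC_CLASS[chars], collapse = ""), ")")
  m <- gregexpr(rx, toupper(sequence), perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

# draw one concrete instance of a degenerate pattern
iupac_instantiate <- function(pattern) {
  chars <- check_iupac(pattern)
  paste(vapply(chars, function(c) {
    opts <- strsplit(gsub("[][]", "", IUPAC_CLASS[[c]]), "")[[1L]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate a synthetic genome set with planted truth
#'
#' Writes one bundle directory (`.faa`/`.fna`/`.ptt`) per genome under
#' `outdir`, named `target` and `ref1` ... `refN`, plus three truth tables:
#' `truth_orthologs.tsv` (planted target/reference gene pairs per family),
#' `truth_tus.tsv` (the planted transcription-unit partition of every
#' genome) and `truth_motifs.tsv` (pattern, concrete instance and genomic
#' position of every planted motif). Gene strands, operon order, gap widths,
#' decoy sequences and motif offsets are all drawn from R's generator seeded
#' with `spec$seed`, so reruns are byte-identical.
#'
#' @param spec A [genome_set_spec()].
#' @param outdir Directory to populate (created if missing).
#' @return Invisibly, a list with `bundle_dirs` (named by genome id),
#'   `truth` (the three truth data frames) and `spec`.
#' @export
generate_genome_set <- function(spec, outdir) {
  stopifnot(inherits(spec, "genome_set_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  fam_proteins <- lapply(spec$families, function(f) random_protein(f$protein_length))
  names(fam_proteins) <- vapply(spec$families, `[[`, character(1), "family_id")
  genome_ids <- c("target", sprintf("ref%d", seq_len(spec$n_references)))
  prefixes <- stats::setNames(
    c("tg", sprintf("r%d", seq_len(spec$n_references))), genome_ids)

  orth_rows <- list(); tu_rows <- list(); motif_rows <- list()
  fam_locus <- list()   # genome -> family -> locus
  bundle_dirs <- character()

  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    present <- if (gid == "target") seq_along(spec$families) else
      which(vapply(spec$families, function(f)
        (gi - 1L) <= f$n_genomes_present, logical(1)))

    # gene entries
    entries <- list()
    for (fi in present) {
      f <- spec$families[[fi]]
      prot <- if (gid == "target") fam_proteins[[f$family_id]] else
        mutate_protein(fam_proteins[[f$family_id]], f$divergence)
      entries[[length(entries) + 1L]] <- list(
        kind = "family", family_id = f$family_id, protein = prot,
        motif = f$motif, operon_position = f$operon_position)
    }
    for (d in seq_len(spec$n_decoys)) {
      entries[[length(entries) + 1L]] <- list(
        kind = "decoy", family_id = NA_character_,
        protein = random_protein(spec$decoy_protein_length),
        motif = NULL, operon_position = "leader")
    }

    # operon blueprint: internal families get a decoy leader; leader
    # families take a decoy follower while at least two decoys remain
    is_decoy <- vapply(entries, function(e) e$kind == "decoy", logical(1))
    pool <- which(is_decoy)
    tus <- list()
    for (i in which(!is_decoy)) {
      e <- entries[[i]]
      if (e$operon_position == "internal") {
        tus[[length(tus) + 1L]] <- c(pool[1L], i); pool <- pool[-1L]
      } else if (length(pool) > 2L) {
        tus[[length(tus) + 1L]] <- c(i, pool[1L]); pool <- pool[-1L]
      } else {
        tus[[length(tus) + 1L]] <- i
      }
    }
    for (i in pool) tus[[length(tus) + 1L]] <- i
    tus <- tus[sample(length(tus))]
    strands <- sample(c("+", "-"), length(tus), replace = TRUE)

    # layout: alternate between-unit gaps and unit bodies
    draw <- function(rng) sample(rng[1L]:rng[2L], 1L)
    parts <- character(); pos <- 0L
    placed <- list()   # per gene: entry idx, start, end, strand, tu index
    pending_left <- NULL  # motif to plant at the start of the next gap
    for (ti in seq_along(tus)) {
      gap_len <- draw(spec$inter_tu_gap_range)
      gap <- random_dna(gap_len)
      members <- tus[[ti]]
      strand <- strands[ti]
      leader_entry <- entries[[members[1L]]]  # members are in transcription order
      half <- floor(gap_len / 2)
      if (!is.null(pending_left)) {
        # minus-strand leader of the previous unit: its upstream reads
        # rightward from the unit end, so the reverse complement of the
        # instance goes at the left edge of this gap
        inst <- iupac_instantiate(pending_left$motif)
        w <- min(350L, half)
        d <- sample(0:(w - nchar(inst)), 1L)
        substr(gap, d + 1L, d + nchar(inst)) <- revcomp(inst)
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          genome_id = gid, locus_idx = pending_left$gene_idx,
          family_id = pending_left$family_id, pattern = pending_left$motif,
          instance = inst, genomic_start = pos + d + 1L, strand = "-",
          stringsAsFactors = FALSE)
        pending_left <- NULL
      }
      if (strand == "+" && leader_entry$kind == "family" &&
          !is.null(leader_entry$motif)) {
        inst <- iupac_instantiate(leader_entry$motif)
        w <- min(350L, half)
        d <- sample(0:(w - nchar(inst)), 1L)   # offset back from gap end
        s0 <- gap_len - d - nchar(inst) + 1L
        substr(gap, s0, s0 + nchar(inst) - 1L) <- inst
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          genome_id = gid, locus_idx = NA_integer_,
          family_id = leader_entry$family_id, pattern = leader_entry$motif,
          instance = inst, genomic_start = pos + s0, strand = "+",
          stringsAsFactors = FALSE)
        motif_pending_plus <- length(motif_rows)  # locus filled once placed
      } else motif_pending_plus <- NA_integer_
      parts[length(parts) + 1L] <- gap
      pos <- pos + gap_len

      # genomic order of members: transcription order for +, reversed for -
      genomic_members <- if (strand == "+") members else rev(members)
      for (mi in seq_along(genomic_members)) {
        if (mi > 1L) {
          ig <- draw(spec$intra_operon_gap_range)
          parts[length(parts) + 1L] <- random_dna(ig)
          pos <- pos + ig
        }
        e_idx <- genomic_members[mi]
        cds <- back_translate(entries[[e_idx]]$protein)
        if (strand == "-") cds <- revcomp(cds)
        placed[[length(placed) + 1L]] <- list(
          entry = e_idx, start = pos + 1L, end = pos + nchar(cds),
          strand = strand, tu = ti)
        parts[length(parts) + 1L] <- cds
        pos <- pos + nchar(cds)
        if (!is.na(motif_pending_plus) && strand == "+" && mi == 1L) {
          motif_rows[[motif_pending_plus]]$locus_idx <- length(placed)
        }
      }
      if (strand == "-" && leader_entry$kind == "family" &&
          !is.null(leader_entry$motif)) {
        pending_left <- list(motif = leader_entry$motif,
                             family_id = leader_entry$family_id,
                             gene_idx = length(placed))
      }
    }
    tail_len <- draw(spec$inter_tu_gap_range)
    tail <- random_dna(tail_len)
    if (!is.null(pending_left)) {
      inst <- iupac_instantiate(pending_left$motif)
      w <- min(350L, floor(tail_len / 2))
      d <- sample(0:(w - nchar(inst)), 1L)
      substr(tail, d + 1L, d + nchar(inst)) <- revcomp(inst)
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        genome_id = gid, locus_idx = pending_left$gene_idx,
        family_id = pending_left$family_id, pattern = pending_left$motif,
        instance = inst, genomic_start = pos + d + 1L, strand = "-",
        stringsAsFactors = FALSE)
    }
    parts[length(parts) + 1L] <- tail
    pos <- pos + tail_len
    residues <- paste(parts, collapse = "")

    # locus tags in genomic order (placement order is already genomic)
    loci <- sprintf("%s%04d", prefixes[gid], seq_along(placed))
    pids <- as.character(1000000L * gi + seq_along(placed))
    products <- vapply(placed, function(p) {
      e <- entries[[p$entry]]
      if (e$kind == "family") paste0("planted family ", e$family_id)
      else "synthetic decoy protein"
    }, character(1))
    genes <- data.frame(
      locus_tag = loci, pid = pids,
      start = vapply(placed, `[[`, integer(1), "start"),
      end = vapply(placed, `[[`, integer(1), "end"),
      strand = vapply(placed, `[[`, character(1), "strand"),
      product = products, stringsAsFactors = FALSE)

    # truth bookkeeping
    fam_locus[[gid]] <- list()
    for (k in seq_along(placed)) {
      e <- entries[[placed[[k]]$entry]]
      if (e$kind == "family") fam_locus[[gid]][[e$family_id]] <- loci[k]
      tu_rows[[length(tu_rows) + 1L]] <- data.frame(
        genome_id = gid, tu_index = placed[[k]]$tu, locus_tag = loci[k],
        strand = placed[[k]]$strand, stringsAsFactors = FALSE)
    }

    # write bundle
    bdir <- file.path(outdir, gid)
    dir.create(bdir, showWarnings = FALSE)
    gseq <- genome_sequence(gid, residues)
    write_fasta(stats::setNames(residues, paste0(gid, " synthetic genome")),
                file.path(bdir, paste0(gid, ".fna")))
    write_ptt(genes, gseq, file.path(bdir, paste0(gid, ".ptt")))
    headers <- sprintf("gi|%s|ref|%s.1| %s", pids, loci, products)
    prots <- vapply(placed, function(p) entries[[p$entry]]$protein, character(1))
    write_fasta(stats::setNames(prots, headers),
                file.path(bdir, paste0(gid, ".faa")))
    bundle_dirs[gid] <- bdir
  }

  for (f in spec$families) {
    for (r in seq_len(f$n_genomes_present)) {
      gid <- genome_ids[r + 1L]
      orth_rows[[length(orth_rows) + 1L]] <- data.frame(
        family_id = f$family_id,
        target_locus = fam_locus[["target"]][[f$family_id]],
        reference_genome = gid,
        reference_locus = fam_locus[[gid]][[f$family_id]],
        divergence = f$divergence,
        n_genomes_present = f$n_genomes_present,
        stringsAsFactors = FALSE)
    }
  }
  motif_truth <- if (length(motif_rows) > 0L) {
    m <- do.call(rbind, motif_rows)
    # resolve gene indices to locus tags
    m$locus_tag <- NA_character_
    for (i in seq_len(nrow(m))) {
      pre <- prefixes[m$genome_id[i]]
      m$locus_tag[i] <- sprintf("%s%04d", pre, m$locus_idx[i])
    }
    m[, c("genome_id", "locus_tag", "family_id", "pattern", "instance",
          "genomic_start", "strand")]
  } else data.frame()
  truth <- list(
    orthologs = do.call(rbind, orth_rows),
    tus = do.call(rbind, tu_rows),
    motifs = motif_truth
  )
  for (nm in names(truth)) {
    utils::write.table(truth[[nm]],
                       file.path(outdir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(bundle_dirs = bundle_dirs, truth = truth, spec = spec))
}
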