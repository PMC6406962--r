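#' Read a genome from FASTA
#'
#' Sequences are uppercased and U is mapped to T. Record names are truncated
#' at the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with a length index in `names()`.
#' @export
read_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) abort("empty FASTA file")
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) abort("duplicate sequence names in FASTA")
  seqs <- Biostrings::DNAStringSet(chartr("U", "T", toupper(as.character(raw))))
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

genome_slice <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Read and validate a somatic mutation table
#'
#' Reads a tab-separated table with header columns `sample`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `tissue`. Rows are validated against the genome:
#' the reference allele must match the genomic base, the site must lie at
#' least 60 bp from either contig end (so a full 121-bp neighborhood
#' exists), and the neighborhood must be free of ambiguous bases. Rejected
#' rows are reported, not silently dropped.
#'
#' @param path Path to the TSV (or a data frame already in that layout).
#' @param genome Genome from [read_genome()].
#' @return Tibble of accepted records with a `subclass` column; the
#'   rejection report is attached as attribute `"rejected"` and retrievable
#'   with [rejection_report()].
#' @export
read_mutations <- function(path, genome) {
  tbl <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      pos = readr::col_double(),
                      .default = readr::col_character()
                    ))
  }
  required <- c("sample", "chrom", "pos", "ref", "alt", "tissue")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  tbl <- dplyr::mutate(tbl, pos = as.integer(.data$pos), row = dplyr::row_number())
  reason <- rep(NA_character_, nrow(tbl))

  ok_alleles <- tbl$ref %in% BASES & tbl$alt %in% BASES & tbl$ref != tbl$alt
  reason[!ok_alleles] <- "bad_alleles"

  known <- tbl$chrom %in% names(genome)
  reason[is.na(reason) & !known] <- "unknown_chrom"

  lens <- setNames(Biostrings::width(genome), names(genome))
  idx <- which(is.na(reason))
  if (length(idx) > 0) {
    clen <- lens[tbl$chrom[idx]]
    edge <- tbl$pos[idx] <= CENTER_OFFSET | tbl$pos[idx] > clen - CENTER_OFFSET
    reason[idx[edge]] <- "edge"
  }
  idx <- which(is.na(reason))
  for (ch in unique(tbl$chrom[idx])) {
    s <- as.character(genome[[ch]])
    j <- idx[tbl$chrom[idx] == ch]
    base_j <- substring(s, tbl$pos[j], tbl$pos[j])
    mism <- base_j != tbl$ref[j]
    reason[j[mism]] <- "ref_mismatch"
    nb_j <- substring(s, tbl$pos[j] - CENTER_OFFSET, tbl$pos[j] + CENTER_OFFSET)
    amb <- !mism & grepl("[^ACGT]", nb_j)
    reason[j[amb]] <- "ambiguous_context"
  }

  rejected <- tbl[!is.na(reason), ] |>
    dplyr::mutate(reason = reason[!is.na(reason)]) |>
    dplyr::select("row", dplyr::all_of(required), "reason")
  accepted <- tbl[is.na(reason), ] |>
    dplyr::mutate(subclass = classify_substitution(.data$ref, .data$alt)) |>
    dplyr::select(dplyr::all_of(required), "subclass")
  if (nrow(rejected) > 0) {
    rlang::inform(paste0("rejected ", nrow(rejected), " of ", nrow(tbl),
                         " rows (",
                         paste(sprintf("%s: %d", names(table(rejected$reason)),
                                       as.integer(table(rejected$reason))),
                               collapse = ", "), ")"))
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' @rdname read_mutations
#' @param records A table returned by [read_mutations()].
#' @export
rejection_report <- function(records) {
  attr(records, "rejected") %||% tibble()
}

#' Write a mutation table to TSV
#'
#' @param records Mutation tibble.
#' @param path Output path.
#' @export
write_mutations <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Export analyzed sites as BED (0-based half-open)
#'
#' @param records Mutation tibble.
#' @param path Output path.
#' @export
export_sites_bed <- function(records, path) {
  bed <- tibble(chrom = records$chrom, start = records$pos - 1L,
                end = records$pos,
                name = paste0(records$ref, ">", records$alt))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Extract strand-normalized context windows for mutation records
#'
#' Returns the 11-mer around each mutated base. Sites with reference G are
#' reverse-complemented so the center is always C, recording the origin
#' strand as "-".
#'
#' @param records Mutation tibble (columns `chrom`, `pos`, `ref`).
#' @param genome Genome from [read_genome()].
#' @param halfwidth Flank size on each side of the mutated base.
#' @return The records tibble with added `window` and `strand` columns.
#' @export
extract_windows <- function(records, genome, halfwidth = 5) {
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, window = character(0), strand = character(0)))
  }
  win <- character(nrow(records))
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    s <- as.character(genome[[ch]])
    win[i] <- substring(s, records$pos[i] - halfwidth, records$pos[i] + halfwidth)
  }
  if (any(grepl("[^ACGT]", win))) abort("ambiguous context")
  flip <- records$ref == "G"
  win[flip] <- revcomp(win[flip])
  dplyr::mutate(records, window = win, strand = ifelse(flip, "-", "+"))
}

#' @rdname extract_windows
#' @param chrom,pos,ref Coordinates and reference allele of one site.
#' @export
extract_window <- function(genome, chrom, pos, ref, halfwidth = 5) {
  rec <- tibble(chrom = chrom, pos = as.integer(pos), ref = ref)
  out <- extract_windows(rec, genome, halfwidth)
  structure(out$window, strand = out$strand)
}

#' Extract the 121-bp DNA neighborhood of a mutation
#'
#' @param genome Genome.
#' @param chrom,pos Site coordinates (1-based).
#' @return Character scalar of length 121 with the mutated base at offset
#'   60 (0-based). Errors for sites within 60 bp of a contig end.
#' @export
extract_neighborhood <- function(genome, chrom, pos) {
  len <- Biostrings::width(genome[chrom])
  if (pos <= CENTER_OFFSET || pos > len - CENTER_OFFSET) {
    abort("edge: site within 60 bp of a contig end")
  }
  genome_slice(genome, chrom, pos - CENTER_OFFSET, pos + CENTER_OFFSET)
}

#' Eligible background sites of a neighborhood
#'
#' Offsets (0-based) of every C and G in the 121-mer whose full +/-5 context
#' lies inside the neighborhood (offsets 5..115), excluding the mutated
#' center at offset 60. G sites are later scored on the reverse complement.
#'
#' @param neighborhood 121-base character scalar.
#' @return Integer vector of offsets (possibly empty).
#' @export
eligible_background_sites <- function(neighborhood) {
  stopifnot(nchar(neighborhood) == NEIGHBORHOOD_LEN)
  chars <- strsplit(neighborhood, "", fixed = TRUE)[[1]]
  off <- which(chars %in% c("C", "G")) - 1L
  off[off >= 5L & off <= 115L & off != CENTER_OFFSET]
}

# Strand-normalized 11-mer windows at given neighborhood offsets.
neighborhood_windows <- function(neighborhood, offsets) {
  if (length(offsets) == 0) return(character(0))
  start <- offsets - 5L + 1L
  win <- substring(neighborhood, start, start + 10L)
  center <- substring(win, 6, 6)
  flip <- center == "G"
  win[flip] <- revcomp(win[flip])
  win
}

#' Shuffle the flanks of context windows
#'
#' Permutes the 10 flanking bases of each window independently, keeping the
#' central mutated base fixed, so each sequence retains its own base
#' composition ("pseudo-mutable motif" construction).
#'
#' @param windows Character vector of 11-mers.
#' @return Character vector of shuffled windows. Uses the current RNG
#'   state; seed with [set.seed()] or [withr::with_seed()] for
#'   reproducibility.
#' @export
shuffle_context <- function(windows) {
  assert_windows(windows)
  vapply(windows, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]]
    flanks <- ch[-6]
    perm <- sample(flanks, length(flanks))
    paste(c(perm[1:5], ch[6], perm[6:10]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

genome_composition <- function(windows) {
  m <- window_char_matrix(windows)
  tab <- tabulate(match(m, BASES), 4L)
  setNames(tab / sum(tab), BASES)
}

#' Sample composition-matched random context windows from a genome
#'
#' Draws strand-normalized C-centered 11-mers at random C/G genomic sites
#' and refines the draw by improving swaps until the sampled set matches
#' the template set's mononucleotide composition within `tol` per base and
#' a two-tailed t-test on per-window A+T fraction shows no significant
#' difference (the re-draw rule). Fails when the target composition cannot
#' be approached within `max_attempts` proposals.
#'
#' @param genome Genome.
#' @param template Character vector of template windows (defines n and the
#'   target composition).
#' @param tol Maximum absolute per-base composition difference (fraction).
#' @param max_attempts Cap on swap proposals.
#' @param seed Optional seed.
#' @return Character vector of sampled windows, same length as `template`.
#' @export
sample_matched_sites <- function(genome, template, tol = 0.01,
                                 max_attempts = 1000, seed = NULL) {
  assert_windows(template, "template")
  target <- genome_composition(template)
  target_at <- at_fraction(template)
  pool <- genome_cg_sites(genome)
  if (nrow(pool) == 0) abort("composition unmatchable: genome has no usable C/G sites")
  n <- length(template)
  with_seed_(seed, {
    pool_win <- site_windows(genome, pool)
    keep <- !grepl("[^ACGT]", pool_win)
    pool_win <- pool_win[keep]
    base_counts <- function(w) {
      m <- window_char_matrix(w)
      vapply(seq_along(w), function(i) tabulate(match(m[, i], BASES), 4L),
             integer(4))
    }
    idx <- sample.int(length(pool_win), n, replace = length(pool_win) < n)
    counts <- base_counts(pool_win[idx]) # 4 x n
    tot <- rowSums(counts) # per-base totals
    dev <- function(tot) sum(abs(tot / (n * WINDOW_LEN) - target))
    cur <- dev(tot)
    matched <- function() {
      if (any(abs(tot / (n * WINDOW_LEN) - target) > tol)) return(FALSE)
      pt <- tryCatch(t.test(at_fraction(pool_win[idx]), target_at)$p.value,
                     error = function(e) 1)
      pt >= 0.05
    }
    for (attempt in seq_len(max_attempts)) {
      if (matched()) return(pool_win[idx])
      j <- sample.int(n, 1)
      k <- sample.int(length(pool_win), 1)
      cand <- tabulate(match(strsplit(pool_win[k], "", fixed = TRUE)[[1]],
                             BASES), 4L)
      new_tot <- tot - counts[, j] + cand
      if (dev(new_tot) < cur) {
        tot <- new_tot
        cur <- dev(new_tot)
        counts[, j] <- cand
        idx[j] <- k
      }
    }
    if (matched()) return(pool_win[idx])
    abort("composition unmatchable")
  })
}

# Per-window A+T fraction among the 10 flanking bases.
at_fraction <- function(windows) {
  m <- window_char_matrix(windows)[-6, , drop = FALSE]
  colMeans(m == "A" | m == "T")
}

# All C/G positions with a full 121-bp neighborhood, per contig.
genome_cg_sites <- function(genome) {
  out <- purrr::map_dfr(names(genome), function(nm) {
    s <- as.character(genome[[nm]])
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- which(chars %in% c("C", "G"))
    pos <- pos[pos > CENTER_OFFSET & pos <= length(chars) - CENTER_OFFSET]
    tibble(chrom = nm, pos = pos, ref = chars[pos])
  })
  out
}

site_windows <- function(genome, sites) {
  win <- character(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    s <- as.character(genome[[ch]])
    win[i] <- substring(s, sites$pos[i] - 5L, sites$pos[i] + 5L)
  }
  flip <- sites$ref == "G"
  win[flip] <- revcomp(win[flip])
  win
}

#' Remove windows with high A/T content
#'
#' Drops windows whose 10 flanking bases contain at least
#' `threshold` * 10 A or T bases (the >= is inclusive). This filter reduces
#' false positives from A/T-rich motifs.
#'
#' @param x Character vector of windows, or a tibble with a `window` column.
#' @param threshold A+T fraction at or above which a window is removed.
#' @return Filtered object of the same type; the number removed is attached
#'   as attribute `"n_removed"`.
#' @export
at_content_filter <- function(x, threshold = 0.5) {
  win <- if (is.data.frame(x)) x$window else x
  assert_windows(win, "x")
  keep <- at_fraction(win) < threshold
  out <- if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Read and write plain-text context sets
#'
#' Context sets are stored one 11-mer per line with `#` comments; FASTA is
#' also accepted on read (each record one 11-mer).
#'
#' @param path File path.
#' @return Character vector of windows.
#' @export
read_context_set <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    win <- as.character(Biostrings::readDNAStringSet(path))
  } else {
    lines <- readLines(path)
    win <- trimws(lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))])
  }
  assert_windows(win, path)
  unname(win)
}

#' @rdname read_context_set
#' @param windows Character vector of 11-mers.
#' @export
write_context_set <- function(windows, path) {
  assert_windows(windows)
  writeLines(windows, path)
  invisible(path)
}

#' Serialize a weight matrix to TSV
#'
#' Four rows (A, C, G, T) by 11 position columns, with metadata lines
#' (`#key=value`) for the pseudocount, scoring window, Smin and Smax, and
#' a header row carrying both -5..+5 and 1..11 position labels.
#'
#' @param wm A `weight_matrix`.
#' @param path Output path.
#' @export
write_weight_matrix <- function(wm, path) {
  meta <- c(
    sprintf("#name=%s", wm$name %||% ""),
    sprintf("#n_sequences=%d", wm$n_sequences),
    sprintf("#pseudocount=%g", wm$pseudocount),
    sprintf("#scoring_positions=%d:%d", min(wm$scoring_positions),
            max(wm$scoring_positions)),
    sprintf("#smin=%.10g", wm$smin),
    sprintf("#smax=%.10g", wm$smax),
    sprintf("#background=%s", paste(sprintf("%s:%.10g", BASES, wm$background),
                                    collapse = ",")),
    paste(c("base", sprintf("%d|%d", POSITIONS, POSITIONS + 6L)),
          collapse = "\t")
  )
  rows <- vapply(BASES, function(b) {
    paste(c(b, sprintf("%.10g", wm$W[b, ])), collapse = "\t")
  }, character(1))
  writeLines(c(meta, rows), path)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- setNames(sub("^#[^=]+=", "", meta_lines),
                   sub("^#([^=]+)=.*$", "\\1", meta_lines))
  body <- lines[!startsWith(lines, "#")]
  tab <- do.call(rbind, strsplit(body[-1], "\t", fixed = TRUE))
  W <- matrix(as.numeric(tab[, -1]), nrow = 4,
              dimnames = list(tab[, 1], as.character(POSITIONS)))
  sp <- as.integer(strsplit(meta[["scoring_positions"]], ":")[[1]])
  bg_parts <- strsplit(strsplit(meta[["background"]], ",")[[1]], ":")
  bg <- setNames(as.numeric(vapply(bg_parts, `[`, "", 2)),
                 vapply(bg_parts, `[`, "", 1))
  out <- list(W = W[BASES, , drop = FALSE], background = bg[BASES],
              scoring_positions = sp[1]:sp[2],
              smin = as.numeric(meta[["smin"]]), smax = as.numeric(meta[["smax"]]),
              pseudocount = as.numeric(meta[["pseudocount"]]),
              n_sequences = as.integer(meta[["n_sequences"]]),
              name = if (nzchar(meta[["name"]])) meta[["name"]] else NULL)
  class(out) <- "weight_matrix"
  out
}
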