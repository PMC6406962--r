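# Shared fixtures and independent naive oracles. Oracles deliberately use
# plain loops and first-principles formulas, independent of the package's
# vectorized implementations.

BASES4 <- c("A", "C", "G", "T")
COMP4 <- c(A = "T", C = "G", G = "C", T = "A")

fixture_genome <- function(length = 50000, seed = 42, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  simulate_genome(length, p, seed = seed)
}

# A small, well-structured training set: T fixed at -1, C at 0, uniform
# elsewhere (APOBEC3A-like).
fixture_contexts <- function(n = 200, seed = 7) {
  spec <- enzyme_motif_spec("APOBEC3A", conservation = 1)
  simulate_context_set(spec, n, seed = seed)
}

fixture_matrix <- function(n = 200, seed = 7) {
  build_weight_matrix(count_contexts(fixture_contexts(n, seed), name = "fix"))
}

# ---- naive oracles -------------------------------------------------------

# Percent score from first principles: direct table lookups, explicit
# min/max column sums.
naive_percent_score <- function(W, scoring_positions, window11) {
  sp <- as.character(scoring_positions)
  chars <- strsplit(window11, "")[[1]]
  s <- 0
  for (j in scoring_positions) {
    s <- s + W[chars[j + 6], as.character(j)]
  }
  smin <- sum(apply(W[, sp, drop = FALSE], 2, min))
  smax <- sum(apply(W[, sp, drop = FALSE], 2, max))
  100 * (s - smin) / (smax - smin)
}

# All 4^k sequences over the scoring window.
enumerate_kmers <- function(k) {
  grid <- do.call(expand.grid, rep(list(BASES4), k))
  apply(grid, 1, paste, collapse = "")
}

# O(n^3) UPGMA producing the cophenetic (ultrametric) distance matrix.
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dd <- d
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  sizes <- rep(1, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && dd[a, b] < bestd) { bestd <- dd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    # average linkage update
    for (k in idx) {
      if (k != a && k != b) {
        dd[a, k] <- dd[k, a] <-
          (sizes[a] * dd[a, k] + sizes[b] * dd[b, k]) / (sizes[a] + sizes[b])
      }
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
  }
  coph
}

# Minimal mutation tibble builder for hand-placed sites.
make_records <- function(chrom, pos, ref, alt, tissue = "t1", sample = "s1") {
  tibble::tibble(sample = sample, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, tissue = tissue,
                 subclass = classify_substitution(ref, alt))
}

write_fasta_lines <- function(path, named) {
  writeLines(unlist(lapply(names(named), function(n) c(paste0(">", n), named[[n]]))),
             path)
}
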