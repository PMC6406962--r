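#' Position-specific motif specification
#'
#' A MotifSpec holds per-position base distributions over the 11 context
#' positions (-5..+5) with the center forced to a point mass on C; it is the
#' generative ground truth for synthetic context sets and planted mutation
#' datasets.
#'
#' @param probs 4 x 11 numeric matrix (rows A,C,G,T; columns positions
#'   -5..+5), each column summing to 1; the center column must be a point
#'   mass on C.
#' @param name Label for the spec.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(probs, name = "custom") {
  stopifnot(is.matrix(probs), nrow(probs) == 4, ncol(probs) == WINDOW_LEN)
  rownames(probs) <- BASES
  colnames(probs) <- as.character(POSITIONS)
  if (any(abs(colSums(probs) - 1) > 1e-8)) abort("columns must sum to 1")
  if (abs(probs["C", "0"] - 1) > 1e-8) {
    abort("center position must be a point mass on C")
  }
  structure(list(probs = probs, name = name), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec %s>\n", x$name))
  print(round(x$probs, 2))
  invisible(x)
}

# Column of probabilities concentrating `conservation` mass on `bases`
# (split evenly), remainder spread evenly over the other bases.
motif_column <- function(bases, conservation = 0.9) {
  p <- setNames(rep((1 - conservation) / (4 - length(bases)), 4), BASES)
  p[bases] <- conservation / length(bases)
  p
}

#' Built-in deaminase motif emulations
#'
#' Synthetic per-position distributions that emulate the qualitative motif
#' structure of the AID/APOBEC cytosine deaminases: TC for APOBEC3A and
#' APOBEC3B, TC with an additional T at -3 for APOBEC1, T at -2 for
#' APOBEC3C, a wcCCw-style pattern for APOBEC3G, and WRC for AID (W = A/T,
#' R = A/G). These are emulations for simulation and testing, not matrices
#' estimated from experimental mutagenesis data.
#'
#' @param enzyme One of "APOBEC1", "APOBEC3A", "APOBEC3B", "APOBEC3C",
#'   "APOBEC3G", "AID".
#' @param conservation Probability mass on the preferred base(s) at each
#'   informative position.
#' @return A `motif_spec`.
#' @export
enzyme_motif_spec <- function(enzyme = c("APOBEC1", "APOBEC3A", "APOBEC3B",
                                         "APOBEC3C", "APOBEC3G", "AID"),
                              conservation = 0.9) {
  enzyme <- match.arg(enzyme)
  probs <- matrix(0.25, 4, WINDOW_LEN, dimnames = list(BASES, as.character(POSITIONS)))
  probs[, "0"] <- c(0, 1, 0, 0)
  set_col <- function(pos, bases, cons = conservation) {
    probs[, as.character(pos)] <<- motif_column(bases, cons)
  }
  switch(enzyme,
    APOBEC1 = { set_col(-1, "T"); set_col(-3, "T") },
    APOBEC3A = set_col(-1, "T"),
    APOBEC3B = set_col(-1, "T"),
    APOBEC3C = set_col(-2, "T"),
    APOBEC3G = {
      set_col(-1, "C"); set_col(-2, "C", conservation * 0.75)
      set_col(-3, c("A", "T"), 0.6); set_col(1, c("A", "T"), 0.6)
    },
    AID = { set_col(-2, c("A", "T")); set_col(-1, c("A", "G")) }
  )
  motif_spec(probs, name = enzyme)
}

#' Weight matrix implied by a motif spec
#'
#' Builds a weight matrix directly from the spec's exact per-position
#' distributions (treated as frequencies from `n` pseudo-observations),
#' bypassing sampling noise. Useful as a generative scoring model.
#'
#' @param spec A `motif_spec`.
#' @param n Pseudo sample size used for smoothing.
#' @param ... Passed to [build_weight_matrix()].
#' @return A `weight_matrix`.
#' @export
spec_weight_matrix <- function(spec, n = 10000, ...) {
  stopifnot(inherits(spec, "motif_spec"))
  counts <- round(spec$probs * n)
  fm <- list(counts = counts, freq = counts / n, n_sequences = n,
             positions = POSITIONS, name = spec$name)
  class(fm) <- "freq_matrix"
  build_weight_matrix(fm, ...)
}

#' Simulate an i.i.d. random genome
#'
#' @param length Contig length in bp (>= 121).
#' @param base_probs Named or ordered (A,C,G,T) probabilities summing to 1.
#' @param seed Optional seed (deterministic output per seed).
#' @param name Contig name.
#' @return A one-contig `DNAStringSet`.
#' @export
simulate_genome <- function(length, base_probs = rep(0.25, 4), seed = NULL,
                            name = "chr1") {
  if (length < NEIGHBORHOOD_LEN) abort("genome length must be at least 121")
  stopifnot(abs(sum(base_probs) - 1) < 1e-8)
  seq <- with_seed_(seed, paste(sample(BASES, length, replace = TRUE,
                                       prob = base_probs), collapse = ""))
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- name
  out
}

#' Simulate a motif-defined context set
#'
#' Draws `n` 11-mers position-independently from a motif spec, emulating a
#' deaminase mutation-context training set.
#'
#' @param spec A `motif_spec`.
#' @param n Number of windows.
#' @param seed Optional seed.
#' @return Character vector of `n` windows.
#' @export
simulate_context_set <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "motif_spec"), n >= 1)
  with_seed_(seed, {
    cols <- lapply(seq_len(WINDOW_LEN), function(j) {
      sample(BASES, n, replace = TRUE, prob = spec$probs[, j])
    })
    do.call(paste0, cols)
  })
}

alt_for_class <- list(
  "C:G>T:A" = "T", "C:G>G:C" = "G", "C:G>A:T" = "A"
)

#' Simulate a mutation table with a planted motif fraction
#'
#' Generates `n` C:G-site mutations on a genome: with probability `pi` a
#' site is drawn from the eligible C/G sites with probability proportional
#' to 2^S (S = raw matching score under the scoring model, a Boltzmann
#' weighting that smoothly enriches high-scoring motif sites); otherwise
#' uniformly. Every record's true origin is retained for recovery tests.
#'
#' @param genome Genome.
#' @param model A `weight_matrix` or `motif_spec` defining the planted motif.
#' @param pi Planted fraction in \[0, 1\].
#' @param n Number of mutations.
#' @param subclass_mix Named probabilities over the C:G substitution
#'   classes.
#' @param tissue,sample_id Labels written into the table.
#' @param seed Optional seed.
#' @return Mutation tibble (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `tissue`, `subclass`) with ground-truth columns `origin`
#'   ("planted"/"background") and `score`; generator settings are attached
#'   as attributes.
#' @export
simulate_mutation_dataset <- function(genome, model, pi, n,
                                      subclass_mix = c("C:G>T:A" = 1),
                                      tissue = "synthetic", sample_id = "s1",
                                      seed = NULL) {
  stopifnot(pi >= 0, pi <= 1, n >= 1)
  if (inherits(model, "motif_spec")) model <- spec_weight_matrix(model)
  stopifnot(inherits(model, "weight_matrix"))
  stopifnot(all(names(subclass_mix) %in% names(alt_for_class)))
  sites <- genome_cg_sites(genome)
  win <- site_windows(genome, sites)
  ok <- !grepl("[^ACGT]", win)
  sites <- sites[ok, , drop = FALSE]
  win <- win[ok]
  if (nrow(sites) < n) abort("insufficient eligible C/G sites in genome")
  scores <- score_windows(model, win)
  with_seed_(seed, {
    planted <- stats::runif(n) < pi
    n_pl <- sum(planted)
    idx <- integer(n)
    boltz <- 2^(scores - max(scores))
    # planted sites are drawn with replacement: recurrent positions are
    # legitimate in a catalogue, and replacement keeps the planted context
    # distribution equal to the motif even when high-scoring sites are rare
    if (n_pl > 0) {
      idx[planted] <- sample.int(nrow(sites), n_pl, replace = TRUE,
                                 prob = boltz)
    }
    idx[!planted] <- sample(seq_len(nrow(sites)), n - n_pl)
    cls <- sample(names(subclass_mix), n, replace = TRUE, prob = subclass_mix)
    ref <- sites$ref[idx]
    alt_c <- unlist(alt_for_class[cls], use.names = FALSE)
    alt <- ifelse(ref == "C", alt_c, COMPLEMENT[alt_c])
    out <- tibble(
      sample = sample_id, chrom = sites$chrom[idx], pos = sites$pos[idx],
      ref = ref, alt = unname(alt), tissue = tissue, subclass = cls,
      origin = ifelse(planted, "planted", "background"),
      score = scores[idx]
    ) |> dplyr::arrange(.data$chrom, .data$pos)
    attr(out, "planted_fraction") <- pi
    attr(out, "model") <- model$name
    attr(out, "seed") <- seed
    out
  })
}
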