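#' Count nucleotide contexts into a frequency matrix
#'
#' Tabulates a set of strand-normalized 11-mer mutation contexts (positions
#' -5..+5, 0 = the mutated cytosine) into per-position base counts and
#' normalized frequencies.
#'
#' @param windows Character vector of 11-mers over A/C/G/T, strand-normalized
#'   so the center base is C for deaminase context sets.
#' @param name Optional provenance label (enzyme name or control tag).
#' @return A `freq_matrix` object: counts and frequencies (4 bases x 11
#'   positions) plus `n_sequences`.
#' @examples
#' fm <- count_contexts(c("AAAAACAAAAA", "AATTACTTTAA"))
#' tidy(fm)
#' @export
count_contexts <- function(windows, name = NULL) {
  assert_windows(windows)
  m <- window_char_matrix(windows)
  counts <- t(apply(m, 1, function(row) tabulate(match(row, BASES), 4L)))
  dimnames(counts) <- NULL
  counts <- t(counts) # 4 x 11
  rownames(counts) <- BASES
  colnames(counts) <- as.character(POSITIONS)
  n <- length(windows)
  out <- list(counts = counts, freq = counts / n, n_sequences = n,
              positions = POSITIONS, name = name)
  class(out) <- "freq_matrix"
  out
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix%s: %d sequences>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_sequences))
  print(round(x$freq, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.freq_matrix <- function(x, ...) {
  tidyr::expand_grid(position = x$positions, base = BASES) |>
    dplyr::mutate(
      count = x$counts[cbind(.data$base, as.character(.data$position))],
      freq = x$freq[cbind(.data$base, as.character(.data$position))],
      # the paper-style 1..11 labels (center = 6) for cross-referencing
      position_1based = .data$position + 6L
    )
}

#' Background base frequencies from the flanking positions
#'
#' The null model e(b) is the mean base frequency over the four outermost,
#' least informative positions -5, -4, +4, +5. This normalizes for overall
#' base-composition differences between the training genome and the genome
#' under study.
#'
#' @param fm A [count_contexts()] frequency matrix.
#' @param flank_positions Positions averaged for the background.
#' @return Named numeric vector e(b) over A,C,G,T summing to 1.
#' @export
background_frequencies <- function(fm, flank_positions = c(-5, -4, 4, 5)) {
  stopifnot(inherits(fm, "freq_matrix"))
  e <- rowMeans(fm$freq[, as.character(flank_positions), drop = FALSE])
  e / sum(e)
}

#' Build a log-odds weight matrix from a frequency matrix
#'
#' W(b,j) = log2(f(b,j) / e(b)), with counts smoothed by a pseudocount and
#' the background floored at 1/(4 n) so W is finite everywhere. The score
#' bounds Smin and Smax are the column-wise minimal and maximal weight sums
#' over the scoring window (default -3..+3).
#'
#' @param fm A `freq_matrix`.
#' @param background Optional background frequencies; default recomputed
#'   from the smoothed frequencies via [background_frequencies()].
#' @param pseudocount Added to each count before frequency computation.
#' @param scoring_positions Contiguous positions actually scored.
#' @param name Provenance label; defaults to the frequency matrix's.
#' @return A `weight_matrix` object with elements `W`, `background`,
#'   `scoring_positions`, `smin`, `smax`, `pseudocount`, `n_sequences`.
#' @examples
#' wm <- count_contexts(rep(c("AATTACTTTAA", "GGTTACTTTCC"), 50)) |>
#'   build_weight_matrix()
#' wm$smax
#' @export
build_weight_matrix <- function(fm, background = NULL, pseudocount = 0.5,
                                scoring_positions = -3:3, name = NULL) {
  stopifnot(inherits(fm, "freq_matrix"), pseudocount > 0)
  stopifnot(all(scoring_positions %in% fm$positions))
  n <- fm$n_sequences
  f <- (fm$counts + pseudocount) / (n + 4 * pseudocount)
  if (is.null(background)) {
    sm <- fm
    sm$freq <- f
    background <- background_frequencies(sm)
  }
  e <- pmax(background, 1 / (4 * n))
  e <- e / sum(e)
  W <- log2(f / e)
  sp <- as.character(scoring_positions)
  smin <- sum(apply(W[, sp, drop = FALSE], 2, min))
  smax <- sum(apply(W[, sp, drop = FALSE], 2, max))
  if (isTRUE(all.equal(smin, smax))) {
    abort("degenerate matrix: Smax equals Smin, percent score undefined")
  }
  out <- list(W = W, background = e, scoring_positions = scoring_positions,
              smin = smin, smax = smax, pseudocount = pseudocount,
              n_sequences = n, name = name %||% fm$name)
  class(out) <- "weight_matrix"
  out
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix%s: %d sequences, scored %d..%d, Smin=%.2f Smax=%.2f>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_sequences, min(x$scoring_positions), max(x$scoring_positions),
              x$smin, x$smax))
  print(round(x$W, 2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.weight_matrix <- function(x, ...) {
  tidyr::expand_grid(position = POSITIONS, base = BASES) |>
    dplyr::mutate(
      weight = x$W[cbind(.data$base, as.character(.data$position))],
      scored = .data$position %in% x$scoring_positions,
      position_1based = .data$position + 6L
    )
}

# Vectorized raw matching score over the scoring window. `windows` are
# either full 11-mers or sequences of exactly the scoring-window length.
score_windows <- function(wm, windows) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (length(windows) == 0) return(numeric(0))
  L <- nchar(windows)
  if (length(unique(L)) != 1) abort("windows of mixed length")
  sp <- wm$scoring_positions
  m <- window_char_matrix(windows)
  if (L[1] == WINDOW_LEN) {
    rows <- sp + 6L
  } else if (L[1] == length(sp)) {
    rows <- seq_along(sp)
  } else {
    abort("window length covers neither the full 11-mer nor the scoring window")
  }
  sub <- m[rows, , drop = FALSE]
  base_idx <- match(sub, BASES)
  if (anyNA(base_idx)) abort("ambiguous base in scoring window")
  pos_col <- match(as.character(sp), colnames(wm$W))
  vals <- wm$W[cbind(base_idx, rep(pos_col, times = ncol(sub)))]
  colSums(matrix(vals, nrow = length(sp)))
}

#' Raw matching score of a window against a weight matrix
#'
#' Sum of W(b_j, j) over the scoring positions; bounded by Smin and Smax.
#'
#' @param wm A `weight_matrix`.
#' @param window Character vector of windows (11-mers, or sequences of the
#'   scoring-window length).
#' @return Numeric score(s) in bits.
#' @export
matching_score <- function(wm, window) {
  score_windows(wm, window)
}

#' Percent matching score ("weight") of a window
#'
#' Affine rescaling of the raw matching score to \[0, 100\] between Smin and
#' Smax. This is the per-site "weight" used by all downstream footprint
#' statistics.
#'
#' @inheritParams matching_score
#' @return Numeric in \[0, 100\].
#' @export
percent_score <- function(wm, window) {
  s <- score_windows(wm, window)
  100 * (s - wm$smin) / (wm$smax - wm$smin)
}

#' Per-position information content and consensus
#'
#' IC(j) = 2 + sum_b f(b,j) log2 f(b,j), in bits (0 = uniform, 2 = fixed
#' base). The consensus letter is upper case when IC >= `upper`, lower case
#' when IC >= `lower`, and "." otherwise.
#'
#' @param fm A `freq_matrix`.
#' @param upper,lower Case thresholds in bits for the consensus string.
#' @return A tibble with `position`, `position_1based`, `ic`, `consensus`.
#' @export
information_content <- function(fm, upper = 1, lower = 0.25) {
  stopifnot(inherits(fm, "freq_matrix"))
  plogp <- fm$freq * log2(fm$freq)
  plogp[fm$freq == 0] <- 0
  ic <- 2 + colSums(plogp)
  top <- BASES[apply(fm$freq, 2, which.max)]
  cons <- unname(ifelse(ic >= upper, top, ifelse(ic >= lower, tolower(top), ".")))
  tibble(position = fm$positions, position_1based = fm$positions + 6L,
         ic = unname(ic), consensus = cons)
}

#' Compare two context sets by chi-squared test on raw base counts
#'
#' For each of the 10 flanking positions (the constant center is excluded) a
#' 2 x 4 contingency table of raw base counts is tested; the per-position
#' chi-squared statistics are summed. Degrees of freedom default to the
#' structural value 3 per position (30 total) but can be overridden, and the
#' Bonferroni-corrected critical value for a family of comparisons is
#' reported alongside.
#'
#' @param setA,setB Character vectors of 11-mer context windows.
#' @param df Degrees of freedom for the p-value; default `3 * 10 = 30`.
#' @param n_comparisons Family size for the Bonferroni critical value.
#' @param alpha Family-wise error rate.
#' @return One-row tibble: `chi2`, `df`, `p`, `critical_value`,
#'   `low_expected` (TRUE when any expected cell < 1).
#' @export
compare_matrices_chi2 <- function(setA, setB, df = NULL, n_comparisons = 1,
                                  alpha = 0.05) {
  assert_windows(setA, "setA")
  assert_windows(setB, "setB")
  ca <- count_contexts(setA)$counts
  cb <- count_contexts(setB)$counts
  flanks <- as.character(setdiff(POSITIONS, 0))
  chi2 <- 0
  low_expected <- FALSE
  for (j in flanks) {
    tab <- rbind(ca[, j], cb[, j])
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 1)) low_expected <- TRUE
    chi2 <- chi2 + sum((tab - expct)^2 / expct)
  }
  df <- df %||% (3L * length(flanks))
  out <- tibble(
    chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
    critical_value = chi2_critical_value(alpha, n_comparisons, df),
    low_expected = low_expected
  )
  if (low_expected) warn("expected cell count < 1 in chi-squared comparison")
  out
}
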