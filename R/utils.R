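BASES <- c("A", "C", "G", "T")
POSITIONS <- -5:5 # 0 = mutated base
WINDOW_LEN <- 11L
NEIGHBORHOOD_LEN <- 121L
CENTER_OFFSET <- 60L # 0-based offset of the mutated base in a neighborhood

#' Six strand-collapsed substitution classes
#'
#' Because the mutated strand is unknown, complementary substitutions are
#' pooled (a C>T on one strand and a G>A on the other are the same event),
#' reducing all single-base substitutions to six classes.
#'
#' @return Character vector of the six class labels.
#' @export
substitution_classes <- function() {
  c("C:G>T:A", "C:G>G:C", "C:G>A:T", "T:A>C:G", "T:A>G:C", "T:A>A:T")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify a substitution into its strand-collapsed class
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Character vector of class labels (see [substitution_classes()]).
#' @export
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  flip <- ref %in% c("G", "A")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  cls <- paste0(r, ":", COMPLEMENT[r], ">", a, ":", COMPLEMENT[a])
  bad <- !(cls %in% substitution_classes())
  cls[bad] <- NA_character_
  cls
}

# Deterministic integer stream seed derived from a master seed and labels,
# so per-(group, matrix) results do not depend on iteration order.
label_seed <- function(master, ...) {
  s <- paste(c(master, ...), collapse = "\r")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

assert_windows <- function(windows, arg = "windows") {
  if (length(windows) == 0) abort(sprintf("no training contexts in `%s`", arg))
  if (any(nchar(windows) != WINDOW_LEN)) {
    abort(sprintf("all context windows in `%s` must have length %d",
                  arg, WINDOW_LEN))
  }
  if (any(grepl("[^ACGT]", windows))) {
    abort(sprintf("`%s` contains non-ACGT characters", arg))
  }
  invisible(windows)
}

# Split windows into an nchar x n character matrix.
window_char_matrix <- function(windows) {
  n <- length(windows)
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = nchar(windows[1]), ncol = n)
}

#' Analytic multiple-testing constants
#'
#' Helpers for the Bonferroni-corrected thresholds used throughout the
#' footprint tests: the per-comparison alpha, the chi-squared critical value
#' for matrix comparisons, and the conservative large-sample two-tailed
#' t critical value.
#'
#' @param alpha Family-wise error rate.
#' @param n_comparisons Number of comparisons in the family.
#' @param df Chi-squared degrees of freedom.
#' @return A single numeric value.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_comparisons = 1) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1)
  alpha / n_comparisons
}

#' @rdname bonferroni_alpha
#' @export
chi2_critical_value <- function(alpha = 0.05, n_comparisons = 1, df) {
  qchisq(bonferroni_alpha(alpha, n_comparisons), df, lower.tail = FALSE)
}

#' @rdname bonferroni_alpha
#' @export
t_critical_value <- function(alpha = 0.05, n_comparisons = 1) {
  # large-sample (normal) two-tailed critical value; conservative gate
  qnorm(bonferroni_alpha(alpha, n_comparisons) / 2, lower.tail = FALSE)
}
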