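new_control_report <- function(kind, outcomes, seed, replicates) {
  sig <- outcomes$significant
  structure(
    list(control_kind = kind, outcomes = outcomes,
         fp_fraction = mean(sig, na.rm = TRUE),
         n_outcomes = sum(!is.na(sig)), seed = seed, replicates = replicates),
    class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat(sprintf("<control_report %s: %d outcomes, significant fraction %.3f>\n",
              x$control_kind, x$n_outcomes, x$fp_fraction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.control_report <- function(x, ...) x$outcomes

#' @exportS3Method generics::glance
glance.control_report <- function(x, ...) {
  tibble(control_kind = x$control_kind, n_outcomes = x$n_outcomes,
         fp_fraction = x$fp_fraction, replicates = x$replicates,
         seed = x$seed %||% NA_integer_)
}

# Significant fraction per matrix template (the prefix before the replicate
# suffix), with the reliability flag.
matrix_reliability <- function(outcomes, fp_threshold = 0.25) {
  outcomes |>
    dplyr::mutate(template = sub("\\.rep[0-9]+$", "", .data$matrix_id)) |>
    dplyr::group_by(.data$template) |>
    dplyr::summarise(fp_fraction = mean(.data$significant, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(unreliable = .data$fp_fraction > fp_threshold)
}

#' Control experiment: shuffled-context ("pseudo-mutable") matrices
#'
#' Per replicate, each training context set is shuffled per-sequence (center
#' base fixed, per-sequence composition preserved), a weight matrix is
#' rebuilt from the shuffled set, and the footprint scan is run against the
#' supplied records. On motif-free records the fraction of significant
#' (matrix x group) outcomes estimates the method's false-positive rate.
#'
#' @param context_sets Named list of character vectors of 11-mer contexts.
#' @param records Mutation tibble (grouped by `tissue` for the scan).
#' @param genome Genome.
#' @param replicates Shuffle replicates per context set.
#' @param seed Master seed.
#' @param ... Passed to [footprint_scan()].
#' @return A `control_report`; `tidy()` gives per-outcome rows, `glance()`
#'   the aggregate false-positive fraction.
#' @export
run_shuffle_control <- function(context_sets, records, genome, replicates = 5,
                                seed = NULL, ...) {
  stopifnot(length(context_sets) >= 1)
  matrices <- list()
  for (r in seq_len(replicates)) {
    for (nm in names(context_sets)) {
      shuffled <- with_seed_(
        if (is.null(seed)) NULL else label_seed(seed, "shuffle", nm, r),
        shuffle_context(context_sets[[nm]]))
      id <- sprintf("%s.rep%d", nm, r)
      matrices[[id]] <- build_weight_matrix(count_contexts(shuffled, name = id))
    }
  }
  outcomes <- footprint_scan(matrices, records, genome, grouping = "tissue",
                             seed = seed, ...)
  new_control_report("shuffle", outcomes, seed, replicates)
}

#' Control experiment: composition-matched random matrices
#'
#' Builds "pseudo-mutable motif" matrices from random genomic C/G sites
#' sampled to match each template context set's size and mononucleotide
#' composition, then scans the records. The per-template significant
#' fraction is the false-positive-fraction quantity exported by the control
#' heatmap; templates exceeding `fp_threshold` are flagged unreliable.
#'
#' @param genome Genome (source of the random sites and of neighborhoods).
#' @param template_sets Named list of template context sets.
#' @param records Mutation tibble.
#' @param replicates Sampled matrices per template.
#' @param seed Master seed.
#' @param fp_threshold Per-template significant fraction above which the
#'   template is flagged unreliable.
#' @param ... Passed to [footprint_scan()].
#' @return A `control_report` with an extra `by_matrix` element.
#' @export
run_random_matrix_control <- function(genome, template_sets, records,
                                      replicates = 5, seed = NULL,
                                      fp_threshold = 0.25, ...) {
  matrices <- list()
  for (r in seq_len(replicates)) {
    for (nm in names(template_sets)) {
      win <- sample_matched_sites(
        genome, template_sets[[nm]],
        seed = if (is.null(seed)) NULL else label_seed(seed, "sample", nm, r))
      id <- sprintf("%s.rep%d", nm, r)
      matrices[[id]] <- build_weight_matrix(count_contexts(win, name = id))
    }
  }
  outcomes <- footprint_scan(matrices, records, genome, grouping = "tissue",
                             seed = seed, ...)
  rep <- new_control_report("random_matrix", outcomes, seed, replicates)
  rep$by_matrix <- matrix_reliability(outcomes, fp_threshold)
  rep
}

#' Control experiment: negative mutation set
#'
#' A plain footprint scan over a mutation set where no motif enrichment is
#' expected (e.g. mitochondrial mutations or a synthetic motif-free set).
#' Expected outcome: ratios at or below ~1 and no dual-test significance;
#' isolated single-test hits are tallied separately, not counted as
#' significant.
#'
#' @param matrices Named list of weight matrices.
#' @param records Negative-control mutation tibble.
#' @param genome Genome.
#' @param seed Master seed.
#' @param ... Passed to [footprint_scan()].
#' @return A `control_report` with `n_single_test_hits`.
#' @export
run_negative_control <- function(matrices, records, genome, seed = NULL, ...) {
  outcomes <- footprint_scan(matrices, records, genome, seed = seed, ...)
  rep <- new_control_report("negative_set", outcomes, seed, 1L)
  single <- xor(outcomes$mc_p < 0.05,
                outcomes$t_statistic >= outcomes$t_critical)
  rep$n_single_test_hits <- sum(single & !outcomes$significant, na.rm = TRUE)
  rep
}

#' Control experiment: positive mutation set
#'
#' A footprint scan over records carrying a known planted motif (the
#' immunoglobulin-gene analog for AID). Expected outcome: the matching
#' matrix is dual-test significant with ratio > 1 while non-matching
#' matrices are not.
#'
#' @inheritParams run_negative_control
#' @param records Positive-control mutation tibble.
#' @return A `control_report`; `tidy()` shows which matrices fired.
#' @export
run_positive_control <- function(matrices, records, genome, seed = NULL, ...) {
  outcomes <- footprint_scan(matrices, records, genome, seed = seed, ...)
  new_control_report("positive_set", outcomes, seed, 1L)
}
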