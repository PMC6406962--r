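# Precompute, per record, the strand-normalized mutated-site window and the
# windows at every eligible background site of its 121-bp neighborhood.
# Computed once per record set and reused across matrices.
prepare_sites <- function(records, genome) {
  stopifnot(all(records$ref %in% c("C", "G")))
  recs <- extract_windows(records, genome)
  nbs <- character(nrow(recs))
  for (ch in unique(recs$chrom)) {
    i <- which(recs$chrom == ch)
    len <- nchar(s <- as.character(genome[[ch]]))
    if (any(recs$pos[i] <= CENTER_OFFSET | recs$pos[i] > len - CENTER_OFFSET)) {
      abort("edge: site within 60 bp of a contig end")
    }
    nbs[i] <- substring(s, recs$pos[i] - CENTER_OFFSET,
                        recs$pos[i] + CENTER_OFFSET)
  }
  bg <- lapply(nbs, function(nb) {
    neighborhood_windows(nb, eligible_background_sites(nb))
  })
  list(records = recs, mut_windows = recs$window, bg_windows = bg)
}

#' Weights of mutated sites
#'
#' Percent matching score of each mutation's strand-normalized context
#' window; the order matches the input records.
#'
#' @param wm A `weight_matrix`.
#' @param records Mutation tibble restricted to C:G sites.
#' @param genome Genome.
#' @return Numeric vector, one weight per record.
#' @export
site_weights <- function(wm, records, genome) {
  recs <- extract_windows(records, genome)
  percent_score(wm, recs$window)
}

#' Pooled weights of neighborhood background sites
#'
#' Percent matching score at every eligible C/G background site of every
#' record's 121-bp neighborhood, pooled across records. Records whose
#' neighborhood has no eligible site contribute nothing.
#'
#' @inheritParams site_weights
#' @return Numeric vector of pooled background weights.
#' @export
background_weights <- function(wm, records, genome) {
  prep <- prepare_sites(records, genome)
  percent_score(wm, unlist(prep$bg_windows, use.names = FALSE))
}

footprint_prepared <- function(wm, prep, matrix_id = NULL, tissue = NA_character_,
                               subclass = NA_character_, mc_iters = 1000,
                               seed = NULL, n_min = 50, n_tests = 1,
                               alpha = 0.05, mc_alpha = 0.05) {
  mut_w <- percent_score(wm, prep$mut_windows)
  lens <- lengths(prep$bg_windows)
  bg_all <- percent_score(wm, unlist(prep$bg_windows, use.names = FALSE))
  bg_per_record <- split(bg_all, rep(seq_along(lens), lens))
  obs_mean <- mean(mut_w)
  bg_mean <- mean(bg_all)
  degenerate <- !is.finite(bg_mean) || bg_mean == 0
  ratio <- if (degenerate) NA_real_ else obs_mean / bg_mean
  tt <- tryCatch(t.test(mut_w, bg_all), error = function(e) NULL)
  t_stat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
  t_p <- if (is.null(tt)) NA_real_ else tt$p.value
  # one draw per mutation per iteration, from its own neighborhood
  use <- lengths(bg_per_record) > 0
  mc_p <- with_seed_(seed, {
    draws <- vapply(bg_per_record[use], function(w) {
      if (length(w) == 1) rep(w, mc_iters) else sample(w, mc_iters, replace = TRUE)
    }, numeric(mc_iters))
    iter_means <- if (is.matrix(draws)) rowMeans(draws) else as.numeric(draws)
    (1 + sum(iter_means >= obs_mean)) / (mc_iters + 1)
  })
  t_crit <- t_critical_value(alpha, n_tests)
  n_mut <- length(mut_w)
  significant <- if (n_mut < n_min || degenerate || is.na(t_stat)) {
    NA
  } else {
    (t_stat >= t_crit) && (mc_p < mc_alpha)
  }
  tibble(
    tissue = tissue, subclass = subclass,
    matrix_id = matrix_id %||% wm$name %||% "matrix",
    n_mutations = n_mut,
    mean_weight_mutated = obs_mean, mean_weight_background = bg_mean,
    ratio = ratio, t_statistic = t_stat, t_p = t_p, mc_p = mc_p,
    t_critical = t_crit, significant = significant,
    degenerate = degenerate, fraction = NA_real_
  )
}

#' Footprint test of one record group against one matrix
#'
#' The core statistic: the ratio of the mean weight of mutated sites to the
#' mean weight of the eligible non-mutated C/G sites in their 121-bp
#' neighborhoods, with two significance tests — a two-tailed Welch t-test
#' and a one-tailed Monte Carlo test that, per iteration, draws one random
#' eligible site from each mutation's own neighborhood and compares the
#' resampled mean to the observed mutated-site mean. A result is called
#' significant only when both gates pass (t above the Bonferroni-corrected
#' conservative critical value and MC p below `mc_alpha`).
#'
#' @inheritParams site_weights
#' @param mc_iters Monte Carlo iterations; p = (1 + k) / (iters + 1).
#' @param seed Optional seed for the Monte Carlo draws.
#' @param n_min Minimum mutations for a significance call (below it the
#'   call is NA).
#' @param n_tests Bonferroni family size for the t critical value.
#' @param alpha,mc_alpha Family-wise alpha for the t gate and per-test
#'   alpha for the MC gate.
#' @param matrix_id Label for the result row.
#' @return One-row tibble (a FootprintResult): n, means, ratio, t statistic
#'   and p, MC p, critical value, significance call.
#' @export
footprint <- function(wm, records, genome, mc_iters = 1000, seed = NULL,
                      n_min = 50, n_tests = 1, alpha = 0.05, mc_alpha = 0.05,
                      matrix_id = NULL) {
  prep <- prepare_sites(records, genome)
  footprint_prepared(wm, prep, matrix_id = matrix_id,
                     tissue = if (length(unique(records$tissue)) == 1)
                       records$tissue[1] else NA_character_,
                     subclass = if (length(unique(records$subclass)) == 1)
                       records$subclass[1] else NA_character_,
                     mc_iters = mc_iters, seed = seed, n_min = n_min,
                     n_tests = n_tests, alpha = alpha, mc_alpha = mc_alpha)
}

#' Footprint scan over groups and matrices
#'
#' Runs [footprint()] for every (tissue x substitution class) group against
#' every matrix, with a Bonferroni correction over the scan's total test
#' count and per-(group, matrix) random streams derived by hashing labels
#' from the master seed (so results are independent of iteration order).
#'
#' @param matrices Named list of `weight_matrix` objects.
#' @param records Mutation tibble.
#' @param genome Genome.
#' @param grouping Columns defining record groups.
#' @param n_tests Bonferroni family size; default groups x matrices.
#' @inheritParams footprint
#' @return Tibble with one FootprintResult row per (group x matrix).
#' @export
footprint_scan <- function(matrices, records, genome,
                           grouping = c("tissue", "subclass"),
                           mc_iters = 1000, seed = NULL, n_min = 50,
                           n_tests = NULL, alpha = 0.05, mc_alpha = 0.05) {
  stopifnot(length(matrices) >= 1)
  if (is.null(names(matrices))) {
    names(matrices) <- vapply(seq_along(matrices), function(i) {
      matrices[[i]]$name %||% paste0("matrix", i)
    }, character(1))
  }
  grouping <- intersect(grouping, names(records))
  groups <- dplyr::group_split(dplyr::group_by(records,
                                               dplyr::across(dplyr::all_of(grouping))))
  n_tests <- n_tests %||% (length(groups) * length(matrices))
  out <- purrr::map_dfr(groups, function(g) {
    prep <- prepare_sites(g, genome)
    tissue <- if ("tissue" %in% names(g)) g$tissue[1] else NA_character_
    subclass <- if ("subclass" %in% names(g)) g$subclass[1] else NA_character_
    purrr::imap_dfr(matrices, function(wm, id) {
      s <- if (is.null(seed)) NULL else label_seed(seed, tissue, subclass, id)
      footprint_prepared(wm, prep, matrix_id = id, tissue = tissue,
                         subclass = subclass, mc_iters = mc_iters, seed = s,
                         n_min = n_min, n_tests = n_tests, alpha = alpha,
                         mc_alpha = mc_alpha)
    })
  })
  attr(out, "n_tests") <- n_tests
  out
}

#' UPGMA clustering of a ratio table
#'
#' Average-linkage (UPGMA) clustering of the rows of a complete ratio
#' matrix under Euclidean distance, returned as a Newick string with branch
#' lengths (ultrametric: leaf-to-node depth = merge height / 2). Rows are
#' sorted by label first so ties break lexicographically.
#'
#' @param x Numeric matrix with row names (e.g. tissues x matrices), or a
#'   tibble whose first column holds row labels.
#' @param margin Cluster `"rows"` (default) or `"cols"`.
#' @return Newick string.
#' @export
upgma_cluster <- function(x, margin = c("rows", "cols")) {
  margin <- match.arg(margin)
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
  } else {
    m <- as.matrix(x)
  }
  if (margin == "cols") m <- t(m)
  if (anyNA(m)) abort("missing cells in ratio matrix; impute or drop first")
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "average")
  ape::write.tree(ape::as.phylo(hc))
}

#' Grayscale bin indices for heatmap export
#'
#' Maps values onto the discrete grayscale ramps used for footprint
#' heatmaps: `bin = floor((v - min) / step)`, clamped to the ramp; values
#' below `white_below` are white (NA).
#'
#' @param values Numeric vector.
#' @param min,max,step Ramp range and interval.
#' @param white_below Values strictly below this are white.
#' @return Integer bin indices (NA = white).
#' @export
heatmap_bins <- function(values, min, max, step, white_below = min) {
  n_bins <- floor((max - min) / step)
  bin <- floor((values - min) / step)
  bin <- pmin(pmax(bin, 0), n_bins)
  bin[values < white_below] <- NA_integer_
  as.integer(bin)
}

#' Default grayscale ramps per substitution class
#'
#' Ratio heatmaps use class-specific ramps (white below 1); the
#' false-positive-fraction control heatmap uses a 0.01–0.84 ramp with white
#' below 0.01.
#'
#' @return Tibble of (class, min, max, step, white_below).
#' @export
heatmap_class_config <- function() {
  tibble(
    class = c("C:G>T:A", "C:G>G:C", "C:G>A:T", "fp_fraction"),
    min = c(1, 1, 1, 0.01),
    max = c(1.573, 1.802, 1.362, 0.84),
    step = c(0.01, 0.01, 0.02, 0.05),
    white_below = c(1, 1, 1, 0.01)
  )
}

#' Export a footprint result table as heatmap gray levels
#'
#' @param results Footprint scan tibble.
#' @param value_col Column holding the plotted value.
#' @param class_col Column matched against the class config (use a constant
#'   e.g. "fp_fraction" for control maps).
#' @param config Ramp table as from [heatmap_class_config()].
#' @return `results` with an added integer `gray_bin` column.
#' @export
heatmap_export <- function(results, value_col = "ratio",
                           class_col = "subclass",
                           config = heatmap_class_config()) {
  cls <- if (class_col %in% names(results)) results[[class_col]] else
    rep(class_col, nrow(results))
  bins <- integer(nrow(results))
  for (k in unique(cls)) {
    cfg <- config[config$class == k, ]
    if (nrow(cfg) == 0) cfg <- tibble(min = 1, max = 2, step = 0.01, white_below = 1)
    sel <- cls == k
    bins[sel] <- heatmap_bins(results[[value_col]][sel], cfg$min, cfg$max,
                              cfg$step, cfg$white_below)
  }
  dplyr::mutate(results, gray_bin = bins)
}
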