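# Shared mid-size fixtures for footprint tests (built once per file).
g50 <- fixture_genome(50000, seed = 101)
wm_a3a <- build_weight_matrix(count_contexts(
  simulate_context_set(enzyme_motif_spec("APOBEC3A"), 500, seed = 102),
  name = "APOBEC3A"))

test_that("site weights follow records one-to-one", {
  wm <- fixture_matrix()
  sp <- as.character(wm$scoring_positions)
  maxi7 <- paste(BASES4[apply(wm$W[, sp], 2, which.max)], collapse = "")
  maxi11 <- paste0("AC", maxi7, "CA")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 65), substr(maxi11, 1, 11), strrep("A", 65))))
  rec <- make_records("chr1", 65 + 6, "C", "T")
  expect_equal(site_weights(wm, rec, g), 100)

  muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0.3, n = 120, seed = 103)
  expect_length(site_weights(wm_a3a, muts, g50), 120)
})

test_that("background weights pool every eligible neighborhood site", {
  muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0, n = 10, seed = 104)
  bw <- background_weights(wm_a3a, muts, g50)
  # conservation: pooled length equals the summed per-record site counts
  naive_all <- c()
  n_sites <- 0
  for (i in seq_len(nrow(muts))) {
    nb <- extract_neighborhood(g50, muts$chrom[i], muts$pos[i])
    chars <- strsplit(nb, "")[[1]]
    for (off in 5:115) {
      if (off == 60 || !(chars[off + 1] %in% c("C", "G"))) next
      n_sites <- n_sites + 1
      w11 <- substr(nb, off - 4, off + 6)
      if (chars[off + 1] == "G") w11 <- revcomp(w11)
      naive_all <- c(naive_all, naive_percent_score(wm_a3a$W, -3:3, w11))
    }
  }
  expect_length(bw, n_sites)
  # naive two-loop oracle reproduces the pooled weights
  expect_equal(bw, naive_all, tolerance = 1e-10)
})

test_that("footprint detects planted signal and stays null without one", {
  null_muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0, n = 400, seed = 105)
  res0 <- footprint(wm_a3a, null_muts, g50, mc_iters = 499, seed = 1)
  expect_lt(abs(res0$ratio - 1), 0.1)

  planted <- simulate_mutation_dataset(g50, wm_a3a, pi = 0.5, n = 2000, seed = 106)
  res1 <- footprint(wm_a3a, planted, g50, mc_iters = 1000, seed = 2)
  expect_gt(res1$ratio, 1)
  expect_equal(res1$mc_p, 1 / 1001)
  expect_true(res1$significant)
  expect_gt(res1$t_statistic, res1$t_critical)
})

test_that("Monte Carlo p on an enumerable toy matches exact enumeration", {
  # 3 records x 2 eligible sites each: enumerate all 2^3 equally likely
  # draw combinations for the exact null distribution of the mean
  wm <- fixture_matrix()
  seg <- function(core) paste0(strrep("A", 55), core, strrep("A", 55))
  # neighborhood core of 11 bases with center C at offset 60 and exactly
  # two other C sites inside the eligible range
  g <- Biostrings::DNAStringSet(c(
    r1 = seg("TTCAACATGAA"), r2 = seg("GATTACATTCA"), r3 = seg("ATCAACTTTGA")))
  recs <- make_records(c("r1", "r2", "r3"), rep(61L, 3), rep("C", 3), rep("T", 3))
  prep_bg <- lapply(seq_len(3), function(i) {
    nb <- extract_neighborhood(g, recs$chrom[i], 61L)
    ws <- eligible_background_sites(nb)
    percent_score(wm, deamfootprint:::neighborhood_windows(nb, ws))
  })
  expect_true(all(lengths(prep_bg) == 2))
  obs <- mean(site_weights(wm, recs, g))
  combos <- expand.grid(1:2, 1:2, 1:2)
  exact_means <- apply(combos, 1, function(ix) {
    mean(c(prep_bg[[1]][ix[1]], prep_bg[[2]][ix[2]], prep_bg[[3]][ix[3]]))
  })
  exact_p <- mean(exact_means >= obs)
  res <- footprint(wm, recs, g, mc_iters = 4000, seed = 9, n_min = 1)
  expect_lt(abs(res$mc_p - exact_p), 0.05)
})

test_that("ratio and tests are invariant to record order and weight scale", {
  muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0.4, n = 300, seed = 107)
  scan1 <- footprint_scan(list(A = wm_a3a), muts, g50, mc_iters = 199, seed = 5)
  perm <- muts[sample(nrow(muts)), ]
  scan2 <- footprint_scan(list(A = wm_a3a), perm, g50, mc_iters = 199, seed = 5)
  expect_equal(scan1$ratio, scan2$ratio)
  expect_equal(scan1$mc_p, scan2$mc_p)

  # scale-free ratio: percent weights rescaled by c > 0 leave the ratio
  # unchanged (equivalently: the ratio of means equals the scaled ratio)
  mut_w <- site_weights(wm_a3a, muts, g50)
  bg_w <- background_weights(wm_a3a, muts, g50)
  r <- mean(mut_w) / mean(bg_w)
  expect_equal(mean(3.7 * mut_w) / mean(3.7 * bg_w), r)
})

test_that("footprint_scan reduces to footprint and covers all cells", {
  muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0.3, n = 200, seed = 108)
  single <- footprint(wm_a3a, muts, g50, mc_iters = 199, seed = 11,
                      matrix_id = "A")
  scanned <- footprint_scan(list(A = wm_a3a), muts, g50, mc_iters = 199,
                            seed = 11, n_tests = 1)
  expect_equal(scanned$ratio, single$ratio)
  expect_equal(scanned$t_statistic, single$t_statistic)

  wm_aid <- build_weight_matrix(count_contexts(
    simulate_context_set(enzyme_motif_spec("AID"), 300, seed = 109),
    name = "AID"))
  two_cls <- simulate_mutation_dataset(
    g50, wm_a3a, pi = 0.2, n = 300,
    subclass_mix = c("C:G>T:A" = 0.5, "C:G>G:C" = 0.5), seed = 110)
  scan <- footprint_scan(list(A = wm_a3a, AID = wm_aid), two_cls, g50,
                         mc_iters = 99, seed = 12)
  expect_equal(nrow(scan), 2L * 2L) # groups x matrices
  expect_equal(attr(scan, "n_tests"), 4L)

  # conservative large-sample critical value for a 24-test family
  expect_equal(round(t_critical_value(0.05, 24), 1), 3.1)
})

test_that("groups below n_min are reported without a significance call", {
  muts <- simulate_mutation_dataset(g50, wm_a3a, pi = 0.5, n = 30, seed = 111)
  res <- footprint(wm_a3a, muts, g50, mc_iters = 99, seed = 3, n_min = 50)
  expect_true(is.na(res$significant))
  expect_equal(res$n_mutations, 30L)
})

test_that("UPGMA clustering matches hand execution and the naive oracle", {
  # d(A,B) = 2, d(A,C) = d(B,C) = 4: ((A,B),C), A-B cophenetic distance 2
  m <- rbind(A = c(0, 0), B = c(2, 0), C = c(1, sqrt(15)))
  nwk <- upgma_cluster(m)
  phy <- ape::read.tree(text = nwk)
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_equal(coph["B", "C"], 4)

  # identical rows merge at height zero
  m2 <- rbind(X = c(1, 1), Y = c(1, 1), Z = c(5, 5))
  coph2 <- ape::cophenetic.phylo(ape::read.tree(text = upgma_cluster(m2)))
  expect_equal(coph2["X", "Y"], 0)

  # random 6x6 ratio tables vs the O(n^3) oracle
  set.seed(77)
  for (i in 1:5) {
    mm <- matrix(runif(36), 6, dimnames = list(paste0("t", 1:6), paste0("m", 1:6)))
    coph_pkg <- ape::cophenetic.phylo(ape::read.tree(text = upgma_cluster(mm)))
    coph_naive <- naive_upgma_cophenetic(dist(mm))
    expect_equal(coph_pkg[rownames(coph_naive), colnames(coph_naive)],
                 coph_naive, tolerance = 1e-9)
  }

  expect_error(upgma_cluster(rbind(A = c(1, NA), B = c(1, 2))), "missing cells")
})

test_that("heatmap binning follows the published grayscale ramps", {
  # C:G>T:A ramp: 1 to 1.573 step 0.01, white below 1
  expect_true(is.na(heatmap_bins(0.99, 1, 1.573, 0.01)))
  expect_equal(heatmap_bins(1.0, 1, 1.573, 0.01), 0L)
  expect_equal(heatmap_bins(1.573, 1, 1.573, 0.01), 57L)
  expect_equal(heatmap_bins(9.9, 1, 1.573, 0.01), 57L) # clamped to darkest

  set.seed(13)
  v <- runif(100, 0.9, 2)
  got <- heatmap_bins(v, 1, 1.573, 0.01)
  naive <- vapply(v, function(x) {
    if (x < 1) return(NA_integer_)
    as.integer(min(max(floor((x - 1) / 0.01), 0), floor(0.573 / 0.01)))
  }, integer(1))
  expect_equal(got, naive)

  res <- tibble::tibble(tissue = "t", matrix_id = "m", subclass = "C:G>T:A",
                        ratio = c(0.95, 1.25))
  out <- heatmap_export(res)
  expect_equal(out$gray_bin, c(NA, 25L))
})
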