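test_that("read_genome normalizes case and U and enforces unique names", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta_lines(f, list(chrA = strrep("acgu", 250), chrB = "ACGTACGTACGT"))
  g <- read_genome(f)
  expect_equal(length(g), 2L)
  expect_equal(Biostrings::width(g)[names(g) == "chrA"], 1000L)
  expect_equal(substr(as.character(g[["chrA"]]), 1, 4), "ACGT")

  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta_lines(f2, list(dup = "ACGT", dup = "ACGT"))
  expect_error(read_genome(f2), "duplicate")
})

test_that("read_mutations validates rows and conserves every input row", {
  g <- fixture_genome(2000, seed = 1)
  gs <- as.character(g[[1]])
  pos_ok <- which(strsplit(gs, "")[[1]] == "C")
  pos_ok <- pos_ok[pos_ok > 60 & pos_ok <= 2000 - 60][1:3]
  tbl <- tibble::tibble(
    sample = "s", chrom = "chr1",
    pos = c(pos_ok, pos_ok[1], 30, pos_ok[2]),
    ref = c("C", "C", "C", "G", "C", "C"),
    alt = c("T", "T", "T", "A", "T", "C"),
    tissue = "t"
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, f)
  rec <- suppressMessages(read_mutations(f, g))
  rej <- rejection_report(rec)
  expect_equal(nrow(rec), 3L)
  expect_equal(nrow(rec) + nrow(rej), nrow(tbl))
  expect_setequal(rej$reason, c("ref_mismatch", "edge", "bad_alleles"))
  expect_true(all(rec$subclass == "C:G>T:A"))

  expect_error(read_mutations(tibble::tibble(sample = "s"), g), "missing columns")
})

test_that("strand collapse maps all twelve substitutions to six classes", {
  expect_equal(classify_substitution("C", "T"), "C:G>T:A")
  expect_equal(classify_substitution("G", "A"), "C:G>T:A")
  expect_equal(classify_substitution("C", "G"), "C:G>G:C")
  expect_equal(classify_substitution("G", "C"), "C:G>G:C")
  expect_equal(classify_substitution("C", "A"), "C:G>A:T")
  expect_equal(classify_substitution("G", "T"), "C:G>A:T")
  expect_equal(classify_substitution("T", "C"), "T:A>C:G")
  expect_equal(classify_substitution("A", "G"), "T:A>C:G")
  expect_equal(classify_substitution("T", "G"), "T:A>G:C")
  expect_equal(classify_substitution("A", "C"), "T:A>G:C")
  expect_equal(classify_substitution("T", "A"), "T:A>A:T")
  expect_equal(classify_substitution("A", "T"), "T:A>A:T")
})

test_that("window extraction strand-normalizes to a central C", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 70), "GTTAA", "C", "AATTG", strrep("A", 70))))
  w <- extract_window(seqs, "chr1", 76L, "C")
  expect_equal(as.character(w), "GTTAACAATTG")
  expect_equal(attr(w, "strand"), "+")

  # a G site returns the reverse complement with center C
  seqs2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 70), "CAATT", "G", "TTAAC", strrep("T", 70))))
  w2 <- extract_window(seqs2, "chr1", 76L, "G")
  expect_equal(as.character(w2), "GTTAACAATTG")
  expect_equal(attr(w2, "strand"), "-")
})

test_that("analysis is invariant under reverse-complementing the genome", {
  g <- fixture_genome(3000, seed = 5)
  gs <- as.character(g[[1]])
  len <- nchar(gs)
  rc <- Biostrings::DNAStringSet(setNames(revcomp(gs), "chr1"))
  chars <- strsplit(gs, "")[[1]]
  pos <- which(chars %in% c("C", "G"))
  pos <- sample(pos[pos > 60 & pos <= len - 60], 50)
  for (p in pos) {
    w1 <- extract_window(g, "chr1", p, chars[p])
    mirrored <- len - p + 1L
    w2 <- extract_window(rc, "chr1", mirrored, COMP4[[chars[p]]])
    expect_equal(as.character(w1), as.character(w2))
  }
})

test_that("neighborhood extraction enforces the 121-bp contract", {
  g <- Biostrings::DNAStringSet(c(tiny = paste(
    c(strrep("A", 60), "C", strrep("T", 60)), collapse = "")))
  nb <- extract_neighborhood(g, "tiny", 61L)
  expect_equal(nchar(nb), 121L)
  expect_equal(substr(nb, 61, 61), "C")
  expect_error(extract_neighborhood(g, "tiny", 60L), "edge")

  # center equals ref across random fixture records
  g2 <- fixture_genome(5000, seed = 2)
  chars <- strsplit(as.character(g2[[1]]), "")[[1]]
  pos <- which(chars == "C")
  pos <- pos[pos > 60 & pos <= 5000 - 60][1:20]
  for (p in pos) {
    expect_equal(substr(extract_neighborhood(g2, "chr1", p), 61, 61), "C")
  }
})

test_that("eligible background sites match a brute-force scan", {
  nb <- paste(c(strrep("A", 60), "C", strrep("A", 60)), collapse = "")
  expect_length(eligible_background_sites(nb), 0)

  # C at every even offset; eligible ones are those in 5..115 except 60
  nb2 <- paste(rep(c("C", "A"), length.out = 121), collapse = "")
  off2 <- eligible_background_sites(nb2)
  expect_equal(off2, as.integer(setdiff(seq(6L, 114L, by = 2L), 60L)))

  set.seed(8)
  for (i in 1:20) {
    nb3 <- paste(sample(BASES4, 121, replace = TRUE), collapse = "")
    chars <- strsplit(nb3, "")[[1]]
    naive <- c()
    for (off in 0:120) {
      if (off >= 5 && off <= 115 && off != 60 && chars[off + 1] %in% c("C", "G")) {
        naive <- c(naive, off)
      }
    }
    expect_equal(eligible_background_sites(nb3), as.integer(naive))
  }
})

test_that("context shuffling preserves composition and fixes the center", {
  w <- "AAAAACAAAAA"
  expect_equal(shuffle_context(w), w)

  win <- fixture_contexts(5, seed = 21)
  set.seed(1)
  for (i in 1:50) {
    sh <- shuffle_context(win)
    expect_equal(substr(sh, 6, 6), substr(win, 6, 6))
    for (k in seq_along(win)) {
      expect_equal(sort(strsplit(sh[k], "")[[1]]), sort(strsplit(win[k], "")[[1]]))
    }
  }
})

test_that("flank shuffling is uniform over permutation orbits", {
  # flanks hold a single T whose shuffled position should be uniform
  # over the 10 flank slots
  w <- "AACCCCCCCCT"
  set.seed(33)
  draws <- replicate(2000, shuffle_context(w))
  t_pos <- vapply(strsplit(draws, ""), function(ch) which(ch[-6] == "T"),
                  integer(1))
  counts <- table(factor(t_pos, levels = 1:10))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("composition-matched sampling honors tolerance and feasibility", {
  g <- fixture_genome(20000, seed = 3)
  template <- fixture_contexts(100, seed = 9)
  for (s in 1:3) {
    win <- sample_matched_sites(g, template, seed = s)
    expect_length(win, length(template))
    expect_equal(substr(win, 6, 6), rep("C", 100))
    tgt <- table(factor(unlist(strsplit(template, "")), levels = BASES4))
    got <- table(factor(unlist(strsplit(win, "")), levels = BASES4))
    expect_true(all(abs(got / sum(got) - tgt / sum(tgt)) <= 0.01 + 1e-9))
  }

  # GC-rich template vs AT-rich genome is infeasible
  at_genome <- simulate_genome(5000, c(0.48, 0.02, 0.02, 0.48), seed = 4)
  gc_template <- rep("GCGCGCGCGCG", 50)
  expect_error(
    sample_matched_sites(at_genome, gc_template, max_attempts = 25, seed = 1),
    "composition unmatchable")
})

test_that("A/T-content filter is inclusive at the threshold and idempotent", {
  half_at <- "AATTACGCGCG"   # flanks AATTA + GCGCG: 5 of 10 A/T -> removed
  gc_only <- "GGCCGCGCCGG"
  out <- at_content_filter(c(half_at, gc_only))
  expect_equal(out, gc_only, ignore_attr = TRUE)
  expect_equal(attr(out, "n_removed"), 1L)
  # idempotent
  out2 <- at_content_filter(out)
  expect_equal(as.character(out2), as.character(out))
  # tibble input filters rows
  tb <- tibble::tibble(window = c(half_at, gc_only), id = 1:2)
  expect_equal(at_content_filter(tb)$id, 2L)
})

test_that("context sets and weight matrices round-trip through disk", {
  win <- fixture_contexts(40, seed = 17)
  f <- withr::local_tempfile(fileext = ".txt")
  write_context_set(win, f)
  expect_equal(read_context_set(f), win)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta_lines(fa, setNames(as.list(win[1:5]), paste0("w", 1:5)))
  expect_equal(read_context_set(fa), win[1:5])

  wm <- fixture_matrix(80, seed = 19)
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_weight_matrix(wm, fm)
  back <- read_weight_matrix(fm)
  expect_equal(back$W, wm$W, tolerance = 1e-9)
  expect_equal(back$smin, wm$smin, tolerance = 1e-9)
  expect_equal(back$smax, wm$smax, tolerance = 1e-9)
  expect_equal(back$scoring_positions, wm$scoring_positions)
  win2 <- fixture_contexts(10, seed = 23)
  expect_equal(percent_score(back, win2), percent_score(wm, win2),
               tolerance = 1e-9)
})
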