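test_that("aggregate_signal_profile: constants, identity smoothing, means", {
  tr <- signal_track("chr1", 0, 1000, 2.5)
  centers <- data.frame(chrom = "chr1", pos = c(300, 600))
  prof <- aggregate_signal_profile(tr, centers, flank = 50, smooth_window = 5)
  expect_equal(prof, rep(2.5, 101))

  # single center, smooth_window 1 -> raw per-base values
  tr2 <- random_track("chr1", 1000L, 12L, 5)
  p2 <- aggregate_signal_profile(tr2, data.frame(chrom = "chr1", pos = 500),
                                 flank = 20, smooth_window = 1)
  expect_equal(p2, dense_track(tr2, "chr1", 1000L)[480:520])

  # two centers with values 1s and 3s -> profile of 2s
  tr3 <- signal_track(c("chr1", "chr1"), c(0, 500), c(400, 900), c(1, 3))
  p3 <- aggregate_signal_profile(tr3, data.frame(chrom = "chr1",
                                                 pos = c(200, 700)),
                                 flank = 30, smooth_window = 3)
  expect_equal(p3, rep(2, 61))

  expect_error(aggregate_signal_profile(tr, centers[0, ], 50, 1), "empty")
  expect_error(aggregate_signal_profile(tr, centers, 50, 4), "odd")
})

test_that("smoothing equals an independent truncated-window oracle", {
  set.seed(11)
  x <- rnorm(41)
  tr <- signal_track("chr1", 0:40, 1:41, abs(x))
  p <- aggregate_signal_profile(tr, data.frame(chrom = "chr1", pos = 21),
                                flank = 20, smooth_window = 7)
  oracle <- vapply(seq_len(41), function(i)
    mean(abs(x)[max(1, i - 3):min(41, i + 3)]), 0)
  expect_equal(p, oracle, tolerance = 1e-12)
})

test_that("triangle coordinates count inclusively at both boundaries", {
  expect_equal(triangle_coordinates(c(0.95, 0.91, 0.05, 0.5)),
               c(N1 = 2, N2 = 1))
  expect_equal(triangle_coordinates(rep(1, 7)), c(N1 = 7, N2 = 0))
  expect_equal(triangle_coordinates(c(0.90, 0.10)), c(N1 = 1, N2 = 1))
  expect_error(triangle_coordinates(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force oracle on random matrices
  set.seed(21)
  m <- matrix(runif(300), 30, 10)
  co <- triangle_coordinates(m)
  for (i in seq_len(30)) {
    expect_equal(co$N1[i], sum(m[i, ] >= 0.9))
    expect_equal(co$N2[i], sum(m[i, ] <= 0.1))
  }
})

test_that("conservation group assignment follows G1 > G3 > G2 precedence", {
  # defaults: S = 10, two primates -> 8 non-primates
  expect_equal(assign_conservation_groups(8, 0, 10, 0, 8), "G1")
  expect_equal(assign_conservation_groups(3, 4, 10, 3, 8), "G2")
  expect_equal(assign_conservation_groups(0, 7, 10, 7, 8), "G3")
  expect_equal(assign_conservation_groups(0, 0, 10, 0, 8), "other")
  # primate-conserved element: lots of aligned primates, absent elsewhere
  expect_equal(assign_conservation_groups(2, 7, 10, 7, 8), "G3")
})

test_that("planted conservation groups are recovered perfectly", {
  w <- small_world()
  aln <- simulate_alignment_fractions(w$truth, seed = 31)
  expect_true(all(aln$fractions >= 0 & aln$fractions <= 1))
  grp <- conservation_groups(aln$fractions, aln$species)
  expect_equal(unname(grp), unname(w$truth$cons_group[names(grp)]))
})

test_that("triangle slices are near-uniform on a uniform grid", {
  grid <- expand.grid(n1 = 0:7, n2 = 0:7)
  sl <- triangle_slices(grid$n1, grid$n2)
  counts <- table(sl)
  expect_length(counts, 16L)
  expect_true(all(abs(counts - 4) <= 1))
  # brute-force: element with maximal N1 sits in the top row
  expect_true(all(sl[grid$n1 == 7] > 12))
  expect_warning(sl2 <- triangle_slices(rep(1, 20), rep(1, 20)), "degenerate")
  expect_true(all(sl2 == sl2[1]))
})

test_that("evolutionary origin picks the most distant aligned clade", {
  sp <- data.frame(species = c("chimp", "macaque", "mouse"),
                   clade = c("great-ape", "old-world-monkey", "non-primate"),
                   distance_rank = 1:3)
  m <- matrix(c(0.9, 0.8, 0.1,
                0.1, 0.0, 0.2,
                0.9, 0.2, 0.95), 3, 3, byrow = TRUE,
              dimnames = list(c("e1", "e2", "e3"), sp$species))
  o <- evolutionary_origin(m, sp)
  expect_identical(unname(o), c("old-world-monkey", "human-specific",
                                "non-primate"))
})

test_that("matched controls equal C+G and CpG counts exactly, reproducibly", {
  w <- small_world()
  els <- w$elements[1:8]
  ctrl <- suppressWarnings(matched_controls(els, w$genome, seed = 77))
  expect_gt(length(ctrl), 0L)
  for (i in seq_along(ctrl)) {
    src <- S4Vectors::mcols(ctrl)$source[i]
    el <- els[src]
    cs <- bccre:::gc_cpg_counts(Biostrings::subseq(
      w$genome[[as.character(GenomicRanges::seqnames(ctrl))[i]]],
      GenomicRanges::start(ctrl)[i], GenomicRanges::end(ctrl)[i]))
    es <- bccre:::gc_cpg_counts(Biostrings::subseq(
      w$genome[[as.character(GenomicRanges::seqnames(el))]],
      GenomicRanges::start(el), GenomicRanges::end(el)))
    expect_identical(cs, es)
  }
  ctrl2 <- suppressWarnings(matched_controls(els, w$genome, seed = 77))
  expect_identical(as.character(ctrl), as.character(ctrl2))
  # exhaustion path: one attempt almost surely fails for a 300-bp element
  expect_warning(
    try(matched_controls(els[1], w$genome, seed = 1, max_attempts = 1L),
        silent = TRUE))
})

test_that("gc_cpg_counts matches the hand-counted example", {
  cs <- bccre:::gc_cpg_counts(Biostrings::DNAString("ACGCG"))
  expect_equal(unname(cs["gc"]), 4)
  expect_equal(unname(cs["cpg"]), 2)
})
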