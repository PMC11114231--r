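test_that("fractional validation weighting reproduces the worked examples", {
  # region 1 fully contains one adult-specific and one fetal-specific element
  # region 2 fully contains one adult-specific element and half an nb element
  # region 3 touches nothing
  els <- element_set("chr1", c(100, 300, 1000, 1200), c(200, 400, 1100, 1400),
                     id = c("a1", "f1", "a2", "n1"),
                     label = c("adult-specific", "fetal-specific",
                               "adult-specific", "nb-cCRE"))
  reg <- element_set("chr1", c(50, 950, 5000), c(450, 1300, 5100),
                     id = c("r1", "r2", "r3"))
  res <- vista_weighted_validation(reg, els)
  w <- res$weights["all", ]
  expect_equal(unname(w["adult-specific"]), 0.5 + 2 / 3)
  expect_equal(unname(w["fetal-specific"]), 0.5)
  expect_equal(unname(w["nb-cCRE"]), 1 / 3)
  expect_equal(unname(w["non-cCRE"]), 1)
  # total weight equals the number of regions (to 1e-9)
  expect_equal(sum(res$weights), 3, tolerance = 1e-9)
})

test_that("weights sum to region count for arbitrary inputs", {
  w <- small_world()
  lab <- ifelse(w$truth$life_stage == "non-brain", "nb-cCRE",
                w$truth$life_stage)
  cls <- w$elements
  S4Vectors::mcols(cls)$label <- unname(lab[names(cls)])
  aux <- simulate_expression_and_regions(w$truth, w$elements, seed = 13,
                                         n_regions = 40)
  res <- vista_weighted_validation(aux$regions, cls)
  expect_equal(sum(res$weights), length(aux$regions), tolerance = 1e-9)
})

test_that("tissue classification follows the brain > nervous > other order", {
  expect_equal(classify_validation_tissue(c("forebrain", "eye")), "brain")
  expect_equal(classify_validation_tissue("eye"), "nervous-nonbrain")
  expect_equal(classify_validation_tissue("limb"), "non-nervous")
  expect_equal(classify_validation_tissue(character()), "inactive")
  expect_warning(cl <- classify_validation_tissue("mystery organ"), "unknown")
  expect_equal(cl, "non-nervous")
})

test_that("shuffle enrichment: saturated targets give 1, planted give ~ratio", {
  gs <- c(chr1 = 100000)
  q <- element_set("chr1", seq(0, 99000, by = 2000), seq(100, 99100, by = 2000))
  # targets covering the entire genome -> every placement intersects
  all_t <- element_set("chr1", 0, 100000)
  r <- shuffle_enrichment(q, all_t, gs, n_shuffles = 20, seed = 4)
  expect_equal(r$enrichment, 1.0)
  expect_equal(r$observed, length(q))

  # planted query entirely inside targets covering ~10% of the genome
  targ <- element_set("chr1", 0, 10000)
  q2 <- element_set("chr1", seq(0, 9000, by = 500), seq(100, 9100, by = 500),
                    id = paste0("q", 1:19))
  r2 <- shuffle_enrichment(q2, targ, gs, n_shuffles = 200, seed = 4)
  # binomial oracle: hit probability ~ (10000 + w) / 100000 per interval
  p_hit <- (10000 + 100) / 100000
  expect_gt(r2$enrichment, 19 / (19 * p_hit) * 0.7)
  expect_lt(r2$enrichment, 19 / (19 * p_hit) * 1.5)
  expect_error(shuffle_enrichment(q2, element_set("chr2", 0, 1)[0], gs),
               "empty target")
})

test_that("TSS windows clip at zero and stay unmerged", {
  tss <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                    pos = c(200000, 50, 200050))
  w <- window_targets_from_tss(tss, window = 100000)
  expect_equal(GenomicRanges::start(w)[2], 100001)  # [100000, 300000)
  expect_equal(GenomicRanges::end(w)[2], 300000)
  w2 <- window_targets_from_tss(data.frame(chrom = "chr1", pos = 50),
                                window = 100)
  expect_equal(GenomicRanges::start(w2), 1)   # clipped at 0
  expect_equal(GenomicRanges::end(w2), 150)
  expect_length(w, 3L)  # overlapping windows are not merged
})

test_that("priority assignment respects class order and region-order invariance", {
  shared <- element_set("chr1", 100, 200, id = "s")
  fetal <- element_set("chr1", 150, 250, id = "f")
  nb <- element_set("chr1", 400, 500, id = "n")
  sets <- list("shared" = shared, "fetal" = fetal, "nb-cCRE" = nb)
  reg <- element_set("chr1", c(120, 420, 900), c(260, 430, 950),
                     id = c("r1", "r2", "r3"))
  lab <- priority_assign(reg, sets)
  expect_identical(unname(lab[c("r1", "r2", "r3")]),
                   c("shared", "nb-cCRE", "non-cCRE"))
  # invariant to internal region order
  lab2 <- priority_assign(rev(reg), sets)
  expect_identical(lab2[names(lab)], lab)
})

test_that("greedy trait selection satisfies the pairwise constraint", {
  rg <- diag(3)
  rg[1, 2] <- rg[2, 1] <- 0.5
  rg[1, 3] <- rg[3, 1] <- 0.1
  dimnames(rg) <- list(paste0("t", 1:3), paste0("t", 1:3))
  # independent oracle: replay the greedy rule for the seeded order
  for (seed in 1:5) {
    kept <- select_independent_traits(rg, seed = seed)
    set.seed(seed)
    ord <- sample.int(3)
    exp_kept <- integer()
    for (i in ord) if (all(rg[i, exp_kept]^2 <= 0.1)) exp_kept <- c(exp_kept, i)
    expect_identical(kept, rownames(rg)[exp_kept])
  }
  # all-zero correlations keep everything
  expect_length(select_independent_traits(diag(5), seed = 1), 5L)
  # missing correlations count as zero
  rgna <- diag(3)
  rgna[1, 2] <- rgna[2, 1] <- 0.9
  rgna[1, 3] <- rgna[3, 1] <- NA
  dimnames(rgna) <- list(paste0("t", 1:3), paste0("t", 1:3))
  for (seed in 1:5) {
    kept <- select_independent_traits(rgna, seed = seed)
    expect_false(all(c("t1", "t2") %in% kept))
    expect_true("t3" %in% kept)
  }
  expect_error(select_independent_traits(matrix(0, 2, 3)), "square")
})
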