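sticky_model <- function() {
  # hand-built model: sticky states, each preferring its own symbol but
  # tolerating zeros, so the zero-run split rule (not decoding) is exercised
  list(init = c(0.2, 0.6, 0.2),
       trans = matrix(c(0.999, 0.0005, 0.0005,
                        0.0005, 0.999, 0.0005,
                        0.0005, 0.0005, 0.999), 3, byrow = TRUE),
       emis = matrix(c(0.5, 0.5, 0.0,
                       0.005, 0.99, 0.005,
                       0.0, 0.5, 0.5), 3, byrow = TRUE))
}

test_that("importance z-scores and discretization follow strict thresholds", {
  x <- matrix(rnorm(200), 10, 20)
  z <- importance_zscores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(importance_zscores(matrix(1, 3, 3)), "degenerate")

  expect_identical(discretize_importance(c(2.5, -2.5, 0)), c(1L, -1L, 0L))
  expect_identical(discretize_importance(c(1.96, -1.96)), c(0L, 0L))
  expect_identical(discretize_importance(rep(0, 5)), rep(0L, 5))
})

test_that("Baum-Welch: degenerate input, monotone likelihood, relabeling", {
  m <- fit_importance_hmm(matrix(0L, 3, 40), seed = 1)
  expect_gte(m$emis["zero", "0"], 0.99)
  expect_true(m$degenerate)

  set.seed(5)
  seqs <- matrix(sample(c(-1L, 0L, 1L), 600, replace = TRUE,
                        prob = c(0.1, 0.8, 0.1)), 5, 120)
  m2 <- fit_importance_hmm(seqs, seed = 2)
  expect_true(all(diff(m2$loglik) > -1e-6))
  expect_false(m2$degenerate)
  # relabeled: state order neg/zero/pos by preferred symbol
  expect_equal(unname(which.max(m2$emis[, "0"])), 2L)
  expect_true(all(abs(rowSums(m2$trans) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m2$emis) - 1) < 1e-9))
  expect_error(fit_importance_hmm(list(integer())), "non-empty")
})

test_that("planted blocks are recovered with base-level Jaccard >= 0.7", {
  set.seed(42)
  nw <- 30L; len <- 200L
  sym <- matrix(0L, nw, len)
  truth <- matrix(FALSE, nw, len)
  for (i in seq_len(nw)) {
    for (b in 1:2) {
      st <- sample(10:(len - 20), 1)
      L <- sample(8:14, 1)
      block <- st:(st + L - 1)
      sym[i, block] <- sample(c(1L, 0L), L, replace = TRUE, prob = c(0.85, 0.15))
      truth[i, block] <- TRUE
    }
    noise <- sample(len, 4)
    sym[i, noise] <- ifelse(truth[i, noise], sym[i, noise],
                            sample(c(-1L, 1L), 4, replace = TRUE))
  }
  model <- fit_importance_hmm(sym, seed = 3)
  calls <- call_ctfbs(model, sym)
  called <- matrix(FALSE, nw, len)
  for (k in seq_len(nrow(calls))) {
    w <- calls$window[k]
    called[w, calls$start[k]:calls$end[k]] <- TRUE
  }
  jac <- sum(called & truth) / sum(called | truth)
  expect_gte(jac, 0.7)
})

test_that("segment splitting excises runs of >= 4 zeros", {
  m <- sticky_model()
  df <- segment_ctfbs(m, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(nrow(df), 2L)
  expect_equal(df$start, c(1L, 8L))
  expect_equal(df$end, c(2L, 9L))
  expect_true(all(df$direction == "positive"))

  df2 <- segment_ctfbs(m, c(1L, 1L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(nrow(df2), 1L)
  expect_equal(c(df2$start, df2$end), c(1L, 7L))

  expect_equal(nrow(segment_ctfbs(m, rep(0L, 30))), 0L)

  # negative-state segments carry negative direction and mean importance
  imp <- c(-3, -3, -2.5, 0, 0)
  df3 <- segment_ctfbs(m, c(-1L, -1L, -1L, 0L, 0L), importance = imp)
  expect_equal(df3$direction[1], "negative")
  expect_lt(df3$mean_importance[1], 0)
})

test_that("motif similarity handles padding, N bases and strands", {
  pwm_ac <- pwm_from_consensus("AC")
  expect_equal(motif_similarity("ACG", pwm_ac, both_strands = FALSE), 2.25)
  # equal-length consensus match attains the maximum L
  pwm5 <- pwm_from_consensus("ACGTA")
  expect_equal(motif_similarity("ACGTA", pwm5), 5)
  # N convention
  expect_equal(motif_similarity("NNN", pwm_from_consensus("ACG")), 0.75)
  # sequence shorter than motif: symmetric 0.25 padding
  expect_equal(motif_similarity("AC", pwm_from_consensus("GACT"),
                                both_strands = FALSE), 2 + 2 * 0.25)
  # strand symmetry
  set.seed(8)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
    pwm <- pwm_from_consensus(paste(
      sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""), p = 0.7)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(motif_similarity(s, pwm), motif_similarity(rc, pwm))
  }
  expect_error(motif_similarity("", pwm_ac), "empty")
})

test_that("best-motif assignment finds planted consensi and breaks ties", {
  set.seed(10)
  cons <- c("ACGTACGT", "GGGGCCCC", "TTTTAAAA", "CACACACA", "GTGTGTGT")
  catalog <- setNames(lapply(cons, pwm_from_consensus, p = 0.9),
                      paste0("M", 1:5))
  res <- assign_best_motif("GGGGCCCC", catalog)
  expect_equal(res$motif, "M2")
  # single-motif catalog
  expect_equal(assign_best_motif("AAAA", catalog["M3"])$motif, "M3")
  # identical PWMs: lexicographically smallest id wins
  cat2 <- list(A1 = pwm_from_consensus("ACGT"), A0 = pwm_from_consensus("ACGT"))
  expect_equal(assign_best_motif("ACGT", cat2)$motif, "A0")
})

test_that("chi-square comparison matches the textbook Yates oracle", {
  yates <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    num <- n * (abs(a * d - b * c) - n / 2)^2
    num / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  res <- motif_set_chi2(c(m = 30L), 1000L, c(m = 10L), 1000L,
                        min_instances = 5L)
  expect_equal(res$chi2, yates(30, 970, 10, 990), tolerance = 1e-9)
  expect_equal(res$p, stats::pchisq(yates(30, 970, 10, 990), 1,
                                    lower.tail = FALSE), tolerance = 1e-9)
  # random tables
  set.seed(12)
  for (rep in 1:10) {
    a <- sample(25:500, 1); b <- sample(25:500, 1)
    ta <- a + sample(500:2000, 1); tb <- b + sample(500:2000, 1)
    r <- motif_set_chi2(c(x = a), ta, c(x = b), tb)
    expect_equal(r$chi2, yates(a, ta - a, b, tb - b), tolerance = 1e-9)
  }
  # equal proportions give p = 1 (chi2 = 0 after correction cap)
  r0 <- motif_set_chi2(c(m = 50L), 500L, c(m = 50L), 500L)
  expect_equal(r0$p, 1)
  # instance floor
  expect_equal(nrow(motif_set_chi2(c(m = 20L), 100L, c(m = 40L), 100L)), 0L)
})

test_that("site specificity is a 1-bp-overlap predicate", {
  a <- element_set("chr1", c(0, 100), c(10, 110), id = c("a1", "a2"))
  b <- element_set("chr1", c(9, 500), c(20, 510), id = c("b1", "b2"))
  cls <- site_specificity_classes(a, b)
  expect_identical(unname(cls[c("a1", "a2", "b1", "b2")]),
                   c("shared", "a-only", "shared", "b-only"))
  same <- site_specificity_classes(a, a)
  expect_true(all(same == "shared"))
})

test_that("site importance profiles average aligned windows per cell type", {
  trA <- signal_track("chr1", 0, 1000, 2.0)
  trB <- signal_track("chr1", 0, 1000, 5.0)
  sites <- element_set("chr1", c(300, 600), c(320, 620), id = c("s1", "s2"))
  prof <- site_importance_profiles(sites, list(A = trA, B = trB), flank = 10)
  expect_equal(unname(prof["A", ]), rep(2, 21))
  expect_equal(unname(prof["B", ]), rep(5, 21))
  expect_error(site_importance_profiles(sites[0], list(A = trA)), "empty")
})

test_that("MEME and JASPAR catalog IO round-trips", {
  catalog <- list(MA0001 = pwm_from_consensus("ACGTAC", p = 0.7),
                  MA0002 = pwm_from_consensus("GGATC", p = 0.85))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(catalog, f)
  back <- read_meme(f)
  expect_identical(names(back), names(catalog))
  expect_equal(back$MA0001, catalog$MA0001, tolerance = 1e-5,
               ignore_attr = TRUE)

  jf <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0099 TEST",
               "A [ 10  0  0 ]",
               "C [  0 10  5 ]",
               "G [  0  0  5 ]",
               "T [  0  0  0 ]"), jf)
  jp <- read_jaspar_pfm(jf)
  expect_equal(jp$MA0099[, 3], c(A = 0, C = 0.5, G = 0.5, T = 0))
})
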