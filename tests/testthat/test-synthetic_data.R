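test_that("genome/element generation is deterministic and validated", {
  w1 <- generate_genome_and_elements(7, n_chroms = 2, chrom_len = 5e4,
                                     n_elements = 60, element_len = 200)
  w2 <- generate_genome_and_elements(7, n_chroms = 2, chrom_len = 5e4,
                                     n_elements = 60, element_len = 200)
  expect_identical(as.character(w1$genome), as.character(w2$genome))
  expect_identical(w1$truth, w2$truth)
  expect_length(w1$elements, 60L)
  expect_true(all(GenomicRanges::width(w1$elements) == 200))
  # elements do not overlap and keep >= 100 bp gaps within a chromosome
  for (ch in c("chr1", "chr2")) {
    e <- w1$elements[as.character(GenomicRanges::seqnames(w1$elements)) == ch]
    gaps <- GenomicRanges::start(e)[-1] - GenomicRanges::end(e)[-length(e)]
    expect_true(all(gaps >= 100))
  }
  expect_error(generate_genome_and_elements(1, n_chroms = 1, chrom_len = 1e3,
                                            n_elements = 100), "too small")
})

test_that("accessibility tracks are seeded-deterministic with planted shifts", {
  w <- small_world()
  a1 <- simulate_accessibility_tracks(w$truth, w$elements, n_adult = 4,
                                      n_fetal = 2, n_neuron = 0, n_glia = 0,
                                      seed = 9)
  a2 <- simulate_accessibility_tracks(w$truth, w$elements, n_adult = 4,
                                      n_fetal = 2, n_neuron = 0, n_glia = 0,
                                      seed = 9)
  expect_identical(a1$tracks, a2$tracks)
  z <- zscore_matrix(a1$tracks, w$elements)
  adult <- a1$groups$class == "adult"
  # planted adult-specific elements sit higher in adult than fetal experiments
  sel <- w$truth$life_stage == "adult-specific"
  gap <- rowMeans(z[sel, adult, drop = FALSE]) -
    rowMeans(z[sel, !adult, drop = FALSE])
  expect_gt(mean(gap), 1.5)
  # noiseless limit recovers truth exactly per experiment
  a0 <- simulate_accessibility_tracks(w$truth, w$elements, n_adult = 1,
                                      n_fetal = 0, n_neuron = 0, n_glia = 0,
                                      noise_sd = 1e-12, seed = 3)
  z0 <- lognorm_zscores(mean_signal_over_elements(a0$tracks[[1]], w$elements))
  act <- call_active_elements(z0)
  expect_identical(unname(act),
                   unname(w$truth$life_stage %in%
                            c("adult-specific", "adult-fetal-shared")))
})

test_that("alignment fractions are valid, deterministic, with planted origins", {
  w <- small_world()
  aln <- simulate_alignment_fractions(w$truth, seed = 4)
  aln2 <- simulate_alignment_fractions(w$truth, seed = 4)
  expect_identical(aln, aln2)
  expect_true(all(aln$fractions >= 0 & aln$fractions <= 1))
  # planted G3: low in a majority of non-primates, aligned in all primates
  g3 <- which(w$truth$cons_group == "G3")
  np <- aln$species$clade == "non-primate"
  expect_true(all(rowSums(aln$fractions[g3, np, drop = FALSE] <= 0.1) >
                    sum(np) / 2))
  # origin implied by fractions is recovered by the pipeline op
  o <- evolutionary_origin(aln$fractions, aln$species)
  expect_identical(unname(o), unname(aln$origin[names(o)]))
})

test_that("importance tracks plant sites at ~site_z and write consensi", {
  w <- small_world()
  aux <- simulate_expression_and_regions(w$truth, w$elements, seed = 2)
  imp <- simulate_importance_tracks(w$truth, w$elements, aux$catalog,
                                    aux$planted_motifs,
                                    cell_types = "neuron", window_len = 402,
                                    max_windows = 30, genome = w$genome,
                                    seed = 6)
  tr <- imp$neuron$sites
  expect_gt(nrow(tr), 10)
  vals <- unlist(lapply(seq_len(nrow(tr)), function(i)
    imp$neuron$importance[tr$window[i], tr$start[i]:tr$end[i]] * tr$sign[i]))
  expect_lt(abs(mean(vals) - 3.0), 0.3)
  # the planted consensus is recoverable from the written genome
  i <- which(tr$sign > 0)[1]
  el <- imp$neuron$windows[tr$window[i]]
  gstart <- GenomicRanges::start(el) + tr$start[i] - 1L
  seq <- as.character(Biostrings::subseq(
    imp$genome[[as.character(GenomicRanges::seqnames(el))]],
    gstart, gstart + (tr$end[i] - tr$start[i])))
  expect_equal(assign_best_motif(seq, aux$catalog)$motif, tr$motif[i])
  # determinism
  imp2 <- simulate_importance_tracks(w$truth, w$elements, aux$catalog,
                                     aux$planted_motifs,
                                     cell_types = "neuron", window_len = 402,
                                     max_windows = 30, genome = small_world()$genome,
                                     seed = 6)
  expect_identical(imp$neuron$importance, imp2$neuron$importance)
})

test_that("expression/region simulation plants recoverable structure", {
  w <- small_world()
  aux <- simulate_expression_and_regions(w$truth, w$elements, seed = 5)
  expect_gte(length(aux$catalog), 20L)
  # distinct consensi
  consensi <- vapply(aux$catalog, function(p)
    paste(rownames(p)[apply(p, 2, which.max)], collapse = ""), "")
  expect_false(anyDuplicated(consensi) > 0)
  # TFs with planted neuron motifs top the neuron expression table
  te <- aux$tf_expression[aux$tf_expression$cell_type == "neuron", ]
  top4 <- te$tf[order(-te$stat)][1:4]
  expect_setequal(top4, paste0("TF_", aux$planted_motifs$neuron))
  # the rg block of three 0.9-correlated traits yields exactly one kept trait
  for (seed in 1:5) {
    kept <- select_independent_traits(aux$rg, seed = seed)
    expect_equal(sum(attr(aux$rg, "block") %in% kept), 1L)
  }
})
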