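# Synthetic inputs with planted, recoverable structure. Every generator is a
# pure function of (parameters, seed); the returned truth object suffices to
# score every recovery property downstream.
#
# Default planted proportions mirror the published atlas composition (about
# 5.6% adult-specific, 4.6% fetal-specific and 5.2% adult/fetal-shared
# elements of the cCRE universe; neuron-specific / glia-specific /
# neuron-glia-shared / low-signal at roughly 13/12/11/64% of brain-active
# elements).

LIFE_STAGE_PROBS <- c("adult-specific" = 0.056, "fetal-specific" = 0.046,
                      "adult-fetal-shared" = 0.052, "non-brain" = 0.846)
CELL_TYPE_PROBS <- c("neuron-specific" = 0.128, "glia-specific" = 0.121,
                     "neuron-glia-shared" = 0.112, "low-signal" = 0.639)
CONS_GROUP_PROBS <- c(G1 = 0.3, G2 = 0.3, G3 = 0.2, other = 0.2)

#' Generate a synthetic genome and element universe with planted truth
#'
#' Draws i.i.d. nucleotides (GC content `gc`), places non-overlapping
#' elements with at least `min_gap` bp between them, and assigns each element
#' planted labels: life stage, cell type (within brain-active elements) and
#' conservation group.
#'
#' @param seed RNG seed (byte-identical outputs per seed).
#' @param n_chroms,chrom_len,n_elements,element_len genome/element geometry.
#' @param gc genome GC content.
#' @param min_gap minimum gap between adjacent elements.
#' @return list with `genome` (`DNAStringSet`), `elements` (element set),
#'   `truth` (planted labels and generator parameters).
#' @export
generate_genome_and_elements <- function(seed, n_chroms = 3L, chrom_len = 1e6,
                                         n_elements = 5000L, element_len = 300L,
                                         gc = 0.5, min_gap = 100L) {
  set.seed(seed)
  per_chrom <- diff(round(seq(0, n_elements, length.out = n_chroms + 1L)))
  if (any(per_chrom * (element_len + min_gap) > chrom_len))
    stop("genome too small for requested elements")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- Biostrings::DNAStringSet(vapply(seq_len(n_chroms), function(i)
    paste(sample(names(probs), chrom_len, replace = TRUE, prob = probs),
          collapse = ""), ""))
  names(genome) <- paste0("chr", seq_len(n_chroms))
  parts <- lapply(seq_len(n_chroms), function(i) {
    k <- per_chrom[i]
    if (k == 0L) return(NULL)
    slack <- chrom_len - k * (element_len + min_gap)
    offs <- sort(sample.int(slack + 1L, k, replace = TRUE)) - 1L
    start0 <- (seq_len(k) - 1L) * (element_len + min_gap) + offs + min_gap %/% 2L
    data.frame(chrom = paste0("chr", i), start0 = start0,
               end = start0 + element_len)
  })
  df <- do.call(rbind, parts)
  df$id <- sprintf("E%05d", seq_len(nrow(df)))
  elements <- element_set(df$chrom, df$start0, df$end, id = df$id)
  ids <- names(elements)
  life_stage <- setNames(sample(names(LIFE_STAGE_PROBS), length(ids),
                                replace = TRUE, prob = LIFE_STAGE_PROBS), ids)
  # guarantee the canonical validation worked examples are constructible:
  # an adjacent adult/fetal pair and an adjacent adult/non-brain pair
  if (length(ids) >= 4L && per_chrom[1L] >= 4L) {
    life_stage[1:4] <- c("adult-specific", "fetal-specific",
                         "adult-specific", "non-brain")
  }
  cell_type <- setNames(rep(NA_character_, length(ids)), ids)
  brain <- which(life_stage != "non-brain")
  cell_type[brain] <- sample(names(CELL_TYPE_PROBS), length(brain),
                             replace = TRUE, prob = CELL_TYPE_PROBS)
  cons_group <- setNames(sample(names(CONS_GROUP_PROBS), length(ids),
                                replace = TRUE, prob = CONS_GROUP_PROBS), ids)
  list(genome = genome, elements = elements,
       truth = list(ids = ids, life_stage = life_stage, cell_type = cell_type,
                    cons_group = cons_group,
                    params = list(seed = seed, n_chroms = n_chroms,
                                  chrom_len = chrom_len,
                                  n_elements = n_elements,
                                  element_len = element_len, gc = gc,
                                  min_gap = min_gap)))
}

# which elements are planted-active in an experiment of a given class
planted_active <- function(truth, class) {
  ls <- truth$life_stage
  ct <- truth$cell_type
  switch(class,
    adult = ls %in% c("adult-specific", "adult-fetal-shared"),
    fetal = ls %in% c("fetal-specific", "adult-fetal-shared"),
    neuron = !is.na(ct) & ct %in% c("neuron-specific", "neuron-glia-shared"),
    glia = !is.na(ct) & ct %in% c("glia-specific", "neuron-glia-shared"),
    stop("unknown experiment class: ", class))
}

#' Simulate per-experiment accessibility signal tracks
#'
#' Per element and experiment, the log-signal is `baseline + shift * active +
#' Normal(0, noise_sd)` where `active` follows the planted labels (adult/fetal
#' experiments from the life-stage truth, neuron/glia experiments from the
#' cell-type truth); the exponentiated signal covers the element's extent and
#' the background is 0.
#'
#' @param truth,elements output of [generate_genome_and_elements()].
#' @param n_adult,n_fetal,n_neuron,n_glia experiment counts per class.
#' @param signal_shift_sd planted log-signal shift for class-active elements,
#'   in log units (i.e. units of the default noise SD 1.0; it does not scale
#'   with `noise_sd`, so the noiseless limit recovers truth exactly).
#' @param noise_sd lognormal noise SD.
#' @param baseline baseline log-signal.
#' @param seed RNG seed.
#' @return list with `tracks` (named list of `RleList`) and `groups`
#'   (`data.frame` experiment/class).
#' @export
simulate_accessibility_tracks <- function(truth, elements, n_adult = 20L,
                                          n_fetal = 6L, n_neuron = 4L,
                                          n_glia = 4L, signal_shift_sd = 2.5,
                                          noise_sd = 1.0, baseline = 2,
                                          seed = 1L) {
  set.seed(seed)
  p <- truth$params
  seqlens <- setNames(rep(p$chrom_len, p$n_chroms),
                      paste0("chr", seq_len(p$n_chroms)))
  classes <- rep(c("adult", "fetal", "neuron", "glia"),
                 c(n_adult, n_fetal, n_neuron, n_glia))
  names_exp <- sprintf("%s_%02d", classes,
                       unlist(lapply(c(n_adult, n_fetal, n_neuron, n_glia),
                                     seq_len)))
  shift <- signal_shift_sd
  chrom <- as.character(GenomicRanges::seqnames(elements))
  start0 <- GenomicRanges::start(elements) - 1L
  end <- GenomicRanges::end(elements)
  tracks <- setNames(vector("list", length(names_exp)), names_exp)
  for (i in seq_along(names_exp)) {
    act <- planted_active(truth, classes[i])
    lv <- baseline + shift * act + rnorm(length(act), 0, noise_sd)
    tracks[[i]] <- signal_track(chrom, start0, end, exp(lv),
                                seqlengths = seqlens)
  }
  list(tracks = tracks,
       groups = data.frame(experiment = names_exp, class = classes,
                           stringsAsFactors = FALSE))
}

#' Simulate an alignment-fraction matrix with planted G1/G2/G3 structure
#'
#' Species metadata places `n_primates` primates (clades great-ape,
#' old-world-monkey, new-world-monkey, lemur, nearest first) before the
#' non-primate block. Planted groups draw fractions so that generator
#' thresholds (hi = 0.9, lo = 0.1, majority = 0.5, G2 floor = 0.1 S) recover
#' them exactly: G1 aligns >= 0.92 in 75% of species; G2 has 30% high and 40%
#' low species (the low ones mostly non-primate but below the non-primate
#' majority); G3 aligns in all primates and is low in 80% of non-primates;
#' `other` stays between the thresholds everywhere.
#'
#' @param truth planted truth (uses `cons_group`).
#' @param n_species,n_primates species counts.
#' @param seed RNG seed.
#' @return list with `fractions` (elements x species matrix), `species`
#'   (`data.frame`: species, clade, distance_rank) and `origin` (per-element
#'   clade-of-origin implied by the drawn fractions at `min_align_frac` 0.5).
#' @export
simulate_alignment_fractions <- function(truth, n_species = 40L,
                                         n_primates = 10L, seed = 1L) {
  set.seed(seed)
  S <- n_species
  np <- n_primates
  nn <- S - np
  primate_clades <- rep(c("great-ape", "old-world-monkey", "new-world-monkey",
                          "lemur"), length.out = np)
  primate_clades <- primate_clades[order(match(primate_clades,
    c("great-ape", "old-world-monkey", "new-world-monkey", "lemur")))]
  species <- data.frame(
    species = sprintf("sp%02d", seq_len(S)),
    clade = c(primate_clades, rep("non-primate", nn)),
    distance_rank = seq_len(S), stringsAsFactors = FALSE)
  ids <- truth$ids
  frac <- matrix(0, length(ids), S, dimnames = list(ids, species$species))
  mid <- function(k) runif(k, 0.15, 0.85)
  hi <- function(k) runif(k, 0.92, 1.0)
  lo <- function(k) runif(k, 0.0, 0.08)
  prim_idx <- seq_len(np)
  nonprim_idx <- np + seq_len(nn)
  for (i in seq_along(ids)) {
    g <- truth$cons_group[i]
    v <- mid(S)
    if (g == "G1") {
      sel <- sample.int(S, floor(0.75 * S))
      v[sel] <- hi(length(sel))
    } else if (g == "G2") {
      n_hi <- round(0.30 * S)
      n_lo_np <- round(0.30 * nn)          # below the non-primate majority
      n_lo_p <- round(0.40 * S) - n_lo_np
      lo_sel <- c(sample(nonprim_idx, n_lo_np), sample(prim_idx, n_lo_p))
      hi_sel <- sample(setdiff(seq_len(S), lo_sel), n_hi)
      v[lo_sel] <- lo(length(lo_sel))
      v[hi_sel] <- hi(length(hi_sel))
    } else if (g == "G3") {
      v[prim_idx] <- hi(np)
      lo_sel <- sample(nonprim_idx, ceiling(0.8 * nn))
      v[lo_sel] <- lo(length(lo_sel))
    }
    frac[i, ] <- v
  }
  aligned <- frac >= 0.5
  origin <- apply(aligned, 1L, function(a) {
    w <- which(a)
    if (length(w) == 0L) "human-specific" else species$clade[max(w)]
  })
  list(fractions = frac, species = species, origin = origin)
}

#' Simulate base-resolution importance tracks with planted motif sites
#'
#' For each requested cell type, takes the windows of elements whose planted
#' cell-type label matches (`neuron` uses neuron-specific and shared elements,
#' etc.; unknown cell types get pure-background windows from low-signal
#' elements), centers a `window_len` window on each element midpoint, fills it
#' with standard-normal background and raises planted motif-length stretches
#' to mean `site_z` (a fraction `neg_frac` planted with mean `-site_z`). When
#' a genome is supplied, each planted site's motif consensus is written into
#' the genome so sequence-level motif assignment can recover it.
#'
#' @param truth,elements planted universe.
#' @param catalog named list of PWMs to plant.
#' @param planted_motifs named list: cell type -> motif ids planted in that
#'   cell type.
#' @param cell_types cell types to simulate (default names of
#'   `planted_motifs`).
#' @param site_z planted site mean importance (z units).
#' @param neg_frac fraction of sites planted with negative importance.
#' @param sites_per_window expected planted sites per window.
#' @param window_len importance window length.
#' @param max_windows cap on windows per cell type.
#' @param genome optional `DNAStringSet` to receive planted consensi.
#' @param seed RNG seed.
#' @return list per cell type: `windows` (element set of window ranges, named
#'   by element id), `importance` (windows x positions matrix), `sites`
#'   (`data.frame`: window, start, end, strand, motif, sign — window-relative
#'   1-based closed coordinates), plus `genome` when one was supplied.
#' @export
simulate_importance_tracks <- function(truth, elements, catalog,
                                       planted_motifs,
                                       cell_types = names(planted_motifs),
                                       site_z = 3.0, neg_frac = 0.2,
                                       sites_per_window = 2L,
                                       window_len = 2114L, max_windows = 150L,
                                       genome = NULL, seed = 1L) {
  set.seed(seed)
  p <- truth$params
  ct_map <- list(neuron = c("neuron-specific", "neuron-glia-shared"),
                 glia = c("glia-specific", "neuron-glia-shared"))
  out <- list()
  for (ct in cell_types) {
    labels <- ct_map[[ct]]
    sel <- if (is.null(labels)) character(0) else
      names(truth$cell_type)[!is.na(truth$cell_type) &
                               truth$cell_type %in% labels]
    planted <- length(sel) > 0L
    if (!planted)
      sel <- names(truth$cell_type)[!is.na(truth$cell_type) &
                                      truth$cell_type == "low-signal"]
    if (length(sel) > max_windows) sel <- sample(sel, max_windows)
    el <- elements[sel]
    mid <- (GenomicRanges::start(el) + GenomicRanges::end(el)) %/% 2L
    wstart <- pmax(1L, pmin(mid - window_len %/% 2L,
                            as.integer(p$chrom_len) - window_len + 1L))
    windows <- element_set(as.character(GenomicRanges::seqnames(el)),
                           wstart - 1L, wstart + window_len - 1L, id = sel)
    # element_set sorts; realign sel to the sorted order
    sel <- names(windows)
    wstart <- GenomicRanges::start(windows)
    imp <- matrix(rnorm(length(sel) * window_len), length(sel), window_len,
                  dimnames = list(sel, NULL))
    sites <- list()
    motif_ids <- planted_motifs[[ct]]
    if (planted && length(motif_ids)) {
      center <- window_len %/% 2L
      half_el <- p$element_len %/% 2L
      for (i in seq_along(sel)) {
        k <- max(1L, stats::rpois(1L, sites_per_window))
        taken <- integer(0)
        for (s in seq_len(k)) {
          m <- sample(motif_ids, 1L)
          L <- ncol(catalog[[m]])
          # keep the site inside both the element and the window
          lo <- max(-half_el + 10L, -(center - 1L))
          hi <- min(half_el - L - 10L, window_len - center - L)
          if (hi < lo) next
          for (att in 1:20) {
            st <- center + sample(seq(lo, hi), 1L)
            if (!any(abs(st - taken) < L + 8L)) break
          }
          if (any(abs(st - taken) < L + 8L)) next
          taken <- c(taken, st)
          sgn <- if (runif(1) < neg_frac) -1 else 1
          strand <- sample(c("+", "-"), 1L)
          imp[i, st:(st + L - 1L)] <- rnorm(L, sgn * site_z, 1)
          if (!is.null(genome)) {
            cons <- DNA_BASES[apply(catalog[[m]], 2L, which.max)]
            if (strand == "-")
              cons <- rev(c(A = "T", C = "G", G = "C", T = "A")[cons])
            gs <- wstart[i] + st - 1L
            ch <- as.character(GenomicRanges::seqnames(windows))[i]
            Biostrings::subseq(genome[[ch]], gs, gs + L - 1L) <-
              Biostrings::DNAString(paste(cons, collapse = ""))
          }
          sites[[length(sites) + 1L]] <-
            data.frame(window = sel[i], start = st, end = st + L - 1L,
                       strand = strand, motif = m, sign = sgn)
        }
      }
    }
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(window = character(), start = integer(), end = integer(),
                 strand = character(), motif = character(), sign = numeric())
    out[[ct]] <- list(windows = windows, importance = imp, sites = sites)
  }
  if (!is.null(genome)) out$genome <- genome
  out
}

#' Simulate a motif catalog, TF expression, validation regions and a
#' genetic-correlation matrix
#'
#' The catalog holds `n_motifs` PWMs with distinct random consensi (0.85
#' consensus-base probability). Motifs are planted per cell type and the
#' corresponding TFs (`TF_<motif>`) receive elevated differential-expression
#' statistics in that cell type. Validation regions are constructed with known
#' composition, including the two canonical worked examples: a region fully
#' containing one adult-specific and one fetal-specific element (weights
#' 0.5/0.5) and a region fully containing one adult-specific element plus
#' exactly half of a non-brain element (weights 2/3 / 1/3). The rg matrix
#' plants one block of three traits at rg 0.9, one missing-value pair, and
#' near-zero correlations elsewhere.
#'
#' @param truth,elements planted universe.
#' @param seed RNG seed.
#' @param n_motifs catalog size (>= 20).
#' @param motif_len_range motif length range.
#' @param n_regions validation-region count.
#' @param n_traits trait count for the rg matrix.
#' @return list: `catalog`, `planted_motifs` (cell type -> motif ids),
#'   `tf_expression` (`data.frame` tf/cell_type/stat), `motif_to_tf`,
#'   `regions` (element set with `tissues` metadata), `region_truth`,
#'   `rg` (matrix with planted `block` attribute).
#' @export
simulate_expression_and_regions <- function(truth, elements, seed = 1L,
                                            n_motifs = 24L,
                                            motif_len_range = c(8L, 12L),
                                            n_regions = 60L, n_traits = 12L) {
  set.seed(seed)
  # distinct-consensus PWM catalog
  consensi <- character(0)
  catalog <- list()
  while (length(catalog) < n_motifs) {
    L <- sample(motif_len_range[1]:motif_len_range[2], 1L)
    cons <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    if (cons %in% consensi) next
    consensi <- c(consensi, cons)
    pwm <- matrix(0.05, 4L, L, dimnames = list(DNA_BASES, NULL))
    pwm[cbind(match(strsplit(cons, "")[[1]], DNA_BASES), seq_len(L))] <- 0.85
    catalog[[sprintf("M%03d", length(catalog) + 1L)]] <- pwm
  }
  planted_motifs <- list(neuron = names(catalog)[1:4],
                         glia = names(catalog)[5:8])
  motif_to_tf <- setNames(paste0("TF_", names(catalog)), names(catalog))
  tf_expression <- do.call(rbind, lapply(c("neuron", "glia"), function(ct) {
    stat <- rnorm(n_motifs, 0, 0.5)
    stat[match(planted_motifs[[ct]], names(catalog))] <- rnorm(4, 4, 0.5)
    data.frame(tf = unname(motif_to_tf), cell_type = ct, stat = stat,
               stringsAsFactors = FALSE)
  }))
  # validation regions with known composition
  ls <- truth$life_stage
  chrom <- as.character(GenomicRanges::seqnames(elements))
  start <- GenomicRanges::start(elements)
  end <- GenomicRanges::end(elements)
  adj_pair <- function(lab1, lab2) {
    # adjacent element pair (i, i+1) on one chromosome with the given labels
    cand <- which(ls[-length(ls)] == lab1 & ls[-1] == lab2 &
                    chrom[-length(ls)] == chrom[-1])
    if (!length(cand)) stop("no adjacent ", lab1, "/", lab2, " pair planted")
    cand[1]
  }
  regions <- list(); rtruth <- list()
  add_region <- function(ch, s1, e1, tissues, desc) {
    regions[[length(regions) + 1L]] <<-
      data.frame(chrom = ch, start0 = s1 - 1L, end = e1, tissues = tissues)
    rtruth[[length(rtruth) + 1L]] <<- desc
  }
  i <- adj_pair("adult-specific", "fetal-specific")
  add_region(chrom[i], start[i] - 20L, end[i + 1L] + 20L, "forebrain",
             "adult+fetal fully contained")
  j <- adj_pair("adult-specific", "non-brain")
  add_region(chrom[j], start[j] - 20L,
             start[j + 1L] + GenomicRanges::width(elements)[j + 1L] %/% 2L - 1L,
             "midbrain", "adult full + half nb")
  used <- c(i, i + 1L, j, j + 1L)
  free <- setdiff(seq_along(elements), used)
  tissue_pool <- list(brain = c("forebrain", "hindbrain", "midbrain;limb"),
                      nervous = c("eye", "neural tube", "cranial nerve"),
                      nonnervous = c("limb", "heart", "somite"),
                      inactive = "")
  for (k in seq_len(n_regions - 2L)) {
    e <- sample(free, 1L)
    free <- setdiff(free, e)
    grp <- sample(names(tissue_pool), 1L,
                  prob = c(0.40, 0.15, 0.25, 0.20))
    tiss <- sample(tissue_pool[[grp]], 1L)
    if (runif(1) < 0.15) {
      # region touching nothing: place in the gap after the element
      s1 <- end[e] + 5L; e1 <- end[e] + 60L
      desc <- "no overlap"
    } else {
      s1 <- start[e] - sample(0:50, 1L); e1 <- end[e] + sample(0:50, 1L)
      desc <- "single element"
    }
    add_region(chrom[e], s1, e1, tiss, desc)
  }
  rdf <- do.call(rbind, regions)
  rdf$id <- sprintf("V%04d", seq_len(nrow(rdf)))
  reg <- element_set(rdf$chrom, rdf$start0, rdf$end, id = rdf$id)
  S4Vectors::mcols(reg)$tissues <- rdf$tissues[match(names(reg), rdf$id)]
  # genetic-correlation matrix with a planted block of 3 at rg 0.9
  rg <- matrix(rnorm(n_traits^2, 0, 0.05), n_traits, n_traits)
  rg <- (rg + t(rg)) / 2
  diag(rg) <- 1
  block <- 1:3
  rg[block, block] <- 0.9
  diag(rg) <- 1
  rg[4, 5] <- rg[5, 4] <- NA  # failed LDSC pair
  dimnames(rg) <- list(paste0("trait", seq_len(n_traits)),
                       paste0("trait", seq_len(n_traits)))
  attr(rg, "block") <- rownames(rg)[block]
  list(catalog = catalog, planted_motifs = planted_motifs,
       tf_expression = tf_expression, motif_to_tf = motif_to_tf,
       regions = reg, region_truth = unlist(rtruth), rg = rg)
}
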