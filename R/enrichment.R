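# Fractional validation-region weighting, tissue-class assignment,
# shuffle-null interval enrichment, priority assignment and independent-trait
# selection.

BRAIN_TISSUES <- c("forebrain", "midbrain", "hindbrain")
NERVOUS_NONBRAIN_TISSUES <- c("cranial nerve", "eye", "neural tube",
                              "dorsal root ganglion", "trigeminal V")
NONNERVOUS_TISSUES <- c("limb", "heart", "branchial arch", "somite", "tail",
                        "nose", "facial mesenchyme", "liver", "blood vessels",
                        "ear", "genital tubercle", "melanocytes", "pancreas",
                        "lung", "other")

#' Classify a validation region by its active tissues
#'
#' `brain` when any of forebrain/midbrain/hindbrain is active; else
#' `nervous-nonbrain` when any other nervous-system tissue (cranial nerve,
#' eye, neural tube, dorsal root ganglion, trigeminal V) is active; else
#' `non-nervous` when any activity at all; else `inactive`. Unknown tissue
#' strings count as non-nervous evidence with a warning.
#'
#' @param active_tissues character vector of tissue names (possibly empty).
#' @param brain_tissues,nervous_tissues,known_tissues controlled vocabularies.
#' @return one of `"brain"`, `"nervous-nonbrain"`, `"non-nervous"`,
#'   `"inactive"`.
#' @export
classify_validation_tissue <- function(active_tissues,
                                       brain_tissues = BRAIN_TISSUES,
                                       nervous_tissues = NERVOUS_NONBRAIN_TISSUES,
                                       known_tissues = NONNERVOUS_TISSUES) {
  active_tissues <- active_tissues[nzchar(active_tissues)]
  if (length(active_tissues) == 0L) return("inactive")
  unknown <- setdiff(active_tissues,
                     c(brain_tissues, nervous_tissues, known_tissues))
  if (length(unknown))
    warning("unknown tissue string(s) treated as non-nervous evidence: ",
            paste(unknown, collapse = ", "))
  if (any(active_tissues %in% brain_tissues)) return("brain")
  if (any(active_tissues %in% nervous_tissues)) return("nervous-nonbrain")
  "non-nervous"
}

#' Fractional weighting of validation regions across element classes
#'
#' Each validation region contributes total weight 1, split across element
#' classes: a region overlapping no element gives weight 1 to `non-cCRE`; a
#' region overlapping a single element gives weight 1 to that element's class;
#' a region overlapping several elements splits its weight proportionally to
#' each element's overlap fraction (overlapping bases / element length),
#' normalized to sum to 1 within the region.
#'
#' @param regions an element set of validation regions; `mcols()$tissues` may
#'   hold a semicolon-separated tissue string used to derive the region's
#'   tissue class (otherwise all regions fall in one `all` class).
#' @param classified an element set with `mcols()$label` giving each element's
#'   class.
#' @param none_label class name for regions overlapping nothing.
#' @return list with `weights` (tissue class x element class matrix of summed
#'   weights; rows sum to the number of regions in that tissue class) and
#'   `rates` (per element class, the share of its weight coming from each
#'   tissue class; columns sum to 1).
#' @export
vista_weighted_validation <- function(regions, classified,
                                      none_label = "non-cCRE") {
  if (any(GenomicRanges::width(regions) < 1L)) stop("zero-length region")
  labels <- S4Vectors::mcols(classified)$label
  if (is.null(labels)) stop("classified elements need a label column")
  classes <- c(sort(unique(labels)), none_label)
  tiss <- S4Vectors::mcols(regions)$tissues
  tclass <- if (is.null(tiss)) rep("all", length(regions)) else
    vapply(strsplit(ifelse(is.na(tiss), "", tiss), ";", fixed = TRUE),
           classify_validation_tissue, "")
  tlevels <- unique(c("brain", "nervous-nonbrain", "non-nervous", "inactive", tclass))
  tlevels <- tlevels[tlevels %in% tclass]
  w <- matrix(0, length(tlevels), length(classes),
              dimnames = list(tlevels, classes))
  ov <- overlap_fractions(regions, classified)
  for (i in seq_along(regions)) {
    rid <- names(regions)[i]
    hits <- ov[ov$query_id == rid, , drop = FALSE]
    if (nrow(hits) == 0L) {
      w[tclass[i], none_label] <- w[tclass[i], none_label] + 1
    } else {
      frac <- hits$fraction / sum(hits$fraction)
      cls <- labels[match(hits$target_id, names(classified))]
      for (k in seq_along(frac))
        w[tclass[i], cls[k]] <- w[tclass[i], cls[k]] + frac[k]
    }
  }
  rates <- sweep(w, 2L, pmax(colSums(w), .Machine$double.eps), `/`)
  list(weights = w, rates = rates)
}

#' Shuffle-null enrichment of query elements in target regions
#'
#' The observed statistic is the number of query elements intersecting (>= 1
#' bp) at least one target. Each shuffle places every query interval uniformly
#' at random (length-preserving) on its own chromosome (or anywhere in the
#' genome with `genome_wide = TRUE`), and the per-shuffle enrichment is
#' observed / simulated intersections. Shuffles with zero simulated
#' intersections are excluded from the mean with their count reported.
#'
#' @param query,targets element sets.
#' @param genome_sizes named vector of chromosome lengths.
#' @param n_shuffles number of random placements.
#' @param seed RNG seed.
#' @param genome_wide place intervals on any chromosome (length-weighted)
#'   instead of within their own chromosome.
#' @param exclude optional element set of regions shuffled intervals must not
#'   touch (rejection sampling).
#' @return list with `observed`, `null_mean`, `null_sd` (mean/SD of simulated
#'   intersection counts), `enrichment` (mean of per-shuffle ratios, the
#'   headline statistic), `enrichment_sd` (SD of the ratios),
#'   `enrichment_ratio_of_means` (= observed / null_mean), and `n_undefined`.
#' @export
shuffle_enrichment <- function(query, targets, genome_sizes, n_shuffles = 100L,
                               seed = 1L, genome_wide = FALSE, exclude = NULL) {
  if (length(query) == 0L) stop("empty query set")
  if (length(targets) == 0L) stop("empty target set")
  set.seed(seed)
  observed <- sum(GenomicRanges::countOverlaps(query, targets) > 0L)
  widths <- GenomicRanges::width(query)
  chroms <- as.character(GenomicRanges::seqnames(query))
  if (!all(chroms %in% names(genome_sizes)))
    stop("query chromosomes missing from genome_sizes")
  sims <- integer(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    if (genome_wide) {
      ch <- names(genome_sizes)[sample.int(length(genome_sizes), length(query),
                                           replace = TRUE, prob = genome_sizes)]
    } else ch <- chroms
    maxstart <- genome_sizes[ch] - widths + 1
    if (any(maxstart < 1)) stop("interval longer than its chromosome")
    st <- floor(runif(length(query)) * maxstart) + 1
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = widths))
    if (!is.null(exclude)) {
      bad <- GenomicRanges::countOverlaps(gr, exclude) > 0L
      tries <- 0L
      while (any(bad) && tries < 100L) {
        st2 <- floor(runif(sum(bad)) * maxstart[bad]) + 1
        gr[bad] <- GenomicRanges::GRanges(ch[bad],
                                          IRanges::IRanges(st2, width = widths[bad]))
        bad <- GenomicRanges::countOverlaps(gr, exclude) > 0L
        tries <- tries + 1L
      }
    }
    sims[s] <- sum(GenomicRanges::countOverlaps(gr, targets) > 0L)
  }
  ok <- sims > 0L
  if (!any(ok)) stop("all shuffles produced zero simulated intersections")
  ratios <- observed / sims[ok]
  list(observed = observed,
       null_mean = mean(sims), null_sd = stats::sd(sims),
       enrichment = mean(ratios), enrichment_sd = stats::sd(ratios),
       enrichment_ratio_of_means = observed / mean(sims),
       n_undefined = sum(!ok))
}

#' Windows around transcription start sites
#'
#' Builds `[max(0, pos - window), pos + window)` intervals (clipped to
#' chromosome ends when sizes are supplied); nearby TSS yield overlapping,
#' unmerged intervals.
#'
#' @param tss `data.frame` with columns `chrom`, `pos` (0-based TSS position)
#'   and optionally `id`.
#' @param window half-window in bp (default 100 kb).
#' @param genome_sizes optional named chromosome lengths for right clipping.
#' @return an element set.
#' @export
window_targets_from_tss <- function(tss, window = 100000L, genome_sizes = NULL) {
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0")
  start0 <- pmax(0, tss$pos - window)
  end <- tss$pos + window
  if (!is.null(genome_sizes))
    end <- pmin(end, genome_sizes[as.character(tss$chrom)])
  id <- if (!is.null(tss$id)) tss$id else
    sprintf("tss_%s_%d", tss$chrom, as.integer(tss$pos))
  element_set(tss$chrom, start0, end, id = id)
}

#' Priority assignment of catalog regions to ordered class sets
#'
#' Each region receives the label of the first class set (in the given
#' priority order) it intersects by >= 1 bp; regions intersecting none get
#' `none_label`.
#'
#' @param catalog_regions an element set.
#' @param class_sets named, priority-ordered list of element sets.
#' @param none_label label for unmatched regions.
#' @return named character vector, one label per catalog region.
#' @export
priority_assign <- function(catalog_regions, class_sets,
                            none_label = "non-cCRE") {
  out <- rep(none_label, length(catalog_regions))
  names(out) <- names(catalog_regions)
  unassigned <- rep(TRUE, length(catalog_regions))
  for (lbl in names(class_sets)) {
    hit <- GenomicRanges::countOverlaps(catalog_regions, class_sets[[lbl]]) > 0L
    out[unassigned & hit] <- lbl
    unassigned <- unassigned & !hit
  }
  out
}

#' Greedy selection of genetically independent traits
#'
#' Visits traits in a seeded-shuffle order and keeps a trait iff its squared
#' genetic correlation with every previously kept trait is at most
#' `threshold_sq`. Missing correlations are treated as 0.
#'
#' @param rg square symmetric genetic-correlation matrix (diagonal 1; `NA`
#'   allowed off-diagonal).
#' @param threshold_sq squared-correlation threshold (default 0.1).
#' @param seed RNG seed for the visiting order.
#' @return character vector of kept trait names, in visiting order.
#' @export
select_independent_traits <- function(rg, threshold_sq = 0.1, seed = 1L) {
  if (!is.matrix(rg) || nrow(rg) != ncol(rg)) stop("rg must be a square matrix")
  traits <- rownames(rg)
  if (is.null(traits)) traits <- as.character(seq_len(nrow(rg)))
  rg[is.na(rg)] <- 0
  set.seed(seed)
  order_idx <- sample.int(nrow(rg))
  kept <- integer()
  for (i in order_idx) {
    if (all(rg[i, kept]^2 <= threshold_sq)) kept <- c(kept, i)
  }
  traits[kept]
}
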