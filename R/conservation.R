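# Conservation profiles, alignment-fraction triangle coordinates, G1/G2/G3
# partitioning, 16-slice triangle partitioning, evolutionary origin, and
# GC/CpG-matched controls.

# centered rolling mean; edge positions use the truncated window
roll_mean_centered <- function(x, w) {
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Aggregate a per-base signal profile around genomic centers
#'
#' Averages the track position-wise across windows of `2*flank + 1` bases
#' centered on each supplied position, then applies a centered rolling mean of
#' width `smooth_window` (odd; edges use the truncated window).
#'
#' @param track a numeric `RleList`.
#' @param centers `data.frame` with columns `chrom` and `pos` (1-based center
#'   positions).
#' @param flank half-window in bp.
#' @param smooth_window odd smoothing width in bp (1 = no smoothing).
#' @return numeric vector of length `2*flank + 1`.
#' @export
aggregate_signal_profile <- function(track, centers, flank, smooth_window = 1L) {
  if (is.null(centers) || nrow(centers) == 0L) stop("empty center list")
  if (smooth_window %% 2L != 1L) stop("smooth_window must be odd")
  if (flank < smooth_window) stop("flank must be >= smooth_window")
  width <- 2L * flank + 1L
  acc <- numeric(width)
  n_used <- 0L
  for (i in seq_len(nrow(centers))) {
    ch <- as.character(centers$chrom[i])
    if (!ch %in% names(track)) next
    r <- track[[ch]]
    s <- centers$pos[i] - flank
    e <- centers$pos[i] + flank
    if (s < 1L || e > length(r)) next  # window must fit inside the track
    acc <- acc + as.numeric(r[s:e])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable centers (all windows out of track bounds)")
  roll_mean_centered(acc / n_used, smooth_window)
}

#' Triangle coordinates (N1, N2) from per-species alignment fractions
#'
#' `N1` counts species aligning at least `hi` (default >= 90%) of the
#' element's sequence, `N2` counts species aligning at most `lo` (default
#' <= 10%). Both boundaries are inclusive.
#'
#' @param fractions numeric vector (one element) or matrix (elements x
#'   species) of alignment fractions in `[0, 1]`.
#' @param hi,lo inclusive thresholds.
#' @return for a vector, a named vector `c(N1 =, N2 =)`; for a matrix, a
#'   `data.frame` with columns `N1`, `N2` (rownames = element ids).
#' @export
triangle_coordinates <- function(fractions, hi = 0.90, lo = 0.10) {
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  if (is.matrix(fractions)) {
    out <- data.frame(N1 = rowSums(fractions >= hi),
                      N2 = rowSums(fractions <= lo))
    rownames(out) <- rownames(fractions)
    return(out)
  }
  c(N1 = sum(fractions >= hi), N2 = sum(fractions <= lo))
}

#' Assign conservation groups G1/G2/G3/other
#'
#' G1: aligned (>= hi) in a majority of species. G3: poorly aligned (<= lo) in
#' a majority of *non-primate* species (the primate-/human-specific
#' carve-out). G2: at least `g2_min_frac * S` species on each side of the
#' triangle (actively evolving). Everything else is `other`. G3 is evaluated
#' before G2 because an element conserved across primates but absent from most
#' other mammals would otherwise always satisfy the G2 counts; the
#' primate-specific reading takes precedence.
#'
#' @param n1,n2 integer vectors of triangle coordinates.
#' @param S total species count.
#' @param n2_nonprimate per-element count of non-primate species aligning
#'   `<= lo`.
#' @param n_nonprimate number of non-primate species.
#' @param params list with `g1_majority_frac` (default 0.5), `g2_min_frac`
#'   (default 0.1, i.e. `g2_min_each = 0.1 * S`), and
#'   `g3_nonprimate_majority_frac` (default 0.5).
#' @return character vector in `{"G1","G2","G3","other"}`.
#' @export
assign_conservation_groups <- function(n1, n2, S, n2_nonprimate, n_nonprimate,
                                       params = list()) {
  p <- utils::modifyList(list(g1_majority_frac = 0.5, g2_min_frac = 0.1,
                              g3_nonprimate_majority_frac = 0.5), params)
  g2_min <- p$g2_min_frac * S
  out <- rep("other", length(n1))
  is_g3 <- n2_nonprimate > p$g3_nonprimate_majority_frac * n_nonprimate
  is_g2 <- n1 >= g2_min & n2 >= g2_min
  out[is_g2] <- "G2"
  out[is_g3] <- "G3"
  out[n1 > p$g1_majority_frac * S] <- "G1"
  out
}

#' Conservation groups from an alignment-fraction matrix
#'
#' @param fractions elements x species matrix of alignment fractions.
#' @param species `data.frame` with columns `species` (matching matrix
#'   columns) and `clade`; clade `"non-primate"` marks non-primate species.
#' @param hi,lo triangle thresholds, see [triangle_coordinates()].
#' @param params see [assign_conservation_groups()].
#' @return named character vector of groups, one per element.
#' @export
conservation_groups <- function(fractions, species, hi = 0.90, lo = 0.10,
                                params = list()) {
  stopifnot(is.matrix(fractions), ncol(fractions) == nrow(species))
  coords <- triangle_coordinates(fractions, hi, lo)
  nonprim <- species$clade == "non-primate"
  n2_np <- rowSums(fractions[, nonprim, drop = FALSE] <= lo)
  g <- assign_conservation_groups(coords$N1, coords$N2, ncol(fractions),
                                  n2_np, sum(nonprim), params)
  names(g) <- rownames(fractions)
  g
}

#' Partition the conservation triangle into density-based slices
#'
#' Column boundaries are the empirical quartiles of N2 and row boundaries the
#' empirical quartiles of N1, computed over all supplied elements; labels run
#' row-major starting at (low N1, low N2), and boundaries are top/right
#' inclusive (an element above a boundary falls in the higher bin). Tied
#' quantiles that collapse a boundary produce fewer effective slices, with a
#' warning.
#'
#' @param n1,n2 integer triangle coordinates for all elements.
#' @param rows,cols grid dimensions (default 4 x 4 = 16 slices).
#' @return integer vector of slice labels in `1..rows*cols`.
#' @export
triangle_slices <- function(n1, n2, rows = 4L, cols = 4L) {
  if (length(n1) < rows * cols) stop("need >= rows*cols elements")
  probs_r <- seq_len(rows - 1L) / rows
  probs_c <- seq_len(cols - 1L) / cols
  rb <- stats::quantile(n1, probs_r, names = FALSE, type = 7)
  cb <- stats::quantile(n2, probs_c, names = FALSE, type = 7)
  if (anyDuplicated(rb) || anyDuplicated(cb))
    warning("degenerate quantile boundaries; fewer effective slices")
  row_idx <- rowSums(outer(n1, rb, `>`)) + 1L
  col_idx <- rowSums(outer(n2, cb, `>`)) + 1L
  (row_idx - 1L) * cols + col_idx
}

#' Estimate evolutionary origin from alignment fractions
#'
#' The origin of an element is the clade of the most distant species (largest
#' `distance_rank`) in which the element aligns at least `min_align_frac` of
#' its sequence; elements aligning in no non-human species are
#' `human-specific`.
#'
#' @param fractions elements x species matrix.
#' @param species `data.frame` with columns `species`, `clade`,
#'   `distance_rank` (1 = nearest to human).
#' @param min_align_frac minimum fraction counting as "aligns".
#' @return named character vector of clade labels.
#' @export
evolutionary_origin <- function(fractions, species, min_align_frac = 0.5) {
  stopifnot(is.matrix(fractions), ncol(fractions) == nrow(species))
  ord <- order(species$distance_rank)
  out <- apply(fractions[, ord, drop = FALSE] >= min_align_frac, 1L, function(a) {
    w <- which(a)
    if (length(w) == 0L) "human-specific" else species$clade[ord][max(w)]
  })
  names(out) <- rownames(fractions)
  out
}

# C+G mononucleotide and CpG dinucleotide counts of a DNAString
gc_cpg_counts <- function(seq) {
  lf <- Biostrings::letterFrequency(seq, c("C", "G"))
  c(gc = sum(lf), cpg = Biostrings::countPattern("CG", seq))
}

#' Sample GC/CpG-matched control regions
#'
#' For each element, proposes uniform random same-length windows on a random
#' chromosome of the same genome until one matches the element's C+G count and
#' CpG dinucleotide count exactly (windows containing N are rejected).
#' Elements for which no match is found within `max_attempts` proposals are
#' skipped with a warning.
#'
#' @param elements an element set.
#' @param genome a named `DNAStringSet`.
#' @param seed integer RNG seed (controls are reproducible given the seed).
#' @param max_attempts proposals per element before giving up.
#' @return an element set of controls; `mcols()$source` holds the matched
#'   element id.
#' @export
matched_controls <- function(elements, genome, seed, max_attempts = 1000L) {
  set.seed(seed)
  chrom_names <- names(genome)
  chrom_len <- Biostrings::width(genome)
  out <- vector("list", length(elements))
  failed <- character()
  for (i in seq_along(elements)) {
    ch <- as.character(GenomicRanges::seqnames(elements))[i]
    w <- GenomicRanges::width(elements)[i]
    target <- gc_cpg_counts(Biostrings::subseq(
      genome[[ch]], GenomicRanges::start(elements)[i], GenomicRanges::end(elements)[i]))
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      j <- sample.int(length(genome), 1L, prob = pmax(chrom_len - w + 1, 0))
      if (chrom_len[j] < w) next
      s <- sample.int(chrom_len[j] - w + 1L, 1L)
      cand <- Biostrings::subseq(genome[[j]], s, s + w - 1L)
      if (Biostrings::countPattern("N", cand) > 0L) next
      if (identical(gc_cpg_counts(cand), target)) {
        out[[i]] <- data.frame(chrom = chrom_names[j], start0 = s - 1L,
                               end = s + w - 1L,
                               id = paste0("ctrl_", names(elements)[i]),
                               source = names(elements)[i])
        ok <- TRUE
        break
      }
    }
    if (!ok) failed <- c(failed, names(elements)[i])
  }
  if (length(failed))
    warning(sprintf("no GC/CpG-matched control found for %d element(s): %s",
                    length(failed), paste(head(failed, 5), collapse = ", ")))
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df)) stop("no controls could be placed")
  ctrl <- element_set(df$chrom, df$start0, df$end, id = df$id)
  S4Vectors::mcols(ctrl)$source <- df$source[match(names(ctrl), df$id)]
  ctrl
}
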