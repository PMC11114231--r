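# Phase-1 per-experiment activity calling and phase-2 consensus definition of
# brain-active elements (b-cCREs), plus life-stage classification.

#' Log-transform and z-normalize accessibility signal
#'
#' Computes `z = (ln(x + pseudocount) - mean) / sd` where the mean and the
#' *population* standard deviation are taken over the full input vector (the
#' normalization universe). The natural log is used; the base only rescales
#' log-values linearly and leaves z-scores unchanged.
#'
#' @param signal non-negative signal values (length >= 2).
#' @param pseudocount positive offset keeping the log finite at 0. Default
#'   0.001: small enough not to distort high signals, large enough to bound
#'   `ln` at zero signal.
#' @return numeric vector of z-scores (mean 0, population SD 1).
#' @export
lognorm_zscores <- function(signal, pseudocount = 0.001) {
  if (length(signal) < 2L) stop("need >= 2 values to normalize")
  if (!is.numeric(pseudocount) || pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and >= 0")
  lv <- log(signal + pseudocount)
  mu <- mean(lv)
  sd_pop <- sqrt(mean((lv - mu)^2))
  if (sd_pop == 0) stop("degenerate input: zero standard deviation")
  (lv - mu) / sd_pop
}

#' Call active elements from z-scores
#'
#' An element is active in an experiment iff its z-score strictly exceeds the
#' threshold. The default 1.64 is the 95th percentile of the standard normal
#' (one-tailed).
#'
#' @param z numeric z-scores (finite).
#' @param threshold activity threshold (strict `>`).
#' @return logical vector.
#' @export
call_active_elements <- function(z, threshold = 1.64) {
  if (any(!is.finite(z))) stop("z-scores must be finite")
  z > threshold
}

#' Consensus calling of brain-active elements
#'
#' An element enters the consensus set when it is active in at least
#' `min_support` experiments. When `rescue_threshold` is set (the fetal rescue
#' rule), elements active in at least one but fewer than `min_support`
#' experiments are rescued if their maximum z-score across experiments exceeds
#' the rescue threshold (99th percentile, 2.32, by default). Elements active
#' in zero experiments are never rescued.
#'
#' @param activity logical matrix, elements x experiments.
#' @param z numeric matrix of the same shape.
#' @param min_support minimum number of supporting experiments (>= 1).
#' @param rescue_threshold rescue z threshold, or `NULL` to disable.
#' @return character vector of consensus element ids (rownames of `activity`).
#' @export
consensus_bccres <- function(activity, z, min_support = 5, rescue_threshold = 2.32) {
  if (!is.matrix(activity) || !is.matrix(z) || !all(dim(activity) == dim(z)))
    stop("activity and z must be matrices of identical shape")
  if (min_support < 1) stop("min_support must be >= 1")
  support <- rowSums(activity)
  keep <- support >= min_support
  if (!is.null(rescue_threshold)) {
    zmax <- apply(z, 1L, max)
    keep <- keep | (support >= 1L & support < min_support & zmax > rescue_threshold)
  }
  ids <- rownames(activity)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(activity)))
  ids[keep]
}

#' Build an element x experiment z-score matrix from signal tracks
#'
#' Runs phase 1 of the consensus approach: for each experiment's track,
#' averages the signal over each element and z-normalizes the log-signal
#' across the normalization universe (all supplied elements).
#'
#' @param tracks named list of signal tracks (`RleList`), one per experiment.
#' @param elements the element universe over which z-scores are normalized.
#' @param pseudocount see [lognorm_zscores()].
#' @return numeric matrix, elements x experiments.
#' @export
zscore_matrix <- function(tracks, elements, pseudocount = 0.001) {
  if (length(tracks) == 0L) stop("need >= 1 track")
  z <- vapply(tracks, function(tr)
    lognorm_zscores(mean_signal_over_elements(tr, elements), pseudocount),
    numeric(length(elements)))
  rownames(z) <- names(elements)
  z
}

#' Classify elements by life stage
#'
#' Partitions the universe into `adult-specific` (adult list only),
#' `fetal-specific` (fetal list only), `adult-fetal-shared` (both), and
#' `non-brain` (neither).
#'
#' @param adult_set,fetal_set character vectors of element ids, subsets of
#'   `universe`.
#' @param universe character vector of all element ids.
#' @return named character vector, one label per universe id.
#' @export
classify_life_stage <- function(adult_set, fetal_set, universe) {
  extra <- setdiff(c(adult_set, fetal_set), universe)
  if (length(extra))
    stop("ids outside universe: ", paste(head(extra, 3), collapse = ", "))
  a <- universe %in% adult_set
  f <- universe %in% fetal_set
  lab <- ifelse(a & f, "adult-fetal-shared",
         ifelse(a, "adult-specific",
         ifelse(f, "fetal-specific", "non-brain")))
  names(lab) <- universe
  lab
}
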