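# Neuron/glia aggregate classification, single-cell coverage metrics and
# pairwise overlap-coefficient matrices.

#' Classify elements by neuron/glia activity pattern
#'
#' Labels each element by the 2x2 activity pattern of its z-scores in the
#' neuronal (NeuN+) and glial (NeuN-) aggregate experiments: active in neurons
#' only -> `neuron-specific`, glia only -> `glia-specific`, both ->
#' `neuron-glia-shared`, neither -> `low-signal`.
#'
#' @param z_neuron,z_glia aligned numeric z-score vectors.
#' @param threshold activity threshold (strict `>`).
#' @param ids optional element ids (defaults to names of `z_neuron`).
#' @return named character vector of labels.
#' @export
classify_neuron_glia <- function(z_neuron, z_glia, threshold = 1.64, ids = NULL) {
  if (length(z_neuron) != length(z_glia))
    stop("z_neuron and z_glia must have equal length")
  n <- call_active_elements(z_neuron, threshold)
  g <- call_active_elements(z_glia, threshold)
  lab <- ifelse(n & g, "neuron-glia-shared",
         ifelse(n, "neuron-specific",
         ifelse(g, "glia-specific", "low-signal")))
  names(lab) <- if (!is.null(ids)) ids else names(z_neuron)
  lab
}

#' Coverage of a reference set by a cell type's top active elements
#'
#' Calls active elements at the threshold; datasets with fewer than
#' `min_active` active elements are dropped. Otherwise the `top_k`
#' highest-scoring active elements (stable sort by decreasing z, then element
#' id, so ties are deterministic) are taken and the fraction belonging to the
#' reference set is the coverage.
#'
#' @param z named numeric z-score vector for one cell type.
#' @param reference_set character vector of reference element ids.
#' @param top_k number of top elements to evaluate.
#' @param min_active minimum active-element count below which the dataset is
#'   dropped.
#' @param threshold activity threshold.
#' @return a list with `dropped` (logical), and when not dropped `active_ids`,
#'   `top_ids` and `coverage`.
#' @export
celltype_activity_coverage <- function(z, reference_set, top_k = 50000,
                                       min_active = 10000, threshold = 1.64) {
  if (is.null(names(z))) names(z) <- as.character(seq_along(z))
  act <- call_active_elements(z, threshold)
  active_ids <- names(z)[act]
  if (length(active_ids) < min_active)
    return(list(dropped = TRUE, n_active = length(active_ids)))
  za <- z[active_ids]
  ord <- order(-za, names(za), method = "radix")
  top_ids <- names(za)[ord][seq_len(min(top_k, length(za)))]
  list(dropped = FALSE, n_active = length(active_ids), active_ids = active_ids,
       top_ids = top_ids,
       coverage = mean(top_ids %in% reference_set))
}

#' Pairwise overlap-coefficient matrix
#'
#' `entry(A, B) = |A intersect B| / min(|A|, |B|)`. Rows/columns for empty
#' sets are 0 with a warning; the diagonal is 1 for non-empty sets.
#'
#' @param sets named list of element-id character vectors (>= 2 sets).
#' @return symmetric numeric matrix with values in `[0, 1]`.
#' @export
overlap_coefficient_matrix <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sizes <- lengths(sets)
  if (any(sizes == 0L)) warning("empty set(s); their coefficients are 0")
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (sizes[i] > 0L && sizes[j] > 0L) {
        m[i, j] <- m[j, i] <-
          length(intersect(sets[[i]], sets[[j]])) / min(sizes[i], sizes[j])
      }
    }
  }
  m
}
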