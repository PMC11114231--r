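# Motif-enrichment machine learning: PWM max-score features, dinucleotide
# shuffled negatives, the 10-model random-forest importance ensemble and
# integration with enrichment scores and differential expression.

#' Maximum PWM scores of sequences (motif feature matrix)
#'
#' Scores each sequence against each motif with a log-odds scan: at every
#' position and on both strands, `sum(log2(max(p, floor) / background))` over
#' the motif columns, and the feature is the maximum over positions/strands
#' (`log_odds = FALSE` instead sums raw probabilities). Sequences shorter than
#' a motif get that motif's dataset minimum with a warning.
#'
#' @param sequences character vector of DNA strings.
#' @param catalog named list of PWMs.
#' @param background background base probability (uniform 0.25).
#' @param floor probability floor applied before the log.
#' @param log_odds use log2 odds (default) or raw probability sums.
#' @return numeric matrix, sequences x motifs.
#' @export
pwm_max_scores <- function(sequences, catalog, background = 0.25,
                           floor = 0.001, log_odds = TRUE) {
  stopifnot(length(sequences) > 0L, length(catalog) > 0L)
  feat <- matrix(NA_real_, length(sequences), length(catalog),
                 dimnames = list(names(sequences), names(catalog)))
  idx_fwd <- lapply(sequences, seq_to_idx)
  idx_rev <- lapply(sequences, function(s) seq_to_idx(revcomp(s)))
  for (m in seq_along(catalog)) {
    pwm <- validate_pwm(catalog[[m]])
    sc <- if (log_odds) log2(pmax(pwm, floor) / background) else pwm
    sc <- rbind(sc, N = if (log_odds) rep(0, ncol(sc)) else rep(background, ncol(sc)))
    L <- ncol(sc)
    for (i in seq_along(sequences)) {
      best <- -Inf
      for (idx in list(idx_fwd[[i]], idx_rev[[i]])) {
        n <- length(idx)
        if (n < L) next
        idx[is.na(idx)] <- 5L
        # positions x motif columns lookup, rowSums = per-offset scores
        pos_mat <- outer(0:(n - L), seq_len(L), `+`)
        scores <- rowSums(matrix(sc[cbind(as.vector(idx[pos_mat]),
                                          rep(seq_len(L), each = n - L + 1L))],
                                 nrow = n - L + 1L))
        best <- max(best, max(scores))
      }
      feat[i, m] <- best
    }
  }
  if (any(!is.finite(feat))) {
    warning("sequence(s) shorter than motif; assigned the dataset minimum")
    feat[!is.finite(feat)] <- min(feat[is.finite(feat)])
  }
  feat
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the output has exactly the same
#' dinucleotide count multiset as the input and the same first and last base.
#' `N` is treated as a fifth symbol whose counts are preserved too.
#'
#' @param seq DNA string (length >= 2).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return shuffled DNA string.
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2")
  set.seed(seed)
  verts <- unique(chars)
  last <- chars[n]
  # multigraph: edge i is chars[i] -> chars[i+1]
  from <- chars[-n]; to <- chars[-1]
  edges_by_vertex <- split(seq_len(n - 1L), from)
  # Altschul-Erickson: for each vertex except the terminal one, pick a random
  # outgoing edge whose targets form a tree rooted at the terminal vertex;
  # those edges are placed last, all other edges are randomly permuted.
  repeat {
    last_edge <- list()
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cand <- edges_by_vertex[[v]]
      last_edge[[v]] <- cand[sample.int(length(cand), 1L)]
    }
    # check: following chosen last-edges from every vertex reaches `last`
    for (v in setdiff(verts, last)) {
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        e <- last_edge[[cur]]
        if (is.null(e)) break
        cur <- to[e]
        steps <- steps + 1L
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- edges_by_vertex[[v]]
    if (is.null(e)) return(integer())
    le <- if (v %in% names(last_edge)) last_edge[[v]] else integer()
    rest <- setdiff(e, le)
    if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
    c(rest, le)
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    e <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    cur <- to[e]
    out[i] <- cur
  }
  paste(out, collapse = "")
}

#' Random-forest motif importance ensemble
#'
#' Trains `n_models` forests on positive vs negative feature matrices with
#' distinct derived seeds; each model's impurity importances are normalized to
#' sum to 1 and the final importance is their mean across models (which again
#' sums to 1).
#'
#' @param pos_features,neg_features numeric matrices (sequences x motifs) with
#'   identical columns.
#' @param n_models ensemble size (default 10).
#' @param seed base RNG seed.
#' @param n_trees,max_depth,min_node forest hyperparameters (see [rf_fit()]).
#' @return named numeric vector of per-motif importances summing to 1.
#' @export
rf_motif_importance <- function(pos_features, neg_features, n_models = 10L,
                                seed = 1L, n_trees = 100L, max_depth = 10L,
                                min_node = 2L) {
  if (!identical(colnames(pos_features), colnames(neg_features)))
    stop("positive and negative features must share motif columns")
  if (nrow(pos_features) < 1L || nrow(neg_features) < 1L)
    stop("both classes must be non-empty")
  X <- rbind(pos_features, neg_features)
  y <- c(rep(1L, nrow(pos_features)), rep(0L, nrow(neg_features)))
  p <- ncol(X)
  acc <- numeric(p)
  for (m in seq_len(n_models)) {
    set.seed(seed + m - 1L)
    fit <- rf_fit(X, y, n_trees = n_trees, max_depth = max_depth,
                  min_node = min_node)
    imp <- fit$importance
    tot <- sum(imp)
    acc <- acc + if (tot > 0) imp / tot else rep(1 / p, p)
  }
  out <- acc / n_models
  names(out) <- colnames(X)
  out
}

#' Combine motif importance with enrichment scores and TF expression
#'
#' Min-max scales the importance and enrichment vectors to `[0, 1]` over
#' their shared motifs, sums them (`combined` in `[0, 2]`) and joins the
#' result to per-TF differential-expression statistics through a motif-to-TF
#' map. Motifs missing from either score map are excluded with a warning;
#' constant score vectors scale to all-0 with a warning.
#'
#' @param importance named numeric vector (motif -> importance).
#' @param enrichment_scores named numeric vector (motif -> enrichment
#'   statistic, e.g. -log10 p).
#' @param tf_expression named numeric vector (TF -> differential-expression
#'   statistic).
#' @param motif_to_tf named character vector (motif -> TF).
#' @return `data.frame` with columns `motif`, `tf`, `scaled_importance`,
#'   `scaled_enrichment`, `combined`, `diff_expression`, sorted by decreasing
#'   combined score.
#' @export
combine_importance_expression <- function(importance, enrichment_scores,
                                          tf_expression, motif_to_tf) {
  shared <- intersect(names(importance), names(enrichment_scores))
  dropped <- setdiff(union(names(importance), names(enrichment_scores)), shared)
  if (length(dropped))
    warning("motif(s) missing from one score map excluded: ",
            paste(head(dropped, 5), collapse = ", "))
  if (length(shared) == 0L) stop("no shared motifs between score maps")
  minmax <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("constant score vector scaled to all-0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  si <- minmax(importance[shared])
  se <- minmax(enrichment_scores[shared])
  tf <- unname(motif_to_tf[shared])
  out <- data.frame(motif = shared, tf = tf,
                    scaled_importance = unname(si), scaled_enrichment = unname(se),
                    combined = unname(si + se),
                    diff_expression = unname(tf_expression[tf]),
                    stringsAsFactors = FALSE)
  out[order(-out$combined), , drop = FALSE]
}
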