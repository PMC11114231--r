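# Candidate TF binding site (cTFBS) calling: discretize base-resolution
# importance scores, fit a 3-state discrete HMM by Baum-Welch, decode with
# Viterbi and post-process the decoded segments.
#
# Symbols are {-1, 0, +1}, stored internally as emission indices {1, 2, 3}.
# States are relabeled after fitting so that state 1 prefers -1, state 2
# prefers 0 and state 3 prefers +1.

#' Dataset-wide importance z-scores
#'
#' Importance scores are z-normalized over *all* window positions of a dataset
#' (not per window), using the population SD.
#'
#' @param x numeric vector or matrix (windows x positions) of raw importance
#'   scores.
#' @return object of the same shape holding z-scores.
#' @export
importance_zscores <- function(x) {
  v <- as.numeric(x)
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) stop("degenerate input: zero standard deviation")
  z <- (x - mu) / s
  z
}

#' Discretize importance z-scores into {-1, 0, +1}
#'
#' Positions with z strictly above `z_hi` become +1, strictly below `-z_hi`
#' become -1, everything else 0. The default 1.96 is two standard deviations
#' (97.5th percentile of the standard normal).
#'
#' @param z z-scores (vector or matrix), see [importance_zscores()].
#' @param z_hi symmetric threshold (strict inequalities).
#' @return integer object of the same shape with values in `{-1, 0, 1}`.
#' @export
discretize_importance <- function(z, z_hi = 1.96) {
  out <- sign(z) * ((z > z_hi) | (z < -z_hi))
  storage.mode(out) <- "integer"
  out
}

symbols_to_idx <- function(sym) {
  if (any(!sym %in% c(-1L, 0L, 1L))) stop("symbols must be in {-1, 0, 1}")
  sym + 2L
}

hmm_validate <- function(model) {
  stopifnot(length(model$init) == 3L,
            all(dim(model$trans) == c(3L, 3L)),
            all(dim(model$emis) == c(3L, 3L)))
  if (abs(sum(model$init) - 1) > 1e-9 ||
      any(abs(rowSums(model$trans) - 1) > 1e-9) ||
      any(abs(rowSums(model$emis) - 1) > 1e-9))
    stop("HMM probabilities must satisfy stochastic constraints")
  invisible(model)
}

# greedy relabeling: choose the state permutation maximizing
# P(state a emits -1) + P(state b emits 0) + P(state c emits +1)
hmm_relabel <- function(model) {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  score <- vapply(perms, function(p)
    model$emis[p[1], 1] + model$emis[p[2], 2] + model$emis[p[3], 3], 0)
  p <- perms[[which.max(score)]]
  model$init <- model$init[p]
  model$trans <- model$trans[p, p, drop = FALSE]
  model$emis <- model$emis[p, , drop = FALSE]
  dimnames(model$trans) <- list(c("neg","zero","pos"), c("neg","zero","pos"))
  dimnames(model$emis) <- list(c("neg","zero","pos"), c("-1","0","+1"))
  names(model$init) <- c("neg","zero","pos")
  model
}

#' Fit the 3-state importance HMM by Baum-Welch
#'
#' Expectation-maximization on discretized importance sequences. The
#' initialization is informative (state k biased towards emitting symbol k,
#' sticky transitions) with a small seeded jitter; the training log-likelihood
#' is non-decreasing across iterations. After convergence, states are
#' relabeled so state 1 maximizes P(emit -1), state 2 P(emit 0) and state 3
#' P(emit +1). Degenerate inputs (a single symbol throughout) converge to
#' degenerate emissions and are flagged via `model$degenerate`.
#'
#' @param sequences integer matrix (windows x positions) or list of integer
#'   vectors with values in `{-1, 0, 1}`.
#' @param seed RNG seed for the jittered initialization.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the total log-likelihood.
#' @return a model list: `init`, `trans` (3x3), `emis` (3x3, columns = symbols
#'   -1/0/+1), `loglik` (per-iteration trace), `degenerate`.
#' @export
fit_importance_hmm <- function(sequences, seed = 1L, max_iter = 100L, tol = 1e-4) {
  if (is.matrix(sequences)) sequences <- asplit(sequences, 1L)
  sequences <- lapply(sequences, as.integer)
  if (length(sequences) == 0L || any(lengths(sequences) == 0L))
    stop("need >= 1 non-empty sequence")
  obs <- lapply(sequences, symbols_to_idx)
  set.seed(seed)
  init <- rep(1/3, 3)
  trans <- matrix(0.05, 3, 3); diag(trans) <- 0.9
  emis <- matrix(0.1, 3, 3); diag(emis) <- 0.8
  emis <- emis + matrix(runif(9, 0, 0.01), 3, 3)
  emis <- emis / rowSums(emis)

  # group sequences by length so forward/backward vectorizes across sequences
  by_len <- split(seq_along(obs), lengths(obs))
  slice <- function(arr, t) matrix(arr[, , t], nrow = dim(arr)[1])
  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, 3, 3)
    E_num <- matrix(0, 3, 3)
    I_num <- numeric(3)
    total_ll <- 0
    for (grp in by_len) {
      Tn <- length(obs[[grp[1]]])
      ns <- length(grp)
      O <- matrix(unlist(obs[grp]), nrow = ns, byrow = TRUE)  # ns x Tn
      eo <- function(t) matrix(emis[, O[, t]], nrow = 3)      # 3 x ns
      # scaled forward
      alpha <- array(0, c(ns, 3, Tn))
      scl <- matrix(0, ns, Tn)
      a <- t(eo(1) * init)
      scl[, 1] <- rowSums(a)
      alpha[, , 1] <- a / scl[, 1]
      if (Tn > 1L) for (t in 2:Tn) {
        a <- (slice(alpha, t - 1L) %*% trans) * t(eo(t))
        scl[, t] <- rowSums(a)
        alpha[, , t] <- a / scl[, t]
      }
      total_ll <- total_ll + sum(log(scl))
      # scaled backward
      beta <- array(0, c(ns, 3, Tn))
      beta[, , Tn] <- 1
      if (Tn > 1L) for (t in (Tn - 1L):1L) {
        b <- (slice(beta, t + 1L) * t(eo(t + 1L))) %*% t(trans)
        beta[, , t] <- b / scl[, t + 1L]
      }
      g1 <- slice(alpha, 1L) * slice(beta, 1L)
      g1 <- g1 / rowSums(g1)
      I_num <- I_num + colSums(g1)
      # flatten to (n, t)-rows x state-columns, n fastest then t
      alpha2 <- matrix(aperm(alpha, c(1L, 3L, 2L)), ncol = 3L)
      beta2 <- matrix(aperm(beta, c(1L, 3L, 2L)), ncol = 3L)
      EO2 <- t(emis)[as.vector(O), , drop = FALSE]  # row (n,t): emis[s, O[n,t]]
      # transition expectations:
      # A_num[i, j] = trans[i, j] * sum_{n, t<Tn} alpha[n, i, t] *
      #               emis[j, O[n, t+1]] * beta[n, j, t+1] / scl[n, t+1]
      if (Tn > 1L) {
        U <- EO2 * beta2 / as.vector(scl)
        head_rows <- seq_len(ns * (Tn - 1L))
        tail_rows <- head_rows + ns
        A_num <- A_num + trans *
          crossprod(alpha2[head_rows, , drop = FALSE],
                    U[tail_rows, , drop = FALSE])
      }
      # emission expectations
      G <- alpha2 * beta2
      G <- G / rowSums(G)
      gsum <- rowsum(G, as.vector(O))
      E_num[, as.integer(rownames(gsum))] <-
        E_num[, as.integer(rownames(gsum)), drop = FALSE] + t(gsum)
    }
    ll_trace <- c(ll_trace, total_ll)
    init <- I_num / sum(I_num)
    rs <- rowSums(A_num)
    if (any(rs > 0)) trans[rs > 0, ] <- A_num[rs > 0, , drop = FALSE] / rs[rs > 0]
    rs <- rowSums(E_num)
    emis[rs > 0, ] <- E_num[rs > 0, , drop = FALSE] / rs[rs > 0]
    emis[rs == 0, ] <- 1/3
    if (is.finite(prev_ll) && abs(total_ll - prev_ll) < tol) break
    prev_ll <- total_ll
  }
  model <- hmm_relabel(list(init = init, trans = trans, emis = emis,
                            loglik = ll_trace))
  model$degenerate <- any(apply(model$emis, 1L, max) > 1 - 1e-6) &&
    length(unique(unlist(sequences))) == 1L
  # model selection against the iid multinomial baseline: the segmentation is
  # only meaningful when the HMM's structure is supported by the data (BIC);
  # on featureless data EM gains only a few nats from noise autocorrelation,
  # far below the parameter penalty, and no site states are reported
  n_sym <- sum(lengths(obs))
  counts <- tabulate(unlist(obs), 3L)
  ll_iid <- sum(counts[counts > 0] * log(counts[counts > 0] / n_sym))
  ll_hmm <- ll_trace[length(ll_trace)]
  model$bic_hmm <- -2 * ll_hmm + 14 * log(n_sym)
  model$bic_iid <- -2 * ll_iid + 2 * log(n_sym)
  model$site_support <- model$bic_hmm < model$bic_iid
  hmm_validate(model)
  model
}

#' Viterbi decoding of a symbol sequence
#'
#' @param model a fitted HMM (see [fit_importance_hmm()]).
#' @param symbols integer vector in `{-1, 0, 1}`.
#' @return integer vector of decoded states (1 = negative-importance state,
#'   2 = background, 3 = positive-importance state).
#' @export
viterbi_decode <- function(model, symbols) {
  hmm_validate(model)
  o <- symbols_to_idx(as.integer(symbols))
  Tn <- length(o)
  lt <- log(pmax(model$trans, 1e-300))
  le <- log(pmax(model$emis, 1e-300))
  li <- log(pmax(model$init, 1e-300))
  delta <- matrix(-Inf, 3, Tn)
  psi <- matrix(0L, 3, Tn)
  delta[, 1] <- li + le[, o[1]]
  if (Tn > 1L) for (t in 2:Tn) {
    cand <- delta[, t - 1L] + lt  # cand[i, j] = delta_i + log trans i->j
    psi[, t] <- max.col(t(cand), ties.method = "first")
    delta[, t] <- cand[cbind(psi[, t], 1:3)] + le[, o[t]]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[, Tn])
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- psi[path[t + 1L], t + 1L]
  path
}

#' Posterior (forward-backward) decoding of a symbol sequence
#'
#' Alternative to [viterbi_decode()]: per-position argmax of the posterior
#' state probability.
#' @inheritParams viterbi_decode
#' @return integer vector of decoded states.
#' @export
posterior_decode <- function(model, symbols) {
  hmm_validate(model)
  o <- symbols_to_idx(as.integer(symbols))
  Tn <- length(o)
  alpha <- matrix(0, 3, Tn); beta <- matrix(0, 3, Tn); sc <- numeric(Tn)
  a <- model$init * model$emis[, o[1]]
  sc[1] <- sum(a); alpha[, 1] <- a / sc[1]
  if (Tn > 1L) for (t in 2:Tn) {
    a <- (t(model$trans) %*% alpha[, t - 1L]) * model$emis[, o[t]]
    sc[t] <- sum(a); alpha[, t] <- a / sc[t]
  }
  beta[, Tn] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L)
    beta[, t] <- model$trans %*% (model$emis[, o[t + 1L]] * beta[, t + 1L]) / sc[t + 1L]
  post <- alpha * beta
  apply(post, 2L, which.max)
}

# batched Viterbi over equal-length windows; returns windows x positions state
# matrix with the same tie rule as viterbi_decode (first index wins)
viterbi_decode_batch <- function(model, O) {
  ns <- nrow(O); Tn <- ncol(O)
  lt <- log(pmax(model$trans, 1e-300))
  le_t <- t(log(pmax(model$emis, 1e-300)))  # symbols x states
  li <- log(pmax(model$init, 1e-300))
  delta <- matrix(li, ns, 3L, byrow = TRUE) + le_t[O[, 1], , drop = FALSE]
  psi <- array(0L, c(ns, 3L, Tn))
  if (Tn > 1L) for (t in 2:Tn) {
    newdelta <- matrix(0, ns, 3L)
    for (j in 1:3) {
      cand <- delta + matrix(lt[, j], ns, 3L, byrow = TRUE)
      arg <- max.col(cand, ties.method = "first")
      psi[, j, t] <- arg
      newdelta[, j] <- cand[cbind(seq_len(ns), arg)]
    }
    delta <- newdelta + le_t[O[, t], , drop = FALSE]
  }
  path <- matrix(0L, ns, Tn)
  path[, Tn] <- max.col(delta, ties.method = "first")
  if (Tn > 1L) for (t in (Tn - 1L):1L)
    path[, t] <- psi[cbind(seq_len(ns), path[, t + 1L], t + 1L)]
  path
}

# split a decoded segment on runs of >= min_zero_run consecutive 0 symbols
split_on_zero_runs <- function(sym_seg, min_zero_run) {
  r <- rle(sym_seg == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cut <- r$values & r$lengths >= min_zero_run
  keep_mask <- rep(TRUE, length(sym_seg))
  for (k in which(cut)) keep_mask[starts[k]:ends[k]] <- FALSE
  rr <- rle(keep_mask)
  e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1L
  data.frame(start = s2[rr$values], end = e2[rr$values])
}

#' Segment cTFBS calls from a decoded window
#'
#' Viterbi-decodes the window (or uses posterior decoding), takes maximal runs
#' of the positive- and negative-importance states as candidate segments,
#' excises runs of `min_zero_run` or more consecutive 0 *symbols* inside each
#' segment (splitting it), and drops empty fragments. A state only yields
#' sites when it predominantly emits its own symbol (its emission probability
#' for the site symbol is at least that of 0); on featureless data the fitted
#' states are weak mixtures and produce no calls.
#'
#' @param model fitted HMM.
#' @param symbols integer vector in `{-1, 0, 1}` for one window.
#' @param min_zero_run zero-run length that splits a segment (default 4).
#' @param importance optional raw importance vector (same length) used to
#'   record each site's mean importance.
#' @param decoding `"viterbi"` (default) or `"posterior"`.
#' @return `data.frame` with columns `start`, `end` (1-based, window-relative,
#'   closed), `direction` (`"positive"`/`"negative"`) and `mean_importance`.
#' @export
segment_ctfbs <- function(model, symbols, min_zero_run = 4L, importance = NULL,
                          decoding = c("viterbi", "posterior")) {
  decoding <- match.arg(decoding)
  path <- if (decoding == "viterbi") viterbi_decode(model, symbols)
          else posterior_decode(model, symbols)
  segment_from_path(path, symbols, min_zero_run, importance,
                    states = site_states(model))
}

# states interpretable as site states: a state only yields sites when it
# predominantly emits its own symbol (at least as often as 0) — a fitted
# state whose modal emission is the background symbol is not a site state
site_states <- function(model) {
  if (!is.null(model$site_support) && !model$site_support) return(integer(0))
  c(1L, 3L)[c(model$emis[1L, 1L] >= model$emis[1L, 2L],
              model$emis[3L, 3L] >= model$emis[3L, 2L])]
}

# shared post-processing of a decoded state path
segment_from_path <- function(path, symbols, min_zero_run, importance = NULL,
                              states = c(1L, 3L)) {
  out <- list()
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values %in% states)) {
    seg <- starts[k]:ends[k]
    pieces <- split_on_zero_runs(symbols[seg], min_zero_run)
    if (nrow(pieces) == 0L) next
    pieces$start <- pieces$start + starts[k] - 1L
    pieces$end <- pieces$end + starts[k] - 1L
    pieces$direction <- if (r$values[k] == 3L) "positive" else "negative"
    out[[length(out) + 1L]] <- pieces
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      direction = character(), mean_importance = numeric()))
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  df$mean_importance <- if (is.null(importance)) {
    vapply(seq_len(nrow(df)), function(i) mean(symbols[df$start[i]:df$end[i]]), 0)
  } else {
    vapply(seq_len(nrow(df)), function(i) mean(importance[df$start[i]:df$end[i]]), 0)
  }
  rownames(df) <- NULL
  df
}

#' Call cTFBS records across a set of windows
#'
#' Runs [segment_ctfbs()] on every row of a symbol matrix and lifts the
#' window-relative coordinates to the genome using the window ranges.
#'
#' @param model fitted HMM.
#' @param symbols integer matrix (windows x positions).
#' @param windows element set of the windows (same order as matrix rows);
#'   `NULL` keeps window-relative coordinates with window index as id.
#' @param importance optional raw importance matrix matching `symbols`.
#' @param min_zero_run,decoding see [segment_ctfbs()].
#' @return `data.frame` with columns `window`, `chrom`, `start`, `end`
#'   (1-based closed genomic, or window-relative when `windows` is `NULL`),
#'   `direction`, `mean_importance`.
#' @export
call_ctfbs <- function(model, symbols, windows = NULL, importance = NULL,
                       min_zero_run = 4L, decoding = "viterbi") {
  stopifnot(is.matrix(symbols))
  paths <- if (decoding == "viterbi")
    viterbi_decode_batch(model, symbols_to_idx(symbols)) else NULL
  res <- lapply(seq_len(nrow(symbols)), function(i) {
    imp_i <- if (is.null(importance)) NULL else importance[i, ]
    df <- if (!is.null(paths))
      segment_from_path(paths[i, ], symbols[i, ], min_zero_run, imp_i,
                        states = site_states(model))
    else
      segment_ctfbs(model, symbols[i, ], min_zero_run, importance = imp_i,
                    decoding = decoding)
    if (nrow(df) == 0L) return(NULL)
    df$window <- if (!is.null(rownames(symbols))) rownames(symbols)[i] else i
    if (!is.null(windows)) {
      ws <- GenomicRanges::start(windows)[i]
      df$chrom <- as.character(GenomicRanges::seqnames(windows))[i]
      df$start <- df$start + ws - 1L
      df$end <- df$end + ws - 1L
    } else df$chrom <- NA_character_
    df
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L)
    return(data.frame(window = character(), chrom = character(),
                      start = integer(), end = integer(),
                      direction = character(), mean_importance = numeric()))
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df[, c("window", "chrom", "start", "end", "direction", "mean_importance")]
}
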