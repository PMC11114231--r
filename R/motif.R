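# PWM catalogs (MEME minimal / JASPAR PFM text), padded similarity scoring,
# motif assignment, chi-square motif-set comparison and site-set operations.

DNA_BASES <- c("A", "C", "G", "T")

#' Validate a PWM
#'
#' A PWM is a 4 x L numeric matrix (rows A, C, G, T) whose columns each sum to
#' 1 within 1e-6.
#' @param pwm matrix to validate.
#' @return the PWM, invisibly.
#' @export
validate_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L || ncol(pwm) < 1L)
    stop("PWM must be a 4 x L matrix with L >= 1")
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  invisible(pwm)
}

#' Read a MEME minimal-format motif file
#'
#' @param path MEME minimal file (letter-probability matrices over ACGT).
#' @return named list of PWMs (4 x L matrices, rows A/C/G/T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) stop("no MOTIF records in ", path)
  out <- list()
  for (k in seq_along(motif_idx)) {
    hdr <- strsplit(trimws(lines[motif_idx[k]]), "\\s+")[[1]]
    id <- hdr[2]
    lp <- grep("^letter-probability", lines[motif_idx[k]:length(lines)])[1] +
      motif_idx[k] - 1L
    if (is.na(lp)) stop("motif ", id, ": missing letter-probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[lp])
    w <- as.integer(w)
    rows <- lines[(lp + 1L):(lp + w)]
    vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                     function(x) as.numeric(x[1:4]), numeric(4)))
    pwm <- t(vals)  # 4 x L
    rownames(pwm) <- DNA_BASES
    validate_pwm(pwm)
    out[[id]] <- pwm
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param catalog named list of PWMs.
#' @param path output path.
#' @param background background frequencies (length 4).
#' @export
write_meme <- function(catalog, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (id in names(catalog)) {
    pwm <- catalog[[id]]
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(pwm)), con)
    writeLines(apply(pwm, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts the `>id name` header followed by four rows of counts, either bare
#' or in the `A [ 1 2 3 ]` bracket style. Counts are normalized to
#' per-column probabilities.
#'
#' @param path PFM file path.
#' @return named list of PWMs.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no '>' motif headers in ", path)
  out <- list()
  for (k in seq_along(hdr_idx)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr_idx[k]]), "\\s+")[[1]][1]
    rows <- lines[hdr_idx[k] + 1:4]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGT]\\s*", "", trimws(r))
      r <- gsub("[][]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop("motif ", id, ": rows of unequal length")
    m <- do.call(rbind, vals)
    rownames(m) <- DNA_BASES
    pwm <- sweep(m, 2L, colSums(m), `/`)
    validate_pwm(pwm)
    out[[id]] <- pwm
  }
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)  # N and others -> NA
}

# similarity of a fixed-orientation sequence against a PWM: max over offsets
# of the shorter object fully inside the longer; unaligned positions of the
# longer object contribute the uniform 0.25; N contributes 0.25 where aligned.
similarity_one_strand <- function(idx, pwm) {
  L <- ncol(pwm)
  n <- length(idx)
  probs <- rbind(pwm, N = rep(0.25, L))  # row 5 handles N
  idx[is.na(idx)] <- 5L
  if (n >= L) {
    offsets <- 0:(n - L)
    best <- -Inf
    for (off in offsets) {
      aligned <- sum(probs[cbind(idx[(off + 1):(off + L)], seq_len(L))])
      best <- max(best, aligned + 0.25 * (n - L))
    }
  } else {
    offsets <- 0:(L - n)
    best <- -Inf
    for (off in offsets) {
      aligned <- sum(probs[cbind(idx, (off + 1):(off + n))])
      best <- max(best, aligned + 0.25 * (L - n))
    }
  }
  best
}

#' Padded similarity between a sequence and a PWM
#'
#' Enumerates every alignment in which the shorter of the two objects lies
#' fully within the longer; the score of an alignment is the sum of the PWM
#' probabilities of the observed bases over aligned positions plus 0.25 for
#' every unaligned position of the longer object (penalizing length
#' mismatch). `N` bases contribute 0.25. The returned value is the maximum
#' over alignments, and over both strands when `both_strands`.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm a 4 x L PWM.
#' @param both_strands also score the reverse complement (default `TRUE`).
#' @return numeric similarity score.
#' @export
motif_similarity <- function(seq, pwm, both_strands = TRUE) {
  if (!nzchar(seq)) stop("empty sequence")
  validate_pwm(pwm)
  s <- similarity_one_strand(seq_to_idx(seq), pwm)
  if (both_strands)
    s <- max(s, similarity_one_strand(seq_to_idx(revcomp(seq)), pwm))
  s
}

#' Assign the best-matching motif to a sequence
#'
#' Argmax of [motif_similarity()] over the catalog; ties break to the
#' lexicographically smallest motif id.
#'
#' @param seq DNA string.
#' @param catalog named list of PWMs.
#' @param both_strands see [motif_similarity()].
#' @return list with `motif` (id) and `similarity`.
#' @export
assign_best_motif <- function(seq, catalog, both_strands = TRUE) {
  if (length(catalog) == 0L) stop("empty motif catalog")
  ids <- sort(names(catalog))
  scores <- vapply(ids, function(id)
    motif_similarity(seq, catalog[[id]], both_strands), 0)
  best <- which.max(scores)  # first max = lexicographically smallest id
  list(motif = ids[best], similarity = unname(scores[best]))
}

#' Chi-square comparison of motif composition between two site sets
#'
#' For each motif with at least `min_instances` instances in *each* set,
#' compares the motif's share of the two sets with a 2x2 Pearson chi-square
#' test with Yates continuity correction. Motifs below the floor, and
#' zero-margin tables, are excluded (the latter with a warning).
#'
#' @param counts_a,counts_b named integer vectors of per-motif instance
#'   counts.
#' @param total_a,total_b total instance counts of each set.
#' @param min_instances per-set instance floor (default 25).
#' @return `data.frame` with columns `motif`, `count_a`, `count_b`, `chi2`,
#'   `p`.
#' @export
motif_set_chi2 <- function(counts_a, total_a, counts_b, total_b,
                           min_instances = 25L) {
  if (any(counts_a > total_a) || any(counts_b > total_b))
    stop("totals must be >= counts")
  motifs <- union(names(counts_a), names(counts_b))
  a <- setNames(rep(0L, length(motifs)), motifs)
  a[names(counts_a)] <- counts_a
  b <- setNames(rep(0L, length(motifs)), motifs)
  b[names(counts_b)] <- counts_b
  keep <- a >= min_instances & b >= min_instances
  motifs <- motifs[keep]
  res <- lapply(motifs, function(m) {
    tab <- matrix(c(a[m], total_a - a[m], b[m], total_b - b[m]), 2L,
                  byrow = TRUE)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning("zero-margin table for motif ", m, "; excluded")
      return(NULL)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    data.frame(motif = m, count_a = unname(a[m]), count_b = unname(b[m]),
               chi2 = unname(ct$statistic), p = ct$p.value)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L)
    return(data.frame(motif = character(), count_a = integer(),
                      count_b = integer(), chi2 = numeric(), p = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify sites as set-specific or shared
#'
#' A site is `shared` when it overlaps (>= 1 bp) any site of the other set,
#' otherwise `a-only`/`b-only`.
#'
#' @param sites_a,sites_b element sets of called sites.
#' @return named character vector over the ids of both sets.
#' @export
site_specificity_classes <- function(sites_a, sites_b) {
  sa <- GenomicRanges::countOverlaps(sites_a, sites_b) > 0L
  sb <- GenomicRanges::countOverlaps(sites_b, sites_a) > 0L
  out <- c(setNames(ifelse(sa, "shared", "a-only"), names(sites_a)),
           setNames(ifelse(sb, "shared", "b-only"), names(sites_b)))
  out
}

#' Positionwise mean importance profiles at sites, per cell type
#'
#' Aligns fixed-width windows centered on each site's midpoint and averages
#' the per-base importance per cell type. Sites whose window exceeds the track
#' bounds are skipped with a warning.
#'
#' @param sites element set of sites.
#' @param tracks named list (cell type -> numeric `RleList` importance track).
#' @param flank half-window in bp (profile length `2*flank + 1`).
#' @return matrix, cell types x positions.
#' @export
site_importance_profiles <- function(sites, tracks, flank = 50L) {
  if (length(sites) == 0L) stop("empty site list")
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) %/% 2L
  centers <- data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                        pos = mid)
  out <- t(vapply(tracks, function(tr)
    aggregate_signal_profile(tr, centers, flank, smooth_window = 1L),
    numeric(2L * flank + 1L)))
  rownames(out) <- names(tracks)
  out
}
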