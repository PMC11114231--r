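#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors Rle runValue runLength queryHits subjectHits mcols mcols<-
#' @importFrom stats rnorm runif setNames qnorm
#' @importFrom utils head tail
NULL

# ---- element sets -----------------------------------------------------------

#' Construct an element set
#'
#' An element set is a `GRanges` holding genomic intervals with unique ids
#' (stored as `names`) and an optional per-element class label
#' (`mcols(x)$label`). Intervals are kept sorted by (chrom, start). On-disk
#' coordinates are BED-style 0-based half-open; in memory the usual R/Bioc
#' 1-based closed convention is used, with conversion confined to the readers
#' and writers.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end integer vectors, 0-based half-open as in BED.
#' @param id element identifiers; autogenerated as `"chrom:start-end"` when
#'   `NULL`.
#' @param label optional character vector of class labels.
#' @return A sorted `GRanges` with unique names.
#' @export
element_set <- function(chrom, start0, end, id = NULL, label = NULL) {
  start0 <- as.numeric(start0); end <- as.numeric(end)
  if (any(start0 >= end))
    stop("invalid interval(s): start must be < end (0-based half-open)")
  if (any(start0 < 0)) stop("negative start coordinate")
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end))
  if (anyDuplicated(id)) stop("element ids must be unique")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end))
  names(gr) <- id
  if (!is.null(label)) S4Vectors::mcols(gr)$label <- label
  sort_element_set(gr)
}

sort_element_set <- function(gr) {
  ord <- order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  gr[ord]
}

#' Read an element BED file (BED3+, optional 4th column id, 5th label)
#'
#' @param path path to a BED3/BED4 file (tab-separated, no header).
#' @return an element set (`GRanges`, see [element_set()]).
#' @export
read_element_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields", bad[1], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad[1], path))
  bad <- which(start0 >= end)
  if (length(bad))
    stop(sprintf("invalid BED line %d in %s: start >= end", bad[1], path))
  id <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  id <- ifelse(is.na(id) | id == ".",
               sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end)), id)
  label <- if (any(nf >= 5L)) {
    vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")
  } else NULL
  element_set(chrom, start0, end, id = id, label = label)
}

#' Write an element set to BED
#'
#' Columns: chrom, start (0-based), end, id, and the `label` metadata column
#' when present.
#' @param elements an element set.
#' @param path output path.
#' @export
write_element_bed <- function(elements, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(elements)),
                   start = GenomicRanges::start(elements) - 1L,
                   end = GenomicRanges::end(elements),
                   id = if (is.null(names(elements)))
                     sprintf("E%d", seq_along(elements)) else names(elements),
                   stringsAsFactors = FALSE)
  if (!is.null(S4Vectors::mcols(elements)$label))
    df$label <- S4Vectors::mcols(elements)$label
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- signal tracks ----------------------------------------------------------

#' Construct a signal track from runs
#'
#' A signal track is a per-chromosome run-length encoded, non-negative,
#' per-base signal (a `SimpleRleList`, the standard Bioconductor coverage
#' container). Positions not covered by any run have value 0, matching
#' bedGraph sparsity semantics.
#'
#' @param chrom,start0,end run coordinates (BED-style 0-based half-open).
#' @param value non-negative finite run values.
#' @param seqlengths named vector of chromosome lengths; inferred from the
#'   right-most run per chromosome when `NULL`.
#' @return a numeric `RleList`, one `Rle` per chromosome.
#' @export
signal_track <- function(chrom, start0, end, value, seqlengths = NULL) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("track values must be finite and >= 0")
  if (any(start0 >= end)) stop("runs must have start < end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end), score = value)
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(GenomicRanges::end(gr),
                               as.character(GenomicRanges::seqnames(gr))), max, 0)
  }
  cov <- GenomicRanges::coverage(gr, weight = gr$score,
                                 width = as.list(seqlengths)[names(seqlengths)])
  self <- GenomicRanges::coverage(gr, width = as.list(seqlengths)[names(seqlengths)])
  if (any(max(self) > 1L)) stop("overlapping runs in signal track")
  cov
}

#' Read a bedGraph file into a signal track
#'
#' @param path bedGraph path (4 columns, no header; track lines are skipped).
#' @param seqlengths optional named chromosome lengths.
#' @return a numeric `RleList`.
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  signal_track(dt$chrom, dt$start, dt$end, dt$value, seqlengths = seqlengths)
}

#' Write a signal track to bedGraph
#'
#' Zero-valued runs are omitted (canonical sparse bedGraph).
#' @param track a numeric `RleList`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(ch) {
    r <- track[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based
    v <- S4Vectors::runValue(r)
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = ch, start = starts[keep], end = ends[keep],
                           value = v[keep])
  })
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Base-weighted mean signal over elements
#'
#' For each element, the mean of the per-base track values across the
#' element's extent. Elements on chromosomes absent from the track get 0 with
#' a warning.
#'
#' @param track a numeric `RleList`.
#' @param elements an element set.
#' @return named numeric vector, one value per element (in element order).
#' @export
mean_signal_over_elements <- function(track, elements) {
  if (length(elements) == 0L) stop("empty element set")
  if (any(GenomicRanges::width(elements) < 1L)) stop("zero-length element")
  out <- numeric(length(elements))
  chroms <- as.character(GenomicRanges::seqnames(elements))
  missing <- !(chroms %in% names(track))
  if (any(missing))
    warning(sprintf("%d element(s) on chromosomes absent from track; value 0",
                    sum(missing)))
  for (ch in unique(chroms[!missing])) {
    i <- which(chroms == ch)
    r <- track[[ch]]
    s <- GenomicRanges::start(elements)[i]
    e <- GenomicRanges::end(elements)[i]
    if (any(e > length(r))) {
      # extend implicit zero tail
      r <- c(r, S4Vectors::Rle(0, max(e) - length(r)))
    }
    out[i] <- IRanges::viewMeans(IRanges::Views(r, start = s, end = e))
  }
  names(out) <- names(elements)
  out
}

#' Pointwise sum of signal tracks
#'
#' @param tracks a list of numeric `RleList` tracks (possibly with different
#'   chromosome sets/lengths; gaps count as 0).
#' @return a numeric `RleList` over the union of chromosomes.
#' @export
sum_tracks <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) stop("need >= 1 track")
  chroms <- unique(unlist(lapply(tracks, names)))
  lens <- setNames(numeric(length(chroms)), chroms)
  for (tr in tracks)
    for (ch in names(tr)) lens[ch] <- max(lens[ch], length(tr[[ch]]))
  out <- lapply(chroms, function(ch) {
    acc <- S4Vectors::Rle(0, lens[ch])
    for (tr in tracks) {
      if (!ch %in% names(tr)) next
      r <- tr[[ch]]
      if (length(r) < lens[ch]) r <- c(r, S4Vectors::Rle(0, lens[ch] - length(r)))
      acc <- acc + r
    }
    acc
  })
  methods::as(setNames(out, chroms), "SimpleRleList")
}

#' Overlap fractions of target elements covered by query elements
#'
#' Reports, for every overlapping (query, target) pair, the number of
#' overlapping bases divided by the target's length. Only pairs with >= 1 bp
#' overlap appear.
#'
#' @param query,targets element sets.
#' @return `data.frame` with columns `query_id`, `target_id`, `fraction`.
#' @export
overlap_fractions <- function(query, targets) {
  hits <- GenomicRanges::findOverlaps(query, targets)
  if (length(hits) == 0L)
    return(data.frame(query_id = character(), target_id = character(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  q <- query[S4Vectors::queryHits(hits)]
  t <- targets[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::width(GenomicRanges::pintersect(q, t))
  data.frame(query_id = names(query)[S4Vectors::queryHits(hits)],
             target_id = names(targets)[S4Vectors::subjectHits(hits)],
             fraction = ov / GenomicRanges::width(t),
             stringsAsFactors = FALSE)
}
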