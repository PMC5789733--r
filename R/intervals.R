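#' Genome coordinate conventions
#'
#' Internally every interval is 0-based half-open `[start, end)`, the native
#' BED convention; SNP positions from association catalogs and eQTL tables are
#' 1-based and converted on read. A 1-based position `pos` overlaps an
#' interval iff `start <= pos - 1 < end`. Chromosome names are matched as
#' exact strings ("chr1" and "1" are different sequences); see
#' [normalize_chrom()] for an explicit conversion.
#'
#' @name coordinate-conventions
NULL

VALID_KINDS <- c("gene", "exon", "promoter", "enhancer", "motif")

validate_intervals <- function(intervals, call = rlang::caller_env()) {
  intervals <- as_tibble(intervals)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "*"
  if (!"feature_id" %in% names(intervals)) {
    intervals$feature_id <- paste0("feature_", seq_len(nrow(intervals)))
  }
  if (!"feature_kind" %in% names(intervals)) intervals$feature_kind <- NA_character_
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  bad <- which(is.na(intervals$start) | is.na(intervals$end) |
                 intervals$start < 0L | intervals$start >= intervals$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval (need 0 <= start < end) at row ", bad[1],
                 ": ", intervals$chrom[bad[1]], ":[", intervals$start[bad[1]],
                 ",", intervals$end[bad[1]], ") feature_id=",
                 intervals$feature_id[bad[1]]), call = call)
  }
  bad_chrom <- which(is.na(intervals$chrom) | intervals$chrom == "")
  if (length(bad_chrom) > 0) {
    abort(paste0("empty chromosome name at row ", bad_chrom[1]), call = call)
  }
  intervals$strand[is.na(intervals$strand) | intervals$strand == "."] <- "*"
  bad_strand <- which(!intervals$strand %in% c("+", "-", "*"))
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand '", intervals$strand[bad_strand[1]],
                 "' at row ", bad_strand[1]), call = call)
  }
  intervals
}

#' Build a searchable index over genomic intervals
#'
#' Wraps a validated interval table in a [GenomicRanges::GRanges]-backed index
#' supporting vectorised point-overlap ([query_points()]) and nearest-feature
#' ([nearest_features()]) queries. Duplicate intervals are preserved.
#'
#' @param intervals A data frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), and optionally `strand`, `feature_id`, `feature_kind`
#'   plus arbitrary payload columns (e.g. `tf` for motif occurrences), which
#'   are carried through query results.
#' @return An object of class `interval_index`.
#' @examples
#' idx <- interval_index(tibble::tibble(
#'   chrom = "chr1", start = 100, end = 200,
#'   feature_id = "gene_1", feature_kind = "gene"))
#' query_points(idx, tibble::tibble(chrom = "chr1", pos = 101))
#' @export
interval_index <- function(intervals) {
  intervals <- validate_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = ifelse(intervals$strand == "*", "*", intervals$strand)
  )
  structure(list(intervals = intervals, gr = gr), class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat("<interval_index> ", nrow(x$intervals), " intervals on ",
      length(unique(x$intervals$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
length.interval_index <- function(x) nrow(x$intervals)

points_to_gr <- function(points, call = rlang::caller_env()) {
  points <- as_tibble(points)
  if (!all(c("chrom", "pos") %in% names(points))) {
    abort("point table needs columns `chrom` and `pos` (1-based)", call = call)
  }
  if (nrow(points) > 0 && any(is.na(points$pos) | points$pos < 1)) {
    abort("positions must be 1-based positive integers", call = call)
  }
  GenomicRanges::GRanges(points$chrom,
                         IRanges::IRanges(points$pos, width = 1L))
}

#' Find all intervals containing each query point
#'
#' @param index An [interval_index()].
#' @param points A data frame with columns `chrom` and `pos` (1-based);
#'   additional columns (e.g. `snp_id`) are carried through.
#' @param kind Optional feature kind filter (e.g. `"motif"`).
#' @return A tibble with one row per (point, containing interval) pair:
#'   the point columns followed by the interval columns. Rows for a given
#'   point are ordered by interval `start`, then `feature_id`. Points on a
#'   chromosome absent from the index simply contribute no rows.
#' @export
query_points <- function(index, points, kind = NULL) {
  stopifnot(inherits(index, "interval_index"))
  points <- as_tibble(points)
  qgr <- points_to_gr(points)
  ivs <- index$intervals
  keep <- rep(TRUE, nrow(ivs))
  if (!is.null(kind)) keep <- ivs$feature_kind %in% kind
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    qgr, index$gr[keep], ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- which(keep)[S4Vectors::subjectHits(hits)]
  point_cols <- setdiff(names(points), names(ivs))
  out <- dplyr::bind_cols(
    points[qi, point_cols, drop = FALSE],
    ivs[si, , drop = FALSE]
  )
  ord <- order(qi, ivs$start[si], ivs$feature_id[si], method = "radix")
  out[ord, , drop = FALSE]
}

#' Logical containment test per point
#'
#' @inheritParams query_points
#' @return Logical vector, one element per row of `points`: does the point
#'   fall inside at least one (kind-filtered) interval?
#' @export
points_overlap <- function(index, points, kind = NULL) {
  stopifnot(inherits(index, "interval_index"))
  points <- as_tibble(points)
  qgr <- points_to_gr(points)
  keep <- rep(TRUE, length(index$gr))
  if (!is.null(kind)) keep <- index$intervals$feature_kind %in% kind
  suppressWarnings(GenomicRanges::countOverlaps(
    qgr, index$gr[keep], ignore.strand = TRUE)) > 0
}

#' Nearest feature of a given kind for each query point
#'
#' Distance is 0 when the point lies inside the feature span; otherwise it is
#' the base-pair offset to the closest base of the span (a point immediately
#' adjacent to a feature is 1 bp away). Ties are broken by smaller distance,
#' then lexicographically smaller `feature_id`, so results are deterministic.
#'
#' @inheritParams query_points
#' @param kind Feature kind to search (e.g. `"gene"`).
#' @return A tibble: the point columns plus `feature_id` and `distance`.
#'   Points on a chromosome with no feature of the kind get `NA` in both,
#'   so the caller decides how to treat them.
#' @export
nearest_features <- function(index, points, kind) {
  stopifnot(inherits(index, "interval_index"))
  points <- as_tibble(points)
  qgr <- points_to_gr(points)
  keep <- which(index$intervals$feature_kind %in% kind)
  out <- points
  out$feature_id <- NA_character_
  out$distance <- NA_integer_
  if (length(keep) == 0 || nrow(points) == 0) return(out)
  sub_gr <- index$gr[keep]
  subs <- index$intervals[keep, , drop = FALSE]
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(
    qgr, sub_gr, select = "all", ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # convert the gap-style IRanges distance (adjacent = 0) to the adjacency =
  # 1 convention; overlapping candidates keep distance 0
  p0 <- points$pos[qi] - 1L
  inside <- p0 >= subs$start[si] & p0 < subs$end[si]
  dist <- ifelse(inside, 0L,
                 as.integer(S4Vectors::mcols(hits)$distance) + 1L)
  cand <- tibble(qi = qi, feature_id = subs$feature_id[si], distance = dist)
  best <- cand |>
    arrange(.data$qi, .data$distance, .data$feature_id) |>
    dplyr::distinct(.data$qi, .keep_all = TRUE)
  out$feature_id[best$qi] <- best$feature_id
  out$distance[best$qi] <- best$distance
  out
}

#' Normalize chromosome naming
#'
#' Chromosome matching everywhere else is exact-string; this helper converts
#' between the "chr1" and "1" styles explicitly.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"chr"` to ensure the "chr" prefix, `"plain"` to strip it.
#' @return Character vector.
#' @export
normalize_chrom <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  stripped <- sub("^chr", "", chrom)
  if (style == "chr") paste0("chr", stripped) else stripped
}
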