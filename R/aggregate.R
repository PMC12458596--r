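#' Aggregate interval features into structure bins
#'
#' The gene-density workflow: features (e.g. genes read from a GTF) are
#' intersected with the bins of the structure and summarized into a new
#' numeric data column, ready to drive a color or scale encoding.
#' Intersection is half-open: a feature that merely touches a bin boundary
#' does not count. Strand is ignored. Modes:
#' \describe{
#'   \item{count}{number of features with non-empty intersection.}
#'   \item{coverage}{fraction of the bin covered by the union of the
#'     (bin-clipped) feature intersections, in `[0, 1]`.}
#'   \item{score_mean}{mean `score` of the overlapping features; bins with
#'     no feature get 0, and which bins those were is recorded in the
#'     structure attribute `<out_column>_missing` (a logical vector).}
#' }
#' Bins with zero features get 0 (not NA) for count/coverage so the column
#' is always encodable.
#'
#' @param s a `genome_structure`.
#' @param f a feature table (see [feature_table()]).
#' @param mode `"count"`, `"coverage"` or `"score_mean"`.
#' @param out_column name for the new column; must not collide with an
#'   existing or reserved column.
#' @return a new `genome_structure` with the added column.
#' @export
bin_features <- function(s, f, mode = c("count", "coverage", "score_mean"),
                         out_column = mode) {
  stopifnot(is_structure(s))
  mode <- match.arg(mode)
  out_column <- out_column[1L]
  if (out_column %in% .RESERVED_COLUMNS)
    stop("'", out_column, "' is a reserved column name")
  if (out_column %in% names(s))
    stop("column '", out_column, "' already exists on the structure")
  if (mode == "score_mean" && all(is.na(f$score)))
    stop("score_mean requires a feature `score` column with values")

  n <- nrow(s)
  val <- numeric(n)
  missing_flag <- rep(TRUE, n)
  if (nrow(f)) {
    lev <- unique(c(s$chrom, f$chrom))
    gr_bins <- .as_granges(s$chrom, s$start, s$end, lev)
    gr_f <- .as_granges(f$chrom, f$start, f$end, lev)
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_f)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    if (length(qh)) missing_flag[unique(qh)] <- FALSE
    if (mode == "count") {
      val <- tabulate(qh, nbins = n)
    } else if (mode == "coverage") {
      if (length(qh)) {
        ## clip features to the bin, then union per bin
        clip_start <- pmax(f$start[sh], s$start[qh])
        clip_end <- pmin(f$end[sh], s$end[qh])
        ir <- IRanges::IRanges(start = clip_start + 1, end = clip_end)
        per_bin <- S4Vectors::split(ir, factor(qh, levels = seq_len(n)))
        covered <- sum(IRanges::width(IRanges::reduce(per_bin)))
        val <- as.numeric(covered) / (s$end - s$start)
      }
    } else {
      if (length(qh)) {
        sums <- tapply(f$score[sh], factor(qh, levels = seq_len(n)), sum)
        cnts <- tabulate(qh, nbins = n)
        val <- ifelse(cnts > 0, unname(ifelse(is.na(sums), 0, sums)) /
                        pmax(cnts, 1L), 0)
      }
    }
  }
  df <- as.data.frame(s)
  df[[out_column]] <- as.numeric(val)
  out <- new_structure(df, id = structure_id(s),
                       synthetic = attr(s, "synthetic_coords"))
  if (mode == "score_mean") attr(out, paste0(out_column, "_missing")) <- missing_flag
  out
}

#' Radial position of each bin
#'
#' Adds a column of Euclidean distances from each bin's point to the
#' centroid of all bin points -- the spatial statistic behind "gene-rich
#' regions sit nearer the center of the structure" style observations.
#'
#' @param s a `genome_structure` with >= 1 bin.
#' @param out_column name of the new column.
#' @return a new `genome_structure` with the added column.
#' @export
radial_position <- function(s, out_column = "radial_dist") {
  stopifnot(is_structure(s), nrow(s) >= 1L)
  if (out_column %in% names(s))
    stop("column '", out_column, "' already exists on the structure")
  cx <- mean(s$x); cy <- mean(s$y); cz <- mean(s$z)
  df <- as.data.frame(s)
  df[[out_column]] <- sqrt((s$x - cx)^2 + (s$y - cy)^2 + (s$z - cz)^2)
  new_structure(df, id = structure_id(s),
                synthetic = attr(s, "synthetic_coords"))
}
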