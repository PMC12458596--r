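#' @importFrom S4Vectors queryHits subjectHits
NULL

## Bin masks: logical per bin of a named structure, tagged with provenance.
new_mask <- function(values, s, provenance) {
  structure(as.logical(values), class = "bin_mask",
            structure_id = structure_id(s), n = n_bins(s),
            provenance = provenance)
}

#' @export
print.bin_mask <- function(x, ...) {
  cat(sprintf("<bin_mask> %d/%d bins of '%s'\n  query: %s\n",
              sum(x), length(x), attr(x, "structure_id"),
              attr(x, "provenance")))
  invisible(x)
}

#' Provenance of a bin mask
#' @param m a `bin_mask`.
#' @export
mask_provenance <- function(m) attr(m, "provenance")

## 0-based half-open -> 1-based closed IRanges; integer-safe for bp values.
## `levels` fixes a shared seqlevel set so overlap queries across objects
## built from different chromosome subsets stay silent.
.as_granges <- function(chrom, start, end, levels = unique(chrom)) {
  GenomicRanges::GRanges(factor(chrom, levels = levels),
                         IRanges::IRanges(start = start + 1, end = end))
}

#' Select bins by genomic range
#'
#' Marks every bin whose interval `[start, end)` has a non-empty half-open
#' intersection with any query interval. Touching endpoints (bin `[0,100)`
#' vs query `[100,200)`) do not overlap. Chromosome names are matched as
#' exact strings; a query chromosome absent from the structure contributes
#' nothing to the mask and raises a warning (not an error), so the same
#' query can be replayed across an ensemble of structures.
#'
#' @param s a `genome_structure`.
#' @param q a range set data frame (`chrom`, `start`, `end`) or a query
#'   string, see [parse_range_query()].
#' @param min_overlap minimum fraction of the bin that must be covered by a
#'   single query interval (default 0 = any overlap of >= 1 bp selects).
#' @return a `bin_mask`.
#' @export
select_by_ranges <- function(s, q, min_overlap = 0) {
  stopifnot(is_structure(s))
  prov <- if (is.character(q)) paste0("ranges(", paste(q, collapse = ","), ")")
          else "ranges(<data.frame>)"
  q <- as_rangeset(q)
  absent <- setdiff(unique(q$chrom), unique(s$chrom))
  if (length(absent))
    warning("query chromosome(s) not in structure: ",
            paste(absent, collapse = ", "))
  if (!nrow(s)) return(new_mask(logical(0), s, prov))
  ## cap whole-chromosome queries (end = Inf) at the structure's extent
  inf <- !is.finite(q$end)
  if (any(inf)) q$end[inf] <- max(s$end) + 1
  q <- q[q$chrom %in% s$chrom, , drop = FALSE]
  mask <- rep(FALSE, nrow(s))
  if (nrow(q)) {
    lev <- unique(c(s$chrom, q$chrom))
    gr_bins <- .as_granges(s$chrom, s$start, s$end, lev)
    gr_q <- .as_granges(q$chrom, q$start, q$end, lev)
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_q)
    if (min_overlap > 0) {
      ov <- IRanges::pintersect(gr_bins[queryHits(hits)],
                                gr_q[subjectHits(hits)])
      frac <- GenomicRanges::width(ov) /
        GenomicRanges::width(gr_bins[queryHits(hits)])
      hits <- hits[frac >= min_overlap]
    }
    mask[unique(queryHits(hits))] <- TRUE
  }
  new_mask(mask, s, prov)
}

#' Select bins within a spherical neighborhood
#'
#' Marks bins whose point lies within Euclidean distance `radius` of the
#' center (closed ball: distance exactly equal to the radius is included,
#' so partitions are deterministic). The center is either a spatial point
#' or a genomic locus; a locus resolves to the stored point of the bin
#' whose interval contains the position -- no interpolation.
#'
#' @param s a `genome_structure`.
#' @param center numeric length-3 point, or a genomic locus given as
#'   `"chrom:position"` string or `list(chrom = , pos = )`.
#' @param radius sphere radius in spatial units, > 0.
#' @return a `bin_mask`.
#' @export
select_sphere <- function(s, center, radius) {
  stopifnot(is_structure(s))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number")
  if (is.character(center) || is.list(center)) {
    locus <- if (is.character(center)) {
      parts <- strsplit(center, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        stop("genomic locus must be 'chrom:position', got '", center, "'")
      list(chrom = parts[1L], pos = .parse_bp(parts[2L], center, 1L))
    } else center
    hit <- which(s$chrom == locus$chrom & s$start <= locus$pos &
                   locus$pos < s$end)
    if (!length(hit))
      stop("locus ", locus$chrom, ":", format(locus$pos),
           " is not covered by any bin")
    center <- c(s$x[hit[1L]], s$y[hit[1L]], s$z[hit[1L]])
  }
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector or a genomic locus")
  d2 <- (s$x - center[1L])^2 + (s$y - center[2L])^2 + (s$z - center[3L])^2
  new_mask(d2 <= radius^2, s,
           sprintf("sphere(center=[%s], r=%s)",
                   paste(format(center), collapse = ", "), format(radius)))
}

#' Select bins on one side of a cutting plane
#'
#' The plane is `{p : unit_normal . p = offset}`. With signed value
#' `v = unit_normal . p - offset`, the positive side keeps `v >= 0` and the
#' negative side keeps `v < 0`, so the two sides always partition the
#' structure exactly (points on the plane go to the positive side).
#'
#' @param s a `genome_structure`.
#' @param normal plane normal, non-zero 3-vector (normalized internally).
#' @param offset signed distance of the plane from the origin along the unit
#'   normal (default 0).
#' @param keep_side `"positive"` or `"negative"`.
#' @return a `bin_mask`.
#' @export
select_cutting_plane <- function(s, normal, offset = 0,
                                 keep_side = c("positive", "negative")) {
  stopifnot(is_structure(s))
  keep_side <- match.arg(keep_side)
  normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal)))
    stop("normal must be a finite 3-vector")
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("plane normal must be non-zero")
  nhat <- normal / nrm
  v <- s$x * nhat[1L] + s$y * nhat[2L] + s$z * nhat[3L] - offset
  mask <- if (keep_side == "positive") v >= 0 else v < 0
  new_mask(mask, s,
           sprintf("plane(n=[%s], offset=%s, side=%s)",
                   paste(format(nhat, digits = 4), collapse = ", "),
                   format(offset), keep_side))
}

#' Combine or invert bin masks
#'
#' Elementwise boolean algebra over masks of the same structure; the
#' provenance records the expression. `and-not` keeps bins in `a` but not
#' `b`. The operators `&`, `|` and `!` are also defined for `bin_mask`.
#'
#' @param a,b `bin_mask` objects over the same structure.
#' @param op `"and"`, `"or"` or `"and-not"`.
#' @return a `bin_mask`.
#' @export
combine_masks <- function(a, b, op = c("and", "or", "and-not")) {
  op <- match.arg(op)
  .check_same(a, b)
  vals <- switch(op,
                 `and` = unclass(a) & unclass(b),
                 `or` = unclass(a) | unclass(b),
                 `and-not` = unclass(a) & !unclass(b))
  structure(vals, class = "bin_mask",
            structure_id = attr(a, "structure_id"), n = attr(a, "n"),
            provenance = sprintf("(%s %s %s)", mask_provenance(a), op,
                                 mask_provenance(b)))
}

#' @rdname combine_masks
#' @export
invert_mask <- function(a) {
  structure(!unclass(a), class = "bin_mask",
            structure_id = attr(a, "structure_id"), n = attr(a, "n"),
            provenance = sprintf("not(%s)", mask_provenance(a)))
}

.check_same <- function(a, b) {
  stopifnot(inherits(a, "bin_mask"), inherits(b, "bin_mask"))
  if (length(a) != length(b))
    stop("mask length mismatch: ", length(a), " vs ", length(b))
  if (!identical(attr(a, "structure_id"), attr(b, "structure_id")))
    stop("masks belong to different structures: '", attr(a, "structure_id"),
         "' vs '", attr(b, "structure_id"), "'")
  invisible(TRUE)
}

#' @export
`&.bin_mask` <- function(e1, e2) combine_masks(e1, e2, "and")

#' @export
`|.bin_mask` <- function(e1, e2) combine_masks(e1, e2, "or")

#' @export
`!.bin_mask` <- function(x) invert_mask(x)

#' Apply a mask, keeping only the selected bins
#'
#' Row order and extra columns are preserved; the resolution is re-inferred
#' from the surviving bins. An all-false mask yields a representable 0-bin
#' structure (which [validate_structure()] flags as empty).
#'
#' @param s a `genome_structure`.
#' @param m a `bin_mask` over `s`.
#' @return a `genome_structure`.
#' @export
apply_mask <- function(s, m) {
  stopifnot(is_structure(s), inherits(m, "bin_mask"))
  if (length(m) != nrow(s))
    stop("mask length ", length(m), " does not match structure with ",
         nrow(s), " bins")
  keep <- which(as.logical(m))
  new_structure(as.data.frame(s)[keep, , drop = FALSE],
                id = structure_id(s),
                synthetic = attr(s, "synthetic_coords"))
}
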