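#' @importFrom stats median
NULL

.RESERVED_COLUMNS <- c("chrom", "start", "end", "x", "y", "z")

#' Build a 3D genome structure from coordinates
#'
#' A structure is a columnar bin table: one row per bin, with a genomic
#' interval (`chrom`, `start`, `end`; 0-based half-open), a spatial position
#' (`x`, `y`, `z` in arbitrary model units) and any number of named extra data
#' columns. When no genomic columns are supplied the bins get synthetic
#' coordinates -- pseudo-chromosome `"chr?"` with 1-bp bins `[i, i+1)` -- so
#' that every downstream operation (selection, aggregation, encoding) is
#' total over bare point clouds.
#'
#' @param coords numeric matrix or data frame with n rows and 3 columns
#'   (x, y, z). All values must be finite.
#' @param chrom,start,end optional genomic columns, all three given or none.
#'   `start` inclusive, `end` exclusive, 0-based. Within each chromosome the
#'   rows must be sorted by `start` and pairwise non-overlapping.
#' @param extra optional named list / data frame of per-bin data columns.
#'   Names must be unique and must not clash with the six reserved column
#'   names (`chrom`, `start`, `end`, `x`, `y`, `z`).
#' @param id structure identifier string.
#' @return A `genome_structure` object: a data frame of bins with attributes
#'   `id`, `resolution` (modal bin width in bp; `NA` for an empty structure)
#'   and `synthetic_coords` (`TRUE` when genomic coordinates were fabricated).
#' @examples
#' s <- make_structure(matrix(rnorm(30), ncol = 3))
#' structure_resolution(s)  # 1 (synthetic 1-bp bins)
#' @export
make_structure <- function(coords, chrom = NULL, start = NULL, end = NULL,
                           extra = NULL, id = "structure") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("`coords` must have exactly 3 columns (x, y, z), got ", ncol(coords))
  n <- nrow(coords)
  if (n < 1L) stop("`coords` must have at least one row")
  storage.mode(coords) <- "double"
  bad <- which(!is.finite(coords[, 1L]) | !is.finite(coords[, 2L]) |
                 !is.finite(coords[, 3L]))
  if (length(bad))
    stop("non-finite coordinate at row ", bad[1L])

  given <- c(!is.null(chrom), !is.null(start), !is.null(end))
  if (any(given) && !all(given))
    stop("supply all of `chrom`, `start`, `end`, or none")
  synthetic <- !any(given)
  if (synthetic) {
    chrom <- rep("chr?", n)
    start <- as.numeric(seq_len(n) - 1L)
    end <- as.numeric(seq_len(n))
  } else {
    if (length(chrom) != n || length(start) != n || length(end) != n)
      stop("genomic columns must match `coords`: expected length ", n)
    chrom <- as.character(chrom)
    start <- as.numeric(start)
    end <- as.numeric(end)
  }

  bins <- data.frame(chrom = chrom, start = start, end = end,
                     x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                     stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE, optional = TRUE)
    if (nrow(extra) != n)
      stop("extra columns must have ", n, " rows, got ", nrow(extra))
    nm <- names(extra)
    if (is.null(nm) || any(!nzchar(nm))) stop("extra columns must be named")
    clash <- intersect(nm, .RESERVED_COLUMNS)
    if (length(clash))
      stop("extra column name(s) reserved: ", paste(clash, collapse = ", "))
    if (anyDuplicated(nm))
      stop("duplicate extra column names")
    bins <- cbind(bins, extra)
  }

  s <- new_structure(bins, id = id, synthetic = synthetic)
  v <- validate_structure(s)
  if (nrow(v))
    stop("invalid structure: ", v$message[1L],
         if (nrow(v) > 1L) paste0(" (and ", nrow(v) - 1L, " more violation(s))"))
  s
}

## Low-level constructor: no validation, recomputes resolution.
new_structure <- function(bins, id = "structure", synthetic = FALSE) {
  rownames(bins) <- NULL
  structure(bins,
            class = c("genome_structure", "data.frame"),
            id = as.character(id),
            synthetic_coords = isTRUE(synthetic),
            resolution = .modal_width(bins$end - bins$start))
}

## Modal bin width; ties broken toward the smallest width. NA when no bins.
.modal_width <- function(widths) {
  if (!length(widths)) return(NA_real_)
  tab <- table(widths)
  best <- names(tab)[tab == max(tab)]
  min(as.numeric(best))
}

#' Infer the genomic resolution of a structure
#'
#' The resolution is the modal bin width `end - start` over all bins, with
#' ties broken toward the smallest width (a deterministic, conservative
#' choice for downstream binning). An empty (0-bin) structure has no width
#' to measure and returns `NA`.
#'
#' @param s a `genome_structure`.
#' @return resolution in bp, or `NA` for an empty structure.
#' @export
infer_resolution <- function(s) {
  stopifnot(is_structure(s))
  .modal_width(s$end - s$start)
}

#' @rdname infer_resolution
#' @export
structure_resolution <- function(s) attr(s, "resolution")

#' @export
structure_id <- function(s) attr(s, "id")

#' Test for the genome_structure class
#' @param x object.
#' @export
is_structure <- function(x) inherits(x, "genome_structure")

#' Number of bins in a structure
#' @param s a `genome_structure`.
#' @export
n_bins <- function(s) nrow(s)

#' Validate structure invariants
#'
#' Checks every bin-table invariant and returns the violations found instead
#' of throwing: identical column lengths are guaranteed by the data-frame
#' representation, so the checks are `end > start` per row, per-chromosome
#' sortedness and pairwise non-overlap, finite spatial coordinates, and
#' extra-column naming. A 0-bin structure is flagged (the table must have at
#' least one row to describe anything).
#'
#' @param s a `genome_structure`.
#' @return data frame with columns `invariant`, `row`, `message`; zero rows
#'   when the structure is valid.
#' @export
validate_structure <- function(s) {
  stopifnot(is_structure(s))
  viol <- function(invariant, row, message)
    data.frame(invariant = invariant, row = row, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  if (nrow(s) < 1L)
    out[[length(out) + 1L]] <- viol("nonempty", NA_integer_,
                                    "structure has zero bins")
  bad <- which(!(s$end > s$start))
  for (i in bad)
    out[[length(out) + 1L]] <- viol("end>start", i,
      sprintf("row %d: end (%s) must exceed start (%s)", i,
              format(s$end[i]), format(s$start[i])))
  for (axis in c("x", "y", "z")) {
    bad <- which(!is.finite(s[[axis]]))
    for (i in bad)
      out[[length(out) + 1L]] <- viol("finite-xyz", i,
        sprintf("row %d: %s is not finite", i, axis))
  }
  ## sortedness + non-overlap within chromosome, in row order
  if (nrow(s) > 1L) {
    same <- s$chrom[-1L] == s$chrom[-nrow(s)]
    prev_end <- s$end[-nrow(s)]
    cur_start <- s$start[-1L]
    bad <- which(same & cur_start < prev_end)
    for (i in bad)
      out[[length(out) + 1L]] <- viol("non-overlap", i + 1L,
        sprintf("row %d: interval starts at %s before previous bin ends at %s",
                i + 1L, format(s$start[i + 1L]), format(prev_end[i])))
    ## a chromosome's rows must be contiguous (no interleaving)
    runs <- rle(s$chrom)$values
    if (anyDuplicated(runs))
      out[[length(out) + 1L]] <- viol("chrom-contiguous", NA_integer_,
        "rows of one chromosome are not contiguous")
  }
  if (length(out)) do.call(rbind, out)
  else viol(character(), integer(), character())
}

#' Rename chromosomes by explicit map
#'
#' Chromosome names are always matched as exact strings (no "chr1" vs "1"
#' aliasing, and haplotype-tagged names like "1(pat)" are kept verbatim);
#' this is the explicit conversion between naming conventions.
#'
#' @param s a `genome_structure`.
#' @param map named character vector, `c(old = "new", ...)`.
#' @export
rename_chroms <- function(s, map) {
  stopifnot(is_structure(s), is.character(map), !is.null(names(map)))
  hit <- s$chrom %in% names(map)
  s$chrom[hit] <- unname(map[s$chrom[hit]])
  new_structure(as.data.frame(s), id = structure_id(s),
                synthetic = attr(s, "synthetic_coords"))
}

#' Chromosomes present in a structure
#' @param s a `genome_structure`.
#' @export
chromosomes <- function(s) unique(s$chrom)

#' Names of the extra (non-reserved) data columns
#' @param s a `genome_structure`.
#' @export
extra_columns <- function(s) setdiff(names(s), .RESERVED_COLUMNS)

#' @export
print.genome_structure <- function(x, ...) {
  res <- structure_resolution(x)
  cat(sprintf("<genome_structure> id=%s  bins=%d  chromosomes=%d  resolution=%s\n",
              structure_id(x), nrow(x), length(chromosomes(x)),
              if (is.na(res)) "unknown" else format(res)))
  ex <- extra_columns(x)
  if (length(ex)) cat("  data columns:", paste(ex, collapse = ", "), "\n")
  if (nrow(x)) {
    cat("  first bins:\n")
    print.data.frame(utils::head(as.data.frame(x), 4L))
  }
  invisible(x)
}

#' Assemble a scene: structures paired with view configs
#'
#' A scene is an ordered, non-empty list of (structure, view config) pairs;
#' each config is validated against its structure at construction so every
#' encoded field is known to exist.
#'
#' @param structures list of `genome_structure` objects (or a single one).
#' @param configs list of `view_config` objects (or a single one, recycled).
#' @return a `genome_scene` object.
#' @export
genome_scene <- function(structures, configs) {
  if (is_structure(structures)) structures <- list(structures)
  if (inherits(configs, "view_config")) configs <- list(configs)
  if (!length(structures)) stop("a scene needs at least one structure")
  if (length(configs) == 1L) configs <- rep(configs, length(structures))
  if (length(configs) != length(structures))
    stop("need one view config per structure")
  for (i in seq_along(structures)) {
    stopifnot(is_structure(structures[[i]]))
    validate_config(configs[[i]], structures[[i]])
  }
  structure(list(structures = structures, configs = configs),
            class = "genome_scene")
}

#' @export
print.genome_scene <- function(x, ...) {
  cat(sprintf("<genome_scene> %d structure(s)\n", length(x$structures)))
  for (i in seq_along(x$structures))
    cat(sprintf("  [%d] %s: %d bins, mark=%s\n", i,
                structure_id(x$structures[[i]]), nrow(x$structures[[i]]),
                x$configs[[i]]$mark))
  invisible(x)
}
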