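#' Read a .3dg genome structure file
#'
#' The `.3dg` format (used for diploid single-cell genome models) is
#' tab-separated with five columns: chromosome, bin start position (bp),
#' x, y, z. Lines starting with `#` are comments. Bin ends are not stored,
#' so each bin becomes `[position, position + r)` where `r` is
#' `resolution_hint` when given, otherwise the minimum positive gap between
#' consecutive positions on each chromosome (robust to gaps in the model;
#' chromosomes with a single bin fall back to the smallest gap seen
#' file-wide, or 1 bp when no gap exists at all).
#'
#' @param path file path.
#' @param resolution_hint optional bin width in bp; overrides inference.
#' @param id structure id; defaults to the file name.
#' @return a `genome_structure`.
#' @export
read_3dg <- function(path, resolution_hint = NULL, id = NULL) {
  if (is.null(id)) id <- basename(path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty .3dg file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 5L))
    stop("line ", lineno[which(ncols < 5L)[1L]],
         ": expected >= 5 tab-separated columns")
  get <- function(j) vapply(fields, `[[`, character(1L), j)
  chrom <- get(1L)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(get(j)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("line ", lineno[bad[1L]], ": non-numeric ", what, " '",
           get(j)[bad[1L]], "'")
    v
  }
  pos <- num(2L, "position")
  x <- num(3L, "x"); y <- num(4L, "y"); z <- num(5L, "z")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (chrom, position) at line ", lineno[d], ": ", key[d])
  }
  ## sort rows per chromosome (chromosomes kept in first-appearance order)
  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; x <- x[ord]; y <- y[ord]; z <- z[ord]

  if (!is.null(resolution_hint)) {
    r <- rep(as.numeric(resolution_hint), length(pos))
  } else {
    gaps <- unlist(lapply(split(pos, chrom), function(p)
      if (length(p) > 1L) diff(sort(p)) else numeric()), use.names = FALSE)
    gaps <- gaps[gaps > 0]
    fallback <- if (length(gaps)) min(gaps) else 1
    r_by_chrom <- vapply(split(pos, chrom), function(p) {
      g <- diff(sort(p)); g <- g[g > 0]
      if (length(g)) min(g) else fallback
    }, numeric(1L))
    r <- unname(r_by_chrom[chrom])
  }
  make_structure(cbind(x, y, z), chrom = chrom, start = pos, end = pos + r,
                 id = id)
}

#' Write a structure in .3dg layout
#'
#' Tab-separated chromosome, bin start, x, y, z (bin ends are implied by the
#' resolution and are not stored, as in the format itself).
#'
#' @param s a `genome_structure`.
#' @param path output path.
#' @export
write_3dg <- function(s, path) {
  stopifnot(is_structure(s))
  lines <- paste(s$chrom, .fmt_num(s$start), .fmt_num(s$x), .fmt_num(s$y),
                 .fmt_num(s$z), sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a generic XYZ table (CSV/TSV) as a structure
#'
#' @param path file path; first row must be a header.
#' @param colmap named character vector mapping roles to column names; must
#'   cover at least `x`, `y`, `z`; `chrom`, `start`, `end` are optional
#'   (absent means synthetic 1-bp bins). Example:
#'   `c(x = "X", y = "Y", z = "Z", chrom = "chr")`.
#' @param delimiter field separator, default `","`.
#' @param id structure id; defaults to the file name.
#' @return a `genome_structure`; unmapped columns become extra data columns.
#' @export
read_xyz_table <- function(path, colmap = c(x = "x", y = "y", z = "z"),
                           delimiter = ",", id = NULL) {
  if (is.null(id)) id <- basename(path)
  colmap <- unlist(colmap)
  need <- c("x", "y", "z")
  if (!all(need %in% names(colmap)))
    stop("colmap must map at least x, y, z")
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  missing <- setdiff(unname(colmap), names(df))
  if (length(missing))
    stop("column(s) ", paste(sQuote(missing), collapse = ", "),
         " not found; available headers: ", paste(names(df), collapse = ", "))
  coords <- as.matrix(df[, colmap[c("x", "y", "z")]])
  genomic <- intersect(c("chrom", "start", "end"), names(colmap))
  extras <- df[, setdiff(names(df), unname(colmap)), drop = FALSE]
  if (!ncol(extras)) extras <- NULL
  if (length(genomic) == 3L) {
    make_structure(coords, chrom = df[[colmap[["chrom"]]]],
                   start = df[[colmap[["start"]]]],
                   end = df[[colmap[["end"]]]], extra = extras, id = id)
  } else {
    make_structure(coords, extra = extras, id = id)
  }
}

#' Read a BED file (BED3-BED6) as a feature table
#'
#' BED is already 0-based half-open, so coordinates are kept as-is.
#' `track` and `browser` lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return a feature table: data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` (`NA` where absent; strand one of `+ - .`).
#' @export
read_bed <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^(track|browser)\\b|^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) return(.empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("line ", lineno[which(ncols < 3L)[1L]], ": BED needs >= 3 columns")
  col <- function(j) vapply(fields, function(f)
    if (length(f) >= j) f[[j]] else NA_character_, character(1L))
  start <- suppressWarnings(as.numeric(col(2L)))
  end <- suppressWarnings(as.numeric(col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": non-numeric BED coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": start >= end (",
         start[bad[1L]], " >= ", end[bad[1L]], ")")
  name <- col(4L)
  score <- suppressWarnings(as.numeric(col(5L)))
  strand <- col(6L)
  strand[!is.na(strand) & !strand %in% c("+", "-", ".")] <- NA_character_
  feature_table(chrom = col(1L), start = start, end = end,
                name = name, score = score, strand = strand)
}

#' Read gene annotations from a GTF file
#'
#' GTF coordinates are 1-based inclusive; they are converted to the internal
#' 0-based half-open convention as `[start - 1, end)`. GFF3 files are not
#' supported (the attribute syntax differs; they are not silently misparsed
#' because `attribute_key "value"` pairs will simply not match).
#'
#' @param path file path.
#' @param feature_filter optional feature type (column 3), e.g. `"gene"`;
#'   rows with other types are dropped.
#' @param attribute_key attribute whose value becomes the feature `name`
#'   (default `"gene_id"`). A malformed attribute field yields an empty name
#'   with a warning, never an error.
#' @return a feature table (see [read_bed()]).
#' @export
read_gtf <- function(path, feature_filter = NULL, attribute_key = "gene_id") {
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) return(.empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 9L))
    stop("line ", lineno[which(ncols < 9L)[1L]], ": GTF needs 9 columns")
  col <- function(j) vapply(fields, `[[`, character(1L), j)
  type <- col(3L)
  sel <- if (is.null(feature_filter)) rep(TRUE, length(type))
         else type == feature_filter
  if (!any(sel)) return(.empty_features())
  start1 <- suppressWarnings(as.numeric(col(4L)[sel]))
  end1 <- suppressWarnings(as.numeric(col(5L)[sel]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("line ", lineno[sel][bad[1L]], ": non-numeric GTF coordinates")
  score <- suppressWarnings(as.numeric(col(6L)[sel]))
  strand <- col(7L)[sel]
  strand[!strand %in% c("+", "-", ".")] <- NA_character_
  attrs <- col(9L)[sel]
  pat <- paste0(attribute_key, "\\s+\"([^\"]*)\"")
  m <- regmatches(attrs, regexec(pat, attrs))
  name <- vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
                 character(1L))
  if (anyNA(name))
    warning(sum(is.na(name)), " feature(s) without parseable '",
            attribute_key, "' attribute; names left empty")
  feature_table(chrom = col(1L)[sel], start = start1 - 1, end = end1,
                name = name, score = score, strand = strand)
}

#' Construct a feature table
#'
#' @param chrom,start,end genomic intervals, 0-based half-open.
#' @param name,score,strand optional metadata (recycled `NA` when absent).
#' @export
feature_table <- function(chrom, start, end, name = NA_character_,
                          score = NA_real_, strand = NA_character_) {
  n <- length(chrom)
  f <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), name = rep_len(as.character(name), n),
                  score = rep_len(as.numeric(score), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  bad <- which(!(f$end > f$start))
  if (length(bad)) stop("feature row ", bad[1L], ": end must exceed start")
  class(f) <- c("feature_table", "data.frame")
  f
}

.empty_features <- function()
  feature_table(character(), numeric(), numeric())

## Deterministic numeric formatting for TSV: '.' decimal, 12 significant
## digits (round-trips real coordinates well within 1e-9 relative), plain
## notation for magnitudes below 1e6.
.fmt_num <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) return("NA")
    if (x == floor(x) && abs(x) < 1e15) return(sprintf("%.0f", x))
    format(x, digits = 12, scientific = abs(x) >= 1e6, trim = TRUE)
  }, character(1L))
}

#' Write a structure to disk
#'
#' `arrow` writes the bin table as an Arrow IPC (Feather) file -- the
#' lossless interchange form; column order chrom, start, end, x, y, z, then
#' extras. `tsv` writes a plain header-ed TSV with 9 significant digits
#' (value-equal on read-back to 1e-9 relative).
#'
#' @param s a `genome_structure`.
#' @param path output path.
#' @param format `"tsv"` or `"arrow"`.
#' @export
write_structure <- function(s, path, format = c("tsv", "arrow")) {
  stopifnot(is_structure(s))
  format <- match.arg(format)
  df <- as.data.frame(s)[, c(.RESERVED_COLUMNS, extra_columns(s))]
  if (format == "arrow") {
    arrow::write_feather(df, path)
  } else {
    num <- vapply(df, is.numeric, logical(1L))
    txt <- df
    txt[num] <- lapply(df[num], .fmt_num)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(txt), collapse = "\t"), con, sep = "\n")
    writeLines(do.call(paste, c(unname(txt), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read back a structure written by [write_structure()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"arrow"`.
#' @param id structure id; defaults to the file name.
#' @export
read_structure <- function(path, format = c("tsv", "arrow"), id = NULL) {
  format <- match.arg(format)
  if (is.null(id)) id <- basename(path)
  df <- if (format == "arrow") as.data.frame(arrow::read_feather(path))
        else utils::read.table(path, sep = "\t", header = TRUE,
                               check.names = FALSE, stringsAsFactors = FALSE,
                               comment.char = "")
  need <- .RESERVED_COLUMNS
  if (!all(need %in% names(df)))
    stop("not a structure table; missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  extras <- df[, setdiff(names(df), need), drop = FALSE]
  if (!ncol(extras)) extras <- NULL
  make_structure(as.matrix(df[, c("x", "y", "z")]), chrom = df$chrom,
                 start = df$start, end = df$end, extra = extras, id = id)
}

#' Write a feature table as GTF
#'
#' Internal 0-based half-open intervals are printed as 1-based inclusive
#' (`start + 1`, `end`), the inverse of [read_gtf()].
#'
#' @param f a feature table.
#' @param path output path.
#' @param feature feature type for column 3 (default `"gene"`).
#' @param source source tag for column 2.
#' @export
write_gtf <- function(f, path, feature = "gene", source = "chromoscene") {
  name <- ifelse(is.na(f$name), paste0("feature_", seq_len(nrow(f))), f$name)
  lines <- paste(f$chrom, source, feature,
                 .fmt_num(f$start + 1), .fmt_num(f$end),
                 ifelse(is.na(f$score), ".", .fmt_num(f$score)),
                 ifelse(is.na(f$strand), ".", f$strand), ".",
                 sprintf("gene_id \"%s\";", name), sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
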