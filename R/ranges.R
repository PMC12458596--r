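#' Parse a genomic range query string
#'
#' Grammar: `"chrom[:start-end]"`, with multiple queries separated by commas.
#' A bare chromosome name selects the whole chromosome. Numbers may carry
#' digit-grouping commas (`1,000,000`) or a `k`/`M`/`G` multiplier suffix
#' (`2M` = 2000000); decimals combine with suffixes (`1.5M`). A comma
#' followed by exactly three digits and then a non-digit is treated as digit
#' grouping; every other comma separates queries.
#'
#' @param q query string, e.g. `"chr1:0-2M, chr2, chrX:1,000-5,000"`.
#' @return a range-set data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open; whole-chromosome queries have `start = 0`,
#'   `end = Inf`).
#' @export
parse_range_query <- function(q) {
  stopifnot(is.character(q), length(q) == 1L)
  tokens <- strsplit(q, ",(?!\\d{3}(\\D|$))", perl = TRUE)[[1L]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop("range query syntax error at position 1: empty query")
  rows <- lapply(seq_along(tokens), function(i) {
    tok <- tokens[[i]]
    if (!grepl(":", tok, fixed = TRUE))
      return(data.frame(chrom = tok, start = 0, end = Inf,
                        stringsAsFactors = FALSE))
    parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]))
      stop("range query syntax error in token ", i, " ('", tok,
           "'): expected chrom:start-end")
    span <- strsplit(parts[2L], "-", fixed = TRUE)[[1L]]
    if (length(span) != 2L)
      stop("range query syntax error in token ", i, " ('", tok,
           "'): expected start-end after ':'")
    start <- .parse_bp(span[1L], tok, i)
    end <- .parse_bp(span[2L], tok, i)
    if (end <= start)
      stop("range query error in token ", i, " ('", tok,
           "'): end must exceed start")
    data.frame(chrom = parts[1L], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.parse_bp <- function(txt, tok, i) {
  txt <- gsub(",", "", trimws(txt), fixed = TRUE)
  m <- regmatches(txt, regexec("^([0-9]*\\.?[0-9]+)([kKmMgG]?)$", txt))[[1L]]
  if (!length(m))
    stop("range query syntax error in token ", i, " ('", tok,
         "'): cannot parse number '", txt, "'")
  mult <- switch(m[3L], k = , K = 1e3, m = , M = 1e6, g = , G = 1e9, 1)
  as.numeric(m[2L]) * mult
}

#' Coerce to a range set
#'
#' A range set is a data frame of genomic intervals (`chrom`, `start`, `end`;
#' 0-based half-open) used as a selection query. Rows may be unsorted and
#' may overlap. Accepts a query string (see [parse_range_query()]) or any
#' data frame with the three columns.
#'
#' @param x query string or data frame.
#' @export
as_rangeset <- function(x) {
  if (is.character(x)) return(parse_range_query(paste(x, collapse = ",")))
  x <- as.data.frame(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("a range set needs columns chrom, start, end; got: ",
         paste(names(x), collapse = ", "))
  x <- x[need]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!(x$end > x$start))
  if (length(bad))
    stop("range set row ", bad[1L], ": end must exceed start")
  x
}
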