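## Built-in color scales. Stops are embedded as constants so interpolation
## is bit-reproducible; RGB rows in 0..255.
.COLORMAPS <- list(
  "viridis-8" = matrix(c(
    0x44, 0x01, 0x54,
    0x46, 0x30, 0x7E,
    0x36, 0x5C, 0x8D,
    0x27, 0x7F, 0x8E,
    0x1F, 0xA1, 0x87,
    0x4A, 0xC1, 0x6D,
    0xA0, 0xDA, 0x39,
    0xFD, 0xE7, 0x25), ncol = 3, byrow = TRUE),
  "greys-2" = matrix(c(
    0x00, 0x00, 0x00,
    0xFF, 0xFF, 0xFF), ncol = 3, byrow = TRUE)
)

## 12-color categorical palette (colorblind-leaning tableau-style hues).
.CATEGORY12 <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
  "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78")

#' Built-in colormaps and palettes
#'
#' `colormap_stops()` returns the RGB stop matrix (rows = stops, columns =
#' R, G, B in 0..255) of a built-in continuous colormap, or passes through a
#' user-supplied stop matrix / vector of colors. `category_palette()`
#' returns the built-in 12-color categorical palette.
#'
#' @param x colormap name (`"viridis-8"`, `"greys-2"`), a vector of >= 2
#'   colors, or an n x 3 RGB matrix.
#' @export
colormap_stops <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L || nrow(x) < 2L)
      stop("a colormap matrix needs >= 2 rows and 3 columns (RGB)")
    return(x)
  }
  if (is.character(x) && length(x) == 1L && x %in% names(.COLORMAPS))
    return(.COLORMAPS[[x]])
  if (is.character(x) && length(x) >= 2L)
    return(t(grDevices::col2rgb(x)))
  stop("unknown colormap: ", paste(x, collapse = ", "),
       " (built-in: ", paste(names(.COLORMAPS), collapse = ", "), ")")
}

#' @rdname colormap_stops
#' @export
category_palette <- function() .CATEGORY12

#' @rdname colormap_stops
#' @export
builtin_colormaps <- function() names(.COLORMAPS)

#' Describe a data-driven visual channel
#'
#' A field encoding maps a per-bin field to a visual channel. The field is
#' a data column of the structure or one of two pseudo-fields:
#' `"coordinate"` (the per-chromosome bin index, 1-based) and `"chrom"`
#' (the chromosome label, categorical). Continuous encodings linearly map
#' the domain onto a colormap or a radius range, clamping out-of-domain
#' values; categorical encodings cycle a palette over categories in order
#' of first appearance.
#'
#' @param field column name, `"coordinate"`, or `"chrom"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param colormap for continuous color: colormap name, colors or RGB stop
#'   matrix (see [colormap_stops()]).
#' @param range for scale: `c(rmin, rmax)` radii, `0 < rmin <= rmax`.
#' @param domain optional `c(lo, hi)`, `lo < hi`; defaults to the observed
#'   min/max of the field at resolve time.
#' @param palette for categorical color: vector of >= 1 colors (default the
#'   built-in 12-color palette).
#' @export
field_encoding <- function(field, kind = c("continuous", "categorical"),
                           colormap = "viridis-8", range = NULL,
                           domain = NULL, palette = NULL) {
  kind <- match.arg(kind)
  if (!is.character(field) || length(field) != 1L)
    stop("`field` must be a single column name")
  if (!is.null(domain)) {
    if (length(domain) != 2L || !(domain[1L] < domain[2L]))
      stop("domain must be c(lo, hi) with lo < hi")
  }
  if (!is.null(range)) {
    if (length(range) != 2L || range[1L] > range[2L])
      stop("range must be c(rmin, rmax) with rmin <= rmax")
  }
  if (kind == "categorical") {
    if (is.null(palette)) palette <- .CATEGORY12
    if (!length(palette)) stop("categorical encoding needs >= 1 palette color")
  }
  structure(list(field = field, kind = kind, colormap = colormap,
                 range = range, domain = domain, palette = palette),
            class = "field_encoding")
}

#' Declare how a structure is drawn
#'
#' The view config is the declarative encoding spec: which mark represents
#' a bin, and how the color and scale channels are driven -- either by a
#' constant (a CSS-style color string; a positive radius) or by a
#' [field_encoding()]. `links = TRUE` connects genomically consecutive bins
#' of the same chromosome (bins whose intervals touch end-to-start) with
#' tube segments.
#'
#' @param mark `"sphere"` or `"box"` (a box's edge length is twice the
#'   radius, matching the sphere's diameter).
#' @param color constant color string or a [field_encoding()].
#' @param scale constant radius (> 0), a [field_encoding()] with a `range`,
#'   or `NULL` to use [default_radius()] of the structure.
#' @param links logical.
#' @export
view_config <- function(mark = c("sphere", "box"), color = "#808080",
                        scale = NULL, links = FALSE) {
  mark <- match.arg(mark)
  if (is.character(color)) .parse_color(color)  # fail fast on bad constants
  else if (!inherits(color, "field_encoding"))
    stop("`color` must be a color string or a field_encoding")
  if (!is.null(scale) && !inherits(scale, "field_encoding")) {
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop("constant `scale` must be a single positive number")
  }
  structure(list(mark = mark, color = color, scale = scale,
                 links = isTRUE(links)),
            class = "view_config")
}

#' @export
print.view_config <- function(x, ...) {
  chan <- function(v) {
    if (is.null(v)) "default"
    else if (inherits(v, "field_encoding"))
      sprintf("field '%s' (%s)", v$field, v$kind)
    else format(v)
  }
  cat(sprintf("<view_config> mark=%s  color=%s  scale=%s  links=%s\n",
              x$mark, chan(x$color), chan(x$scale), x$links))
  invisible(x)
}

## CSS-ish color string -> length-4 rgba in 0..255. Accepts #rgb, #rrggbb,
## #rrggbbaa and R/CSS color names.
.parse_color <- function(col) {
  if (!is.character(col) || length(col) != 1L)
    stop("a constant color must be a single string")
  if (grepl("^#[0-9a-fA-F]{3}$", col)) {
    d <- strsplit(substring(col, 2L), "")[[1L]]
    col <- paste0("#", d[1L], d[1L], d[2L], d[2L], d[3L], d[3L])
  }
  rgba <- tryCatch(grDevices::col2rgb(col, alpha = TRUE)[, 1L],
                   error = function(e) stop("unparseable color: '", col, "'"))
  unname(rgba)
}

#' Validate a view config against a structure
#'
#' Checks that every encoded field exists on the structure (or is a
#' pseudo-field), constants parse, and scale encodings carry a usable
#' positive radius range. Throws on the first problem; returns the config
#' invisibly when valid.
#'
#' @param vc a `view_config`.
#' @param s a `genome_structure`.
#' @export
validate_config <- function(vc, s) {
  stopifnot(inherits(vc, "view_config"), is_structure(s))
  known <- c(extra_columns(s), "coordinate", "chrom")
  check_field <- function(enc, channel) {
    if (!enc$field %in% known)
      stop("view config ", channel, " references unknown field '", enc$field,
           "'; available: ", paste(known, collapse = ", "))
  }
  if (inherits(vc$color, "field_encoding")) check_field(vc$color, "color")
  if (inherits(vc$scale, "field_encoding")) {
    check_field(vc$scale, "scale")
    if (is.null(vc$scale$range))
      stop("a scale field_encoding needs a radius `range = c(rmin, rmax)`")
    if (vc$scale$range[1L] <= 0)
      stop("scale range: rmin must be positive (radii must be positive)")
  }
  invisible(vc)
}

## clamp to [0, 1]
.unit_clamp <- function(t) pmin(pmax(t, 0), 1)

## round half away from zero to integer (values here are >= 0)
.round_half_up <- function(x) floor(x + 0.5)

.field_domain <- function(values, enc) {
  if (!is.null(enc$domain)) return(as.numeric(enc$domain))
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    warning("degenerate domain for field '", enc$field,
            "' (all values equal); mapping all bins to the scale origin")
    return(NULL)
  }
  rng
}

#' Map continuous values to colors
#'
#' Values are normalized by the domain, `t = clamp((v - lo)/(hi - lo), 0, 1)`,
#' and colors are piecewise-linearly interpolated between equally spaced
#' colormap stops in plain RGB space; channels round half-up to integers,
#' alpha is 255. With a degenerate domain (all values equal and no explicit
#' domain) every value maps to the first stop, with a warning.
#'
#' @param values numeric vector.
#' @param enc a continuous [field_encoding()].
#' @return integer matrix, one row per value, columns r, g, b, a in 0..255.
#' @export
map_color <- function(values, enc) {
  stopifnot(inherits(enc, "field_encoding"), enc$kind == "continuous")
  stops <- colormap_stops(enc$colormap)
  dom <- .field_domain(values, enc)
  if (is.null(dom)) {
    rgba <- matrix(rep(c(stops[1L, ], 255), each = length(values)),
                   ncol = 4L)
    colnames(rgba) <- c("r", "g", "b", "a")
    return(rgba)
  }
  t <- .unit_clamp((values - dom[1L]) / (dom[2L] - dom[1L]))
  k <- nrow(stops)
  pos <- t * (k - 1)
  i <- pmin(floor(pos), k - 2)          # lower stop index, 0-based
  frac <- pos - i
  lower <- stops[i + 1L, , drop = FALSE]
  upper <- stops[i + 2L, , drop = FALSE]
  rgb <- .round_half_up(lower + frac * (upper - lower))
  rgba <- cbind(rgb, 255)
  storage.mode(rgba) <- "integer"
  colnames(rgba) <- c("r", "g", "b", "a")
  rgba
}

#' Map continuous values to mark radii
#'
#' `radius = rmin + clamp((v - lo)/(hi - lo), 0, 1) * (rmax - rmin)`.
#' A degenerate domain maps everything to `rmin`.
#'
#' @param values numeric vector.
#' @param enc a continuous [field_encoding()] with a `range`.
#' @return numeric vector of radii.
#' @export
map_scale <- function(values, enc) {
  stopifnot(inherits(enc, "field_encoding"))
  if (is.null(enc$range)) stop("scale encoding needs `range = c(rmin, rmax)`")
  rmin <- enc$range[1L]; rmax <- enc$range[2L]
  if (rmin <= 0) stop("rmin must be positive (radii must be positive)")
  dom <- .field_domain(values, enc)
  if (is.null(dom)) return(rep(rmin, length(values)))
  t <- .unit_clamp((values - dom[1L]) / (dom[2L] - dom[1L]))
  rmin + t * (rmax - rmin)
}

#' Map categorical labels to palette colors
#'
#' Categories are ordered by first appearance in `values`; the palette is
#' cycled modularly when there are more categories than colors.
#'
#' @param values vector of labels.
#' @param palette vector of >= 1 colors.
#' @return integer rgba matrix as in [map_color()].
#' @export
map_categorical <- function(values, palette = category_palette()) {
  if (!length(palette)) stop("palette must contain at least one color")
  idx <- match(values, unique(values))
  cols <- t(grDevices::col2rgb(palette, alpha = TRUE))
  rgba <- cols[((idx - 1L) %% nrow(cols)) + 1L, , drop = FALSE]
  storage.mode(rgba) <- "integer"
  colnames(rgba) <- c("r", "g", "b", "a")
  rgba
}

#' Default mark radius for a structure
#'
#' Half the median Euclidean distance between genomically consecutive bins
#' on the same chromosome -- marks of this size roughly touch along the
#' fiber without engulfing it. Falls back to 1.0 when the structure has no
#' consecutive pair (e.g. a single bin).
#'
#' @param s a `genome_structure`.
#' @export
default_radius <- function(s) {
  stopifnot(is_structure(s))
  if (nrow(s) < 2L) return(1.0)
  same <- s$chrom[-1L] == s$chrom[-nrow(s)]
  if (!any(same)) return(1.0)
  dx <- diff(s$x); dy <- diff(s$y); dz <- diff(s$z)
  d <- sqrt(dx^2 + dy^2 + dz^2)[same]
  0.5 * stats::median(d)
}

.pseudo_field <- function(s, field) {
  switch(field,
         coordinate = as.numeric(stats::ave(seq_len(nrow(s)), s$chrom,
                                            FUN = seq_along)),
         chrom = s$chrom,
         s[[field]])
}

#' Resolve a view config against a structure
#'
#' Materializes the declarative encoding into concrete per-bin visual
#' attributes: position, mark type, radius, and rgba color. Constants
#' broadcast to every bin; field encodings are mapped by [map_color()],
#' [map_scale()] or [map_categorical()]. With `links = TRUE`, a link
#' segment is emitted between each pair of bins adjacent in genomic order
#' on the same chromosome (`end[i] == start[i+1]`); gaps and chromosome
#' boundaries break the chain.
#'
#' @param s a `genome_structure`.
#' @param vc a `view_config`.
#' @return a `resolved_scene`: list with `marks` (data frame: x, y, z, mark,
#'   radius, r, g, b, a, structure), `links` (data frame of segment
#'   endpoints x0..z1 plus bin indices), and `default_radius`.
#' @export
resolve <- function(s, vc = view_config()) {
  validate_config(vc, s)
  n <- nrow(s)
  if (inherits(vc$color, "field_encoding")) {
    vals <- .pseudo_field(s, vc$color$field)
    rgba <- if (vc$color$kind == "categorical")
      map_categorical(vals, vc$color$palette %||% category_palette())
    else map_color(as.numeric(vals), vc$color)
  } else {
    rgba <- matrix(rep(.parse_color(vc$color), each = n), ncol = 4L)
  }
  if (inherits(vc$scale, "field_encoding")) {
    radius <- map_scale(as.numeric(.pseudo_field(s, vc$scale$field)), vc$scale)
  } else {
    radius <- rep(if (is.null(vc$scale)) default_radius(s) else vc$scale, n)
  }
  marks <- data.frame(x = s$x, y = s$y, z = s$z,
                      mark = rep(vc$mark, n), radius = radius,
                      r = as.integer(rgba[, 1L]), g = as.integer(rgba[, 2L]),
                      b = as.integer(rgba[, 3L]), a = as.integer(rgba[, 4L]),
                      structure = rep(structure_id(s), n),
                      stringsAsFactors = FALSE)
  links <- if (vc$links && n > 1L) {
    i <- which(s$chrom[-n] == s$chrom[-1L] & s$end[-n] == s$start[-1L])
    data.frame(from = i, to = i + 1L,
               x0 = s$x[i], y0 = s$y[i], z0 = s$z[i],
               x1 = s$x[i + 1L], y1 = s$y[i + 1L], z1 = s$z[i + 1L])
  } else {
    data.frame(from = integer(), to = integer(),
               x0 = numeric(), y0 = numeric(), z0 = numeric(),
               x1 = numeric(), y1 = numeric(), z1 = numeric())
  }
  structure(list(marks = marks, links = links,
                 default_radius = default_radius(s)),
            class = "resolved_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve every structure of a scene
#'
#' @param scene a [genome_scene()].
#' @return one `resolved_scene` with the marks of all structures stacked in
#'   scene order (`structure` column tells them apart) and link indices
#'   offset accordingly.
#' @export
resolve_scene <- function(scene) {
  stopifnot(inherits(scene, "genome_scene"))
  parts <- Map(resolve, scene$structures, scene$configs)
  offset <- 0L
  marks <- list(); links <- list()
  for (p in parts) {
    marks[[length(marks) + 1L]] <- p$marks
    l <- p$links
    l$from <- l$from + offset
    l$to <- l$to + offset
    links[[length(links) + 1L]] <- l
    offset <- offset + nrow(p$marks)
  }
  structure(list(marks = do.call(rbind, marks), links = do.call(rbind, links),
                 default_radius = parts[[1L]]$default_radius),
            class = "resolved_scene")
}

#' @export
print.resolved_scene <- function(x, ...) {
  cat(sprintf("<resolved_scene> %d mark(s), %d link(s), default radius %.4g\n",
              nrow(x$marks), nrow(x$links), x$default_radius))
  invisible(x)
}

#' Read / write view configs as JSON
#'
#' The JSON schema mirrors [view_config()]: top-level keys `mark`, `color`,
#' `scale`, `links`; a channel is a constant or an object with keys `field`,
#' `kind`, `colormap`, `range`, `domain`, `palette`. Unknown keys are
#' rejected (strict schema) so typos in channel names fail loudly.
#'
#' @param path JSON file path (or a JSON string for `read_view_config`).
#' @export
read_view_config <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n")
         else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  allowed <- c("mark", "color", "scale", "links")
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("unknown view config key(s): ", paste(extra, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  parse_channel <- function(ch, what) {
    if (is.null(ch) || !is.list(ch)) return(ch)
    eallowed <- c("field", "kind", "colormap", "range", "domain", "palette")
    eextra <- setdiff(names(ch), eallowed)
    if (length(eextra))
      stop("unknown ", what, " encoding key(s): ",
           paste(eextra, collapse = ", "))
    field_encoding(field = ch$field,
                   kind = ch$kind %||% "continuous",
                   colormap = ch$colormap %||% "viridis-8",
                   range = ch$range, domain = ch$domain,
                   palette = ch$palette)
  }
  view_config(mark = obj$mark %||% "sphere",
              color = parse_channel(obj$color, "color") %||% "#808080",
              scale = parse_channel(obj$scale, "scale"),
              links = isTRUE(obj$links))
}

#' @rdname read_view_config
#' @param vc a `view_config`.
#' @export
write_view_config <- function(vc, path) {
  stopifnot(inherits(vc, "view_config"))
  enc <- function(ch) {
    if (inherits(ch, "field_encoding")) {
      out <- ch[!vapply(ch, is.null, logical(1L))]
      if (is.matrix(out$colormap)) out$colormap <- NULL
      unclass(out)
    } else ch
  }
  obj <- list(mark = vc$mark, color = enc(vc$color), scale = enc(vc$scale),
              links = vc$links)
  obj <- obj[!vapply(obj, is.null, logical(1L))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
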