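#' Render a static raster preview of a resolved scene
#'
#' Orthographic projection along a view direction: marks are drawn as
#' filled discs of their projected radius, back-to-front by projected depth
#' (painter's algorithm), links as straight lines underneath the marks.
#' Output is deterministic for fixed inputs -- the same scene and view
#' always produce a byte-identical PNG.
#'
#' @param scene a non-empty `resolved_scene`.
#' @param path output PNG path.
#' @param view viewing direction (non-zero 3-vector); the camera looks along
#'   it.
#' @param size image size in pixels (square), default 400.
#' @param background background color, default white.
#' @return the path, invisibly.
#' @export
render_preview <- function(scene, path, view = c(1, 1, 1), size = 400L,
                           background = "#FFFFFF") {
  stopifnot(inherits(scene, "resolved_scene"))
  m <- scene$marks
  if (!nrow(m)) stop("cannot render an empty scene")
  view <- as.numeric(view)
  if (length(view) != 3L || !all(is.finite(view)) || all(view == 0))
    stop("view must be a non-zero 3-vector")
  w <- view / sqrt(sum(view^2))
  ref <- if (abs(w[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- .cross3(ref, w); u <- u / sqrt(sum(u^2))
  v <- .cross3(w, u)

  px <- m$x * u[1L] + m$y * u[2L] + m$z * u[3L]
  py <- m$x * v[1L] + m$y * v[2L] + m$z * v[3L]
  depth <- m$x * w[1L] + m$y * w[2L] + m$z * w[3L]

  rad <- m$radius
  lim <- c(min(px - rad), max(px + rad), min(py - rad), max(py + rad))
  span <- max(lim[2L] - lim[1L], lim[4L] - lim[3L], .Machine$double.eps)
  margin <- 0.02 * span
  scale <- (size - 1L) / (span + 2 * margin)
  to_col <- function(p) (p - lim[1L] + margin) * scale + 1
  to_row <- function(p) size - (p - lim[3L] + margin) * scale

  bg <- .parse_color(background) / 255
  img <- array(0, dim = c(size, size, 4L))
  img[, , 1L] <- bg[1L]; img[, , 2L] <- bg[2L]
  img[, , 3L] <- bg[3L]; img[, , 4L] <- bg[4L]

  ## links first (underneath), then marks far-to-near
  if (nrow(scene$links)) {
    for (i in seq_len(nrow(scene$links))) {
      l <- scene$links[i, ]
      p0 <- c(l$x0 * u[1L] + l$y0 * u[2L] + l$z0 * u[3L],
              l$x0 * v[1L] + l$y0 * v[2L] + l$z0 * v[3L])
      p1 <- c(l$x1 * u[1L] + l$y1 * u[2L] + l$z1 * u[3L],
              l$x1 * v[1L] + l$y1 * v[2L] + l$z1 * v[3L])
      steps <- max(2L, ceiling(max(abs(to_col(p1[1L]) - to_col(p0[1L])),
                                   abs(to_row(p1[2L]) - to_row(p0[2L])))) + 1L)
      t <- seq(0, 1, length.out = steps)
      cc <- round(to_col(p0[1L] + t * (p1[1L] - p0[1L])))
      rr <- round(to_row(p0[2L] + t * (p1[2L] - p0[2L])))
      ok <- cc >= 1L & cc <= size & rr >= 1L & rr <= size
      col <- c(m$r[l$from], m$g[l$from], m$b[l$from]) / 255
      for (k in which(ok)) {
        img[rr[k], cc[k], 1L] <- col[1L]
        img[rr[k], cc[k], 2L] <- col[2L]
        img[rr[k], cc[k], 3L] <- col[3L]
        img[rr[k], cc[k], 4L] <- 1
      }
    }
  }

  ord <- order(depth, decreasing = TRUE)  # far first, near painted last
  for (i in ord) {
    cc <- to_col(px[i]); rr <- to_row(py[i])
    rpix <- rad[i] * scale
    c0 <- max(1L, floor(cc - rpix)); c1 <- min(size, ceiling(cc + rpix))
    r0 <- max(1L, floor(rr - rpix)); r1 <- min(size, ceiling(rr + rpix))
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    dist2 <- outer((rows - rr)^2, (cols - cc)^2, `+`)
    inside <- dist2 <= rpix^2
    if (!any(inside)) next
    col <- c(m$r[i], m$g[i], m$b[i], m$a[i]) / 255
    for (ch in 1:4) {
      plane <- img[rows, cols, ch]
      plane[inside] <- col[ch]
      img[rows, cols, ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
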