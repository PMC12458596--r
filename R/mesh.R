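## Unit icosahedron: 12 vertices on the unit sphere, 20 faces.
.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  p,  0,   1,  p,  0,  -1, -p,  0,   1, -p,  0,
     0, -1,  p,   0,  1,  p,   0, -1, -p,   0,  1, -p,
     p,  0, -1,   p,  0,  1,  -p,  0, -1,  -p,  0,  1),
    ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6,   1, 6, 2,    1, 2, 8,    1, 8, 11,   1, 11, 12,
    2, 6, 10,   6, 12, 5,   12, 11, 3,  11, 8, 7,   8, 2, 9,
    4, 10, 5,   4, 5, 3,    4, 3, 7,    4, 7, 9,    4, 9, 10,
    5, 10, 6,   3, 5, 12,   7, 3, 11,   9, 7, 8,    10, 9, 2),
    ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

## One midpoint subdivision step, vertices re-projected to the unit sphere.
## Midpoints are shared between faces so vertex counts follow 10*4^s + 2.
.subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    m <- (verts[[a]] + verts[[b]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    idx <- length(verts)
    cache[[key]] <- idx
    idx
  }
  out <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    out[4L * i - 3L, ] <- c(a, ab, ca)
    out[4L * i - 2L, ] <- c(b, bc, ab)
    out[4L * i - 1L, ] <- c(c, ca, bc)
    out[4L * i, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, verts), faces = out)
}

## Unit icosphere at a given subdivision level (memoized per session).
.icosphere_cache <- new.env(parent = emptyenv())
.icosphere <- function(subdiv) {
  key <- as.character(subdiv)
  hit <- .icosphere_cache[[key]]
  if (!is.null(hit)) return(hit)
  mesh <- .icosahedron()
  for (i in seq_len(subdiv)) mesh <- .subdivide_sphere(mesh)
  .icosphere_cache[[key]] <- mesh
  mesh
}

## Unit cube (half-edge 1): 8 vertices, 12 triangles, outward winding.
.unit_box <- function() {
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  dimnames(v) <- NULL
  f <- matrix(c(
    1, 3, 2,  2, 3, 4,    # z = -1
    5, 6, 7,  6, 8, 7,    # z = +1
    1, 2, 5,  2, 6, 5,    # y = -1
    3, 7, 4,  4, 7, 8,    # y = +1
    1, 5, 3,  3, 5, 7,    # x = -1
    2, 4, 6,  4, 8, 6),   # x = +1
    ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

## 8-sided open tube between two points: 16 vertices, 16 triangles.
.tube <- function(p0, p1, radius, sides = 8L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len == 0) return(NULL)
  w <- axis / len
  ref <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  vv <- c(w[2L] * u[3L] - w[3L] * u[2L],
          w[3L] * u[1L] - w[1L] * u[3L],
          w[1L] * u[2L] - w[2L] * u[1L])
  ang <- 2 * pi * (seq_len(sides) - 1L) / sides
  ring <- t(vapply(ang, function(a) radius * (cos(a) * u + sin(a) * vv),
                   numeric(3L)))
  verts <- rbind(sweep(ring, 2L, p0, `+`), sweep(ring, 2L, p1, `+`))
  i <- seq_len(sides)
  j <- c(seq_len(sides)[-1L], 1L)
  faces <- rbind(cbind(i, j, i + sides),
                 cbind(j, j + sides, i + sides))
  dimnames(faces) <- NULL
  list(vertices = verts, faces = faces)
}

#' Turn a resolved scene into a colored triangle mesh
#'
#' Each sphere mark becomes an icosphere with `20 * 4^subdiv` faces, scaled
#' by its radius and translated to its position; each box mark becomes a
#' 12-triangle cuboid with edge length `2 * radius`. Every vertex carries
#' the rgba color of its mark. Link segments become open tubes with an
#' 8-sided cross-section and radius `0.25 *` the scene's default radius,
#' colored per end by the linked marks.
#'
#' @param scene a `resolved_scene`.
#' @param sphere_subdiv icosphere subdivision level, 0..5 (default 2;
#'   higher levels are refused as a mesh-size guard).
#' @return a `scene_mesh`: list with `vertices` (n x 3), `colors`
#'   (n x 4 integer rgba) and `faces` (m x 3, 1-based).
#' @export
to_mesh <- function(scene, sphere_subdiv = 2L) {
  stopifnot(inherits(scene, "resolved_scene"))
  sphere_subdiv <- as.integer(sphere_subdiv)
  if (sphere_subdiv < 0L || sphere_subdiv > 5L)
    stop("sphere_subdiv must be between 0 and 5 (mesh-size guard)")
  verts <- list(); cols <- list(); faces <- list()
  offset <- 0L
  add <- function(v, f, rgba_rows) {
    verts[[length(verts) + 1L]] <<- v
    cols[[length(cols) + 1L]] <<- rgba_rows
    faces[[length(faces) + 1L]] <<- f + offset
    offset <<- offset + nrow(v)
  }
  sph <- .icosphere(sphere_subdiv)
  box <- .unit_box()
  m <- scene$marks
  for (i in seq_len(nrow(m))) {
    base <- if (m$mark[i] == "sphere") sph else box
    v <- base$vertices * m$radius[i]
    v <- sweep(v, 2L, c(m$x[i], m$y[i], m$z[i]), `+`)
    rgba <- matrix(rep(c(m$r[i], m$g[i], m$b[i], m$a[i]), each = nrow(v)),
                   ncol = 4L)
    add(v, base$faces, rgba)
  }
  link_r <- 0.25 * scene$default_radius
  for (i in seq_len(nrow(scene$links))) {
    l <- scene$links[i, ]
    tube <- .tube(c(l$x0, l$y0, l$z0), c(l$x1, l$y1, l$z1), link_r)
    if (is.null(tube)) next
    half <- nrow(tube$vertices) / 2L
    c0 <- c(m$r[l$from], m$g[l$from], m$b[l$from], m$a[l$from])
    c1 <- c(m$r[l$to], m$g[l$to], m$b[l$to], m$a[l$to])
    rgba <- rbind(matrix(rep(c0, each = half), ncol = 4L),
                  matrix(rep(c1, each = half), ncol = 4L))
    add(tube$vertices, tube$faces, rgba)
  }
  vertices <- if (length(verts)) do.call(rbind, verts)
              else matrix(numeric(), ncol = 3L)
  colors <- if (length(cols)) do.call(rbind, cols)
            else matrix(integer(), ncol = 4L)
  storage.mode(colors) <- "integer"
  fmat <- if (length(faces)) do.call(rbind, faces)
          else matrix(integer(), ncol = 3L)
  storage.mode(fmat) <- "integer"
  structure(list(vertices = vertices, colors = colors, faces = fmat),
            class = "scene_mesh")
}

#' @export
print.scene_mesh <- function(x, ...) {
  cat(sprintf("<scene_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write a mesh as ascii PLY with per-vertex colors
#'
#' Vertex colors are stored as uchar red/green/blue/alpha properties; face
#' indices are 0-based in the file. [read_ply()] parses the files this
#' writer produces (ascii, the same property layout), enabling lossless
#' round-trips of topology and colors.
#'
#' @param mesh a `scene_mesh`.
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "scene_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format ascii 1.0",
              "comment chromoscene resolved scene",
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue", "property uchar alpha",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- if (nv) paste(.fmt_num(mesh$vertices[, 1L]),
                          .fmt_num(mesh$vertices[, 2L]),
                          .fmt_num(mesh$vertices[, 3L]),
                          mesh$colors[, 1L], mesh$colors[, 2L],
                          mesh$colors[, 3L], mesh$colors[, 4L])
            else character()
  flines <- if (nf) paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                          mesh$faces[, 3L] - 1L)
            else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, vlines, flines), con, sep = "\n")
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ascii PLY file (no end_header): ", path)
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  body <- lines[-seq_len(end)]
  vert <- matrix(numeric(), ncol = 3L)
  cols <- matrix(integer(), ncol = 4L)
  if (nv > 0L) {
    vtok <- do.call(rbind, strsplit(body[seq_len(nv)], " ", fixed = TRUE))
    vert <- matrix(as.numeric(vtok[, 1:3]), ncol = 3L)
    cols <- matrix(as.integer(vtok[, 4:7]), ncol = 4L)
  }
  faces <- matrix(integer(), ncol = 3L)
  if (nf > 0L) {
    ftok <- do.call(rbind, strsplit(body[nv + seq_len(nf)], " ", fixed = TRUE))
    faces <- matrix(as.integer(ftok[, 2:4]), ncol = 3L) + 1L
  }
  structure(list(vertices = vert, colors = cols, faces = faces),
            class = "scene_mesh")
}

#' Write a mesh as Wavefront OBJ
#'
#' OBJ carries no per-vertex colors (a limitation of the format); only
#' geometry and topology are written.
#'
#' @param mesh a `scene_mesh`.
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "scene_mesh"))
  vlines <- if (nrow(mesh$vertices))
    paste("v", .fmt_num(mesh$vertices[, 1L]), .fmt_num(mesh$vertices[, 2L]),
          .fmt_num(mesh$vertices[, 3L]))
  else character()
  flines <- if (nrow(mesh$faces))
    paste("f", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L])
  else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# chromoscene mesh", vlines, flines), con, sep = "\n")
  invisible(path)
}
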