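test_that("sphere meshes follow the icosphere face-count formula", {
  m0 <- to_mesh(single_mark_scene(), sphere_subdiv = 0)
  expect_equal(nrow(m0$faces), 20)           # icosahedron
  expect_equal(nrow(m0$vertices), 12)

  for (n in c(1, 3, 7)) {
    m1 <- to_mesh(single_mark_scene(n = n), sphere_subdiv = 1)
    expect_equal(nrow(m1$faces), 80 * n)
    expect_equal(nrow(m1$vertices), 42 * n)  # 10 * 4^s + 2 per sphere
  }
  m2 <- to_mesh(single_mark_scene(), sphere_subdiv = 2)
  expect_equal(nrow(m2$faces), 320)
  expect_error(to_mesh(single_mark_scene(), sphere_subdiv = 6), "guard")
})

test_that("box marks are 8-vertex 12-triangle cuboids of edge 2r", {
  sc <- single_mark_scene(mark = "box", radius = 0.7)
  m <- to_mesh(sc)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  edge <- diff(range(m$vertices[, 1]))
  expect_equal(edge, 1.4)
})

test_that("mesh bounding box is the mark bounding box inflated by the radius", {
  sc <- single_mark_scene(n = 20, radius = 0.3, seed = 9)
  m <- to_mesh(sc, sphere_subdiv = 2)
  pts <- sc$marks
  for (j in 1:3) {
    axis <- c("x", "y", "z")[j]
    expect_equal(min(m$vertices[, j]), min(pts[[axis]]) - 0.3,
                 tolerance = 1e-9)
    expect_equal(max(m$vertices[, j]), max(pts[[axis]]) + 0.3,
                 tolerance = 1e-9)
  }
})

test_that("links become 8-sided tubes colored by their end marks", {
  s <- make_structure(rbind(c(0, 0, 0), c(1, 0, 0)),
                      chrom = c("chr1", "chr1"), start = c(0, 100),
                      end = c(100, 200))
  rs <- resolve(s, view_config(scale = 0.2, links = TRUE))
  m <- to_mesh(rs, sphere_subdiv = 0)
  expect_equal(nrow(m$faces), 2 * 20 + 16)
  expect_equal(nrow(m$vertices), 2 * 12 + 16)
})

test_that("PLY files round-trip topology and vertex colors", {
  sc <- single_mark_scene(n = 4, seed = 2)
  mesh <- to_mesh(sc, 1)
  p <- tempfile(fileext = ".ply")
  write_ply(mesh, p)
  back <- read_ply(p)
  expect_identical(back$faces, mesh$faces)
  expect_identical(back$colors, mesh$colors)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
  # all face indices address existing vertices
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))
})

test_that("an empty scene still writes a valid 0-element PLY", {
  empty <- structure(list(
    marks = data.frame(x = numeric(), y = numeric(), z = numeric(),
                       mark = character(), radius = numeric(),
                       r = integer(), g = integer(), b = integer(),
                       a = integer(), structure = character()),
    links = data.frame(from = integer(), to = integer(), x0 = numeric(),
                       y0 = numeric(), z0 = numeric(), x1 = numeric(),
                       y1 = numeric(), z1 = numeric()),
    default_radius = 1), class = "resolved_scene")
  mesh <- to_mesh(empty)
  p <- tempfile(fileext = ".ply")
  write_ply(mesh, p)
  back <- read_ply(p)
  expect_equal(nrow(back$vertices), 0)
  expect_equal(nrow(back$faces), 0)
})

test_that("OBJ export writes parseable geometry", {
  mesh <- to_mesh(single_mark_scene(n = 2, seed = 3), 0)
  p <- tempfile(fileext = ".obj")
  write_obj(mesh, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
})

test_that("preview renders deterministic orthographic discs", {
  s <- make_structure(matrix(0, 1, 3))
  rs <- resolve(s, view_config(color = "#ff0000", scale = 1))
  p <- tempfile(fileext = ".png")
  render_preview(rs, p, view = c(0, 0, 1), size = 51)
  img <- png::readPNG(p)
  center <- img[26, 26, ]
  expect_equal(center[1:3], c(1, 0, 0))      # center pixel is red

  # nearer of two overlapping spheres wins the overlap pixels
  s2 <- make_structure(rbind(c(0, 0, 0), c(0.1, 0, 5)))
  vc2 <- view_config(color = field_encoding("coordinate",
                                            colormap = c("#ff0000", "#0000ff")),
                     scale = 2)
  rs2 <- resolve(s2, vc2)
  p2 <- tempfile(fileext = ".png")
  # camera looks along +z; the z=0 sphere (red) is nearer
  render_preview(rs2, p2, view = c(0, 0, 1), size = 51)
  img2 <- png::readPNG(p2)
  mid <- img2[26, 26, 1:3]
  expect_equal(unname(mid), c(1, 0, 0))

  p3 <- tempfile(fileext = ".png")
  render_preview(rs2, p3, view = c(0, 0, 1), size = 51)
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(p3, "raw", file.size(p3)))
  expect_error(render_preview(rs2, p3, view = c(0, 0, 0)), "non-zero")
})
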