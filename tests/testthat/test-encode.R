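test_that("constant channels broadcast to every bin", {
  s <- random_structure(15, seed = 9)
  rs <- resolve(s, view_config(color = "#ff0000", scale = 0.2))
  expect_true(all(rs$marks$r == 255 & rs$marks$g == 0 & rs$marks$b == 0 &
                    rs$marks$a == 255))
  expect_true(all(rs$marks$radius == 0.2))
  expect_equal(nrow(rs$marks), 15)
})

test_that("links join only genomically adjacent bins of one chromosome", {
  s <- make_structure(matrix(rnorm(9), 3), chrom = rep("chr1", 3),
                      start = c(0, 100, 300), end = c(100, 200, 400))
  rs <- resolve(s, view_config(links = TRUE))
  expect_equal(nrow(rs$links), 1)            # the gap breaks the chain
  expect_equal(rs$links$from, 1)

  s2 <- make_structure(matrix(rnorm(12), 4),
                       chrom = c("chr1", "chr1", "chr2", "chr2"),
                       start = c(0, 100, 0, 100), end = c(100, 200, 100, 200))
  rs2 <- resolve(s2, view_config(links = TRUE))
  expect_equal(nrow(rs2$links), 2)           # none spans chromosomes
  expect_true(all(rs2$links$from != 2))
})

test_that("continuous color maps hit the stops exactly at the endpoints", {
  for (cm in builtin_colormaps()) {
    stops <- colormap_stops(cm)
    enc <- field_encoding("v", colormap = cm, domain = c(0, 10))
    rgba <- map_color(c(0, 10, -5, 99), enc)
    expect_equal(unname(rgba[1, 1:3]), unname(stops[1, ]), label = cm)
    expect_equal(unname(rgba[2, 1:3]), unname(stops[nrow(stops), ]),
                 label = cm)
    # clamping: out-of-domain values pin to the endpoint stops
    expect_equal(rgba[3, ], rgba[1, ])
    expect_equal(rgba[4, ], rgba[2, ])
  }
})

test_that("midpoint of a black->white two-stop map is mid-grey", {
  enc <- field_encoding("v", colormap = "greys-2", domain = c(0, 1))
  mid <- map_color(0.5, enc)
  expect_true(all(abs(mid[1, 1:3] - 128) <= 1))
})

test_that("piecewise-linear interpolation matches a closed-form check", {
  stops <- colormap_stops("viridis-8")
  enc <- field_encoding("v", colormap = "viridis-8", domain = c(0, 1))
  set.seed(13)
  v <- runif(50)
  got <- map_color(v, enc)
  for (i in seq_along(v)) {
    pos <- v[i] * (nrow(stops) - 1)
    k <- min(floor(pos), nrow(stops) - 2)
    want <- floor(stops[k + 1, ] + (pos - k) * (stops[k + 2, ] - stops[k + 1, ]) + 0.5)
    expect_equal(unname(got[i, 1:3]), unname(want))
  }
})

test_that("degenerate color domain falls back to the first stop, warning", {
  enc <- field_encoding("v", colormap = "viridis-8")
  expect_warning(rgba <- map_color(rep(3, 4), enc), "degenerate")
  expect_true(all(rgba[, 1] == colormap_stops("viridis-8")[1, 1]))
})

test_that("scale mapping hits rmin/rmax at the endpoints and is monotone", {
  enc <- field_encoding("v", range = c(0.1, 0.5), domain = c(0, 100))
  expect_equal(map_scale(c(0, 100), enc), c(0.1, 0.5))
  v <- sort(runif(30, -20, 140))
  r <- map_scale(v, enc)
  expect_true(all(diff(r) >= 0))
  # direct per-element formula oracle
  t <- pmin(pmax(v / 100, 0), 1)
  expect_equal(r, 0.1 + t * 0.4)
  expect_error(map_scale(1, field_encoding("v", range = c(0, 1))), "positive")
  enc2 <- field_encoding("v", range = c(0.2, 0.9))
  expect_warning(r2 <- map_scale(rep(7, 3), enc2), "degenerate")
  expect_equal(r2, rep(0.2, 3))
})

test_that("categorical colors follow first appearance and cycle the palette", {
  pal <- c("#ff0000", "#0000ff")
  got <- map_categorical(c("A", "B", "A"), pal)
  expect_equal(got[, 1], c(255L, 0L, 255L))
  expect_equal(got[, 3], c(0L, 255L, 0L))
  wrap <- map_categorical(c("A", "B", "C"), pal)
  expect_equal(wrap[3, ], wrap[1, ])         # third label wraps to palette[1]
  # assignment depends only on first-appearance order
  shuffled <- map_categorical(c("B", "A", "B"), pal)
  expect_equal(unname(shuffled[1, 1]), 255L)
  expect_error(map_categorical("A", character()), "palette")
})

test_that("default radius is half the median consecutive-bin distance", {
  s <- make_structure(cbind(0:4, 0, 0), chrom = rep("chr1", 5),
                      start = 0:4 * 10, end = 0:4 * 10 + 10)
  expect_equal(default_radius(s), 0.5)
  expect_equal(default_radius(make_structure(matrix(1, 1, 3))), 1.0)
  s2 <- random_structure(40, n_chroms = 2, seed = 17)
  d <- sqrt(diff(s2$x)^2 + diff(s2$y)^2 + diff(s2$z)^2)
  d <- d[s2$chrom[-1] == s2$chrom[-40]]
  expect_equal(default_radius(s2), 0.5 * median(d))
})

test_that("resolve is deterministic and validates encoded fields", {
  s <- random_structure(25, seed = 19, extra = list(dens = runif(25)))
  vc <- view_config(color = field_encoding("dens"),
                    scale = field_encoding("dens", range = c(0.1, 0.3)),
                    links = TRUE)
  r1 <- resolve(s, vc)
  r2 <- resolve(s, vc)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_error(resolve(s, view_config(color = field_encoding("missing"))),
               "missing")
})

test_that("scale encoding can only shrink total mark volume vs rmax", {
  s <- random_structure(50, seed = 23, extra = list(dens = runif(50)))
  enc <- field_encoding("dens", range = c(0.05, 0.4))
  r_enc <- resolve(s, view_config(scale = enc))$marks$radius
  vol <- function(r) sum(4 / 3 * pi * r^3)
  expect_lte(vol(r_enc), vol(rep(0.4, 50)))
})

test_that("per-chromosome coordinate encoding pins telomeric bins to the scale ends", {
  spec <- sim_spec(n_chroms = 4, bins_per_chrom = 40, resolution = 1000,
                   seed = 101)
  s <- simulate_structure(spec)
  enc <- field_encoding("coordinate", colormap = "greys-2")
  rs <- resolve(s, view_config(color = enc))
  stops <- colormap_stops("greys-2")
  for (ch in chromosomes(s)) {
    rows <- which(s$chrom == ch)
    first <- rs$marks[rows[1], c("r", "g", "b")]
    last <- rs$marks[rows[length(rows)], c("r", "g", "b")]
    expect_equal(unname(unlist(first)), unname(stops[1, ]), label = ch)
    expect_equal(unname(unlist(last)), unname(stops[2, ]), label = ch)
  }
})

test_that("JSON view configs round-trip and reject unknown keys", {
  vc <- view_config(mark = "box",
                    color = field_encoding("dens", domain = c(0, 1)),
                    scale = 0.25, links = TRUE)
  p <- tempfile(fileext = ".json")
  write_view_config(vc, p)
  back <- read_view_config(p)
  expect_equal(back$mark, "box")
  expect_equal(back$color$field, "dens")
  expect_equal(back$scale, 0.25)
  expect_true(back$links)

  expect_error(read_view_config('{"mark": "sphere", "colour": "#fff"}'),
               "colour")
  expect_error(read_view_config('{"color": {"field": "v", "knid": "x"}}'),
               "knid")
})
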