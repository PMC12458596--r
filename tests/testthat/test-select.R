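test_that("query strings parse chrom, spans, suffixes and grouped digits", {
  q <- parse_range_query("chr1:0-2M, chr2, chrX:1,000-5,000")
  expect_equal(q$chrom, c("chr1", "chr2", "chrX"))
  expect_equal(q$start, c(0, 0, 1000))
  expect_equal(q$end, c(2e6, Inf, 5000))
  expect_equal(parse_range_query("chr1:1.5k-2k")$start, 1500)
  expect_error(parse_range_query("chr1:10"), "syntax")
  expect_error(parse_range_query("chr1:200-100"), "end must exceed")
})

test_that("range selection uses half-open intersection semantics", {
  s <- make_structure(matrix(0, 2, 3) + 1:2, chrom = c("chr1", "chr1"),
                      start = c(0, 100), end = c(100, 200))
  expect_equal(as.logical(select_by_ranges(s, "chr1:50-150")), c(TRUE, TRUE))
  # touching endpoints never overlap
  expect_equal(as.logical(select_by_ranges(s, "chr1:100-200")),
               c(FALSE, TRUE))
  expect_equal(as.logical(
    select_by_ranges(s, data.frame(chrom = "chr1", start = 100, end = 200)))[1],
    FALSE)
})

test_that("absent query chromosome warns and selects nothing for it", {
  s <- random_structure(10, n_chroms = 1, seed = 2)
  expect_warning(m <- select_by_ranges(s, "chrZ:0-1000"), "chrZ")
  expect_false(any(m))
})

test_that("range selection matches the brute-force oracle", {
  set.seed(404)
  for (rep in 1:20) {
    s <- random_structure(200, n_chroms = 3)
    q <- data.frame(chrom = sample(c("chr1", "chr2", "chr3", "chrZ"), 10,
                                   replace = TRUE),
                    start = sample(0:6000, 10))
    q$end <- q$start + sample(50:2000, 10)
    got <- suppressWarnings(select_by_ranges(s, q))
    expect_equal(as.logical(got), oracle_range_mask(s, q))
  }
})

test_that("range selection is invariant to splitting query intervals", {
  s <- random_structure(80, n_chroms = 2, seed = 8)
  whole <- select_by_ranges(s, data.frame(chrom = "chr1", start = 120,
                                          end = 3800))
  cuts <- c(120, 700, 701, 2050, 3800)
  pieces <- data.frame(chrom = "chr1",
                       start = c(120, 700, 701, 2050),
                       end = c(700, 701, 2050, 3800))
  split_mask <- select_by_ranges(s, pieces)
  expect_equal(as.logical(whole), as.logical(split_mask))
})

test_that("the same range replays identically across equal-binned structures", {
  s1 <- random_structure(60, n_chroms = 2, seed = 31)
  s2 <- random_structure(60, n_chroms = 2, seed = 32)  # same bins, new shape
  q <- "chr1:500-2,500, chr2:0-900"
  expect_equal(as.logical(select_by_ranges(s1, q)),
               as.logical(select_by_ranges(s2, q)))
})

test_that("sphere selection is a closed ball", {
  s <- make_structure(rbind(c(0.5, 0, 0), c(1, 0, 0), c(1.5, 0, 0)))
  m <- select_sphere(s, c(0, 0, 0), 1.0)
  expect_equal(as.logical(m), c(TRUE, TRUE, FALSE))
  expect_true(all(select_sphere(s, c(0, 0, 0), 1e9)))
})

test_that("genomic-locus centers resolve to the containing bin's point", {
  s <- random_structure(40, n_chroms = 2, resolution = 100, seed = 12)
  m <- select_sphere(s, "chr1:150", 1e-9)   # bin [100,200) on chr1
  expect_true(m[2])                          # at least its own point
  expect_error(select_sphere(s, "chr9:5", 1), "chr9:5")
  expect_error(select_sphere(s, c(0, 0, 0), -1), "positive")
})

test_that("sphere selection matches the oracle and grows monotonically", {
  set.seed(505)
  for (rep in 1:20) {
    s <- random_structure(500)
    center <- rnorm(3, sd = 2)
    r <- runif(1, 0.5, 6)
    m <- select_sphere(s, center, r)
    expect_equal(as.logical(m), oracle_sphere_mask(s, center, r))
    bigger <- select_sphere(s, center, r * 1.5)
    expect_true(all(bigger[as.logical(m)]))  # no bin lost when r grows
  }
})

test_that("cutting plane keeps the requested half-space, ties positive", {
  s <- make_structure(rbind(c(-1, 0, 0), c(0, 5, 5), c(2, 0, 0)))
  pos <- select_cutting_plane(s, c(1, 0, 0), 0, "positive")
  expect_equal(as.logical(pos), c(FALSE, TRUE, TRUE))  # x = 0 goes positive
  neg <- select_cutting_plane(s, c(1, 0, 0), 0, "negative")
  expect_equal(as.logical(neg), !as.logical(pos))
  expect_error(select_cutting_plane(s, c(0, 0, 0)), "non-zero")
})

test_that("plane sides partition every structure and match the oracle", {
  set.seed(606)
  for (rep in 1:20) {
    s <- random_structure(300)
    normal <- rnorm(3); offset <- rnorm(1)
    pos <- select_cutting_plane(s, normal, offset, "positive")
    neg <- select_cutting_plane(s, normal, offset, "negative")
    expect_true(all(xor(as.logical(pos), as.logical(neg))))
    expect_equal(as.logical(pos),
                 oracle_plane_mask(s, normal, offset, "positive"))
  }
})

test_that("mask algebra obeys boolean laws and records provenance", {
  s <- random_structure(64, seed = 77)
  a <- select_cutting_plane(s, c(1, 1, 1), 0.3)
  b <- select_sphere(s, c(0, 0, 0), 3)
  expect_false(any(a & !a))
  expect_true(all(a | !a))
  # De Morgan over all four per-element combinations present in random masks
  expect_equal(as.logical(!(a & b)), as.logical((!a) | (!b)))
  expect_equal(as.logical(combine_masks(a, b, "and-not")),
               as.logical(a) & !as.logical(b))
  expect_match(mask_provenance(a & b), "and")
  s_other <- random_structure(64, seed = 78)
  attr(s_other, "id") <- "other"
  expect_error(a & select_sphere(s_other, c(0, 0, 0), 1), "different")
})

test_that("apply_mask preserves order and columns, allows empty results", {
  s <- random_structure(30, seed = 41, extra = list(v = 1:30))
  all_true <- select_sphere(s, c(0, 0, 0), 1e9)
  expect_equal(as.data.frame(apply_mask(s, all_true)), as.data.frame(s))

  none <- invert_mask(all_true)
  empty <- apply_mask(s, none)
  expect_equal(n_bins(empty), 0)
  expect_true(any(validate_structure(empty)$invariant == "nonempty"))

  half <- select_cutting_plane(s, c(0, 0, 1), 0)
  s2 <- apply_mask(s, half)
  expect_equal(s2$v, s$v[as.logical(half)])      # extras carried, order kept
  expect_equal(n_bins(apply_mask(s2, select_sphere(s2, c(0, 0, 0), 1e9))),
               n_bins(s2))                        # idempotent under all-true
})
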