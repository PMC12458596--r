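# Fixture builders and brute-force oracles shared across the suite.
# Oracles are deliberately naive (double loops, direct formulas) and never
# call the package's own selection/encoding code paths.

random_structure <- function(n = 50, n_chroms = 2, resolution = 100,
                             seed = NULL, extra = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- diff(floor(seq(0, n, length.out = n_chroms + 1)))
  per[per == 0] <- 1
  chrom <- rep(paste0("chr", seq_len(n_chroms)), per)
  n <- length(chrom)
  start <- unlist(lapply(per, function(k) (seq_len(k) - 1) * resolution))
  make_structure(matrix(rnorm(3 * n, sd = 3), ncol = 3),
                 chrom = chrom, start = start, end = start + resolution,
                 extra = extra, id = paste0("fix", n))
}

single_mark_scene <- function(mark = "sphere", radius = 0.5, n = 1,
                              seed = 1) {
  set.seed(seed)
  s <- make_structure(matrix(rnorm(3 * n), ncol = 3))
  resolve(s, view_config(mark = mark, scale = radius))
}

# interval overlap, half-open, by double loop
oracle_range_mask <- function(s, q) {
  vapply(seq_len(nrow(s)), function(i) {
    any(vapply(seq_len(nrow(q)), function(j) {
      s$chrom[i] == q$chrom[j] &&
        s$start[i] < q$end[j] && q$start[j] < s$end[i]
    }, logical(1)))
  }, logical(1))
}

oracle_sphere_mask <- function(s, center, radius) {
  vapply(seq_len(nrow(s)), function(i) {
    sqrt(sum((c(s$x[i], s$y[i], s$z[i]) - center)^2)) <= radius
  }, logical(1))
}

oracle_plane_mask <- function(s, normal, offset, side) {
  nhat <- normal / sqrt(sum(normal^2))
  vapply(seq_len(nrow(s)), function(i) {
    v <- sum(c(s$x[i], s$y[i], s$z[i]) * nhat) - offset
    if (side == "positive") v >= 0 else v < 0
  }, logical(1))
}

# interval-union sweep for coverage of one bin
oracle_coverage <- function(bin_start, bin_end, f_start, f_end) {
  cs <- pmax(f_start, bin_start)
  ce <- pmin(f_end, bin_end)
  keep <- cs < ce
  cs <- cs[keep]; ce <- ce[keep]
  if (!length(cs)) return(0)
  o <- order(cs)
  cs <- cs[o]; ce <- ce[o]
  tot <- 0; cur_s <- cs[1]; cur_e <- ce[1]
  for (i in seq_along(cs)[-1]) {
    if (cs[i] <= cur_e) cur_e <- max(cur_e, ce[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- cs[i]; cur_e <- ce[i] }
  }
  (tot + cur_e - cur_s) / (bin_end - bin_start)
}
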