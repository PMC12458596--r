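#' Simulation settings for synthetic genome structures
#'
#' The simulator emulates desk-scale chromatin models: each chromosome is a
#' confined random walk (fixed step length, rejected at the wall of a
#' spherical nucleus), and annotations are planted with a radially decaying
#' density so that recovery of the "gene-rich center" signal can be tested.
#'
#' @param n_chroms number of chromosomes (>= 1), named `"chr1".."chrN"`.
#' @param bins_per_chrom bins per chromosome (>= 2).
#' @param resolution bin width in bp.
#' @param step_length spatial distance between consecutive bins (model
#'   units); must satisfy `step_length < 2 * confinement_radius`.
#' @param confinement_radius radius of the confining sphere.
#' @param seed RNG seed; the same spec always reproduces the same structure
#'   and features.
#' @param density_gradient decay rate gamma >= 0 of feature density with
#'   radial position: expected features per bin is
#'   `2 * exp(-gamma * d / confinement_radius)` where `d` is the bin's
#'   distance from the structure centroid. 0 plants no gradient.
#' @export
sim_spec <- function(n_chroms = 4L, bins_per_chrom = 250L,
                     resolution = 100000L, step_length = 1,
                     confinement_radius = 10, seed = 42L,
                     density_gradient = 0) {
  stopifnot(n_chroms >= 1L, bins_per_chrom >= 2L, resolution >= 1,
            step_length > 0, confinement_radius > 0, density_gradient >= 0)
  if (!(step_length < 2 * confinement_radius))
    stop("step_length must be smaller than the confinement diameter")
  structure(list(n_chroms = as.integer(n_chroms),
                 bins_per_chrom = as.integer(bins_per_chrom),
                 resolution = as.numeric(resolution),
                 step_length = as.numeric(step_length),
                 confinement_radius = as.numeric(confinement_radius),
                 seed = as.integer(seed),
                 density_gradient = as.numeric(density_gradient)),
            class = "sim_spec")
}

## Run `expr` under a given seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.runif_ball <- function(radius) {
  repeat {
    p <- stats::runif(3L, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

.rand_direction <- function() {
  repeat {
    g <- stats::rnorm(3L)
    n <- sqrt(sum(g^2))
    if (n > 0) return(g / n)
  }
}

#' Simulate a confined random-walk genome structure
#'
#' Each chromosome starts uniformly inside the confining ball and takes
#' steps of fixed length in uniformly random directions; a step whose
#' endpoint would leave the ball is re-drawn (up to 10^4 retries per step).
#' Bins are laid out at the spec's resolution on chromosomes
#' `"chr1".."chrN"`. Deterministic given the spec's seed.
#'
#' @param spec a [sim_spec()].
#' @return a `genome_structure`.
#' @export
simulate_structure <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    k <- spec$bins_per_chrom
    R <- spec$confinement_radius
    ell <- spec$step_length
    coords <- vector("list", spec$n_chroms)
    for (ci in seq_len(spec$n_chroms)) {
      pts <- matrix(0, nrow = k, ncol = 3L)
      pts[1L, ] <- .runif_ball(R)
      for (i in 2L:k) {
        tries <- 0L
        repeat {
          cand <- pts[i - 1L, ] + ell * .rand_direction()
          if (sum(cand^2) <= R^2) break
          tries <- tries + 1L
          if (tries >= 1e4L)
            stop("simulation stuck: 10^4 rejected steps in a row ",
                 "(step_length too large for the confinement radius?)")
        }
        pts[i, ] <- cand
      }
      coords[[ci]] <- pts
    }
    coords <- do.call(rbind, coords)
    chrom <- rep(paste0("chr", seq_len(spec$n_chroms)), each = k)
    start <- rep((seq_len(k) - 1L) * spec$resolution, spec$n_chroms)
    make_structure(coords, chrom = chrom, start = start,
                   end = start + spec$resolution,
                   id = sprintf("sim-seed%d", spec$seed))
  })
}

#' Simulate interval features with a planted radial density gradient
#'
#' Per bin, a feature count is drawn from a Poisson law with mean
#' `2 * exp(-gamma * d / R)`, where `d` is the bin's radial position
#' (distance to the structure centroid), `R` the confinement radius and
#' `gamma` the spec's `density_gradient`. Features are 1-bp intervals
#' placed uniformly inside their bin. With `gamma = 0` the density is
#' spatially uniform; with large `gamma` inner bins are feature-rich --
#' the planted signal the aggregation workflow should recover.
#' Deterministic given the spec's seed (the feature stream is derived from
#' `seed + 1` so structure and annotation are independently reproducible).
#'
#' @param s a `genome_structure` (typically from [simulate_structure()]).
#' @param spec a [sim_spec()].
#' @return a feature table.
#' @export
simulate_features <- function(s, spec) {
  stopifnot(is_structure(s), inherits(spec, "sim_spec"))
  .with_seed(spec$seed + 1L, {
    sr <- radial_position(s, out_column = ".radial_tmp")
    d <- sr$.radial_tmp
    lambda <- 2 * exp(-spec$density_gradient * d / spec$confinement_radius)
    counts <- stats::rpois(length(lambda), lambda)
    idx <- rep(seq_len(nrow(s)), counts)
    if (!length(idx)) return(.empty_features())
    width <- s$end[idx] - s$start[idx]
    offs <- floor(stats::runif(length(idx)) * pmax(width - 1, 1))
    start <- s$start[idx] + offs
    feature_table(chrom = s$chrom[idx], start = start, end = start + 1,
                  name = sprintf("feat_%05d", seq_along(idx)),
                  strand = ".")
  })
}
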