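#' Generate a synthetic sphere or ellipsoid phantom
#'
#' Builds a 3D volume containing a single hard-edged object of known
#' geometry together with its exact ground-truth mask, so every stage of the
#' pipeline can be tested without external image data. A voxel whose centre
#' lies inside the analytic shape gets `fg`, all others `bg`; independent
#' Gaussian noise of standard deviation `noise_sd` is then added from a
#' generator seeded with `rng_seed` (the truth mask is noise-free by
#' construction). Identical specifications and seeds give bitwise-identical
#' output.
#'
#' Optionally a one-voxel linear partial-volume shell can be enabled to
#' imitate MR boundary blur; it is off by default.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param dims Length-3 integer grid dimensions.
#' @param spacing Length-3 voxel spacing, mm.
#' @param center Object centre in world mm (default: volume centre).
#' @param radius Sphere radius in mm, or length-3 semi-axes for an ellipsoid.
#' @param fg,bg Foreground / background intensities.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param rng_seed Integer seed for the noise generator.
#' @param origin,direction Grid geometry (defaults: zero origin, identity).
#' @param pv_shell Logical; linear partial-volume transition of one voxel
#'   width across the boundary (default FALSE).
#' @return List with `volume` (`image_volume`) and `truth` (`binary_mask`).
#' @examples
#' ph <- make_phantom(radius = 10, dims = c(48, 48, 48), rng_seed = 1)
#' mask_volume(ph$truth)$mm3 / (4 / 3 * pi * 10^3)  # close to 1
#' @export
make_phantom <- function(shape = c("sphere", "ellipsoid"),
                         dims = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                         center = NULL, radius = 15,
                         fg = 150, bg = 50, noise_sd = 0, rng_seed = 1L,
                         origin = c(0, 0, 0), direction = diag(3),
                         pv_shell = FALSE) {
  shape <- match.arg(shape)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 2L), noise_sd >= 0)
  semi <- if (shape == "sphere") rep(radius[1L], 3L) else as.numeric(radius)
  if (length(semi) != 3L || any(semi <= 0)) {
    stop("radius/semi-axes must be positive (length 3 for an ellipsoid)",
         call. = FALSE)
  }

  geom <- image_volume(array(0, dims), spacing = spacing, origin = origin,
                       direction = direction)
  if (is.null(center)) {
    center <- drop(index_to_world(geom, (dims - 1) / 2))
  }
  center <- as.numeric(center)

  idx <- as.matrix(expand.grid(i = 0:(dims[1L] - 1L), j = 0:(dims[2L] - 1L),
                               k = 0:(dims[3L] - 1L)))
  ctr <- index_to_world(geom, idx)
  rel <- sweep(ctr, 2L, center, "-")
  q <- sqrt(rowSums(sweep(rel, 2L, semi, "/")^2))   # <= 1 inside

  # the object must fit inside the grid: check the axis-aligned extremes
  for (a in 1:3) {
    for (sgn in c(-1, 1)) {
      p <- center + sgn * semi[a] * geom$direction[, a]
      if (!point_in_grid(geom, matrix(p, ncol = 3L))) {
        stop("object does not fit inside the grid", call. = FALSE)
      }
    }
  }

  inside <- q <= 1
  vox <- ifelse(inside, fg, bg)
  if (pv_shell) {
    # linear ramp across one voxel-sized shell around the boundary
    h <- min(spacing) / mean(semi)
    frac <- pmin(1, pmax(0, (1 + h / 2 - q) / h))
    vox <- bg + (fg - bg) * frac
  }

  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(rng_seed))
    vox <- vox + rnorm(length(vox), mean = 0, sd = noise_sd)
  }

  volume <- image_volume(array(vox, dims), spacing = spacing,
                         origin = origin, direction = direction)
  truth <- binary_mask(array(inside, dims), geometry = volume)
  list(volume = volume, truth = truth, center = center)
}
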