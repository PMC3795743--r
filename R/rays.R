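#' Estimate the object's mean grey value around the seed
#'
#' Averages all voxels whose index lies within a cube of half-width
#' `radius_voxels` centred on the seed's voxel, clipped to the grid. This is
#' the automatic estimate of the target object's average intensity taken from
#' the immediate neighbourhood of the user-defined seed point.
#'
#' @param volume An `image_volume`.
#' @param seed Length-3 world position (mm) inside the volume.
#' @param radius_voxels Positive integer cube half-width (default 3, i.e. up
#'   to a 7x7x7 neighbourhood).
#' @return Scalar mean intensity.
#' @export
estimate_mean <- function(volume, seed, radius_voxels = 3L) {
  stopifnot(inherits(volume, "image_volume"))
  if (radius_voxels < 1 || radius_voxels != round(radius_voxels)) {
    stop("`radius_voxels` must be a positive integer", call. = FALSE)
  }
  seed <- resolve_seed(volume, seed, "world")
  ctr <- round(drop(world_to_index(volume, seed)))
  d <- dim(volume$voxels)
  rng <- lapply(1:3, function(a) {
    lo <- max(0, ctr[a] - radius_voxels)
    hi <- min(d[a] - 1, ctr[a] + radius_voxels)
    (lo:hi) + 1L
  })
  mean(volume$voxels[rng[[1L]], rng[[2L]], rng[[3L]]])
}

#' Sample intensities along template rays
#'
#' Places the template at the seed and samples the volume along every ray at
#' radii `step, 2*step, ..., Z*step` (the seed itself is not a node). Sample
#' `z` of ray `r` sits at world position `seed + z * step * direction(r)`
#' with `z = 1..Z`. Samples falling outside the grid are flagged `oob` and
#' carry `NA` intensity.
#'
#' @param volume An `image_volume`.
#' @param seed Length-3 world position (mm) inside the volume.
#' @param template A `spherical_template`.
#' @param Z Samples per ray (>= 2; default 60).
#' @param step Radial sampling distance in mm (> 0; default `min(spacing)`).
#' @param method Intensity lookup: `"nearest"` takes the grey value of the
#'   voxel containing the sample (the default), `"linear"` interpolates
#'   trilinearly.
#' @return An object of class `ray_grid`: list with `seed`, `template`, `Z`,
#'   `step`, `method`, `intensities` (R x Z, NA when oob) and `oob` (R x Z
#'   logical).
#' @export
sample_rays <- function(volume, seed, template, Z = 60L,
                        step = min(volume$spacing),
                        method = c("nearest", "linear")) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(template, "spherical_template"))
  method <- match.arg(method)
  if (Z < 2 || Z != round(Z)) stop("`Z` must be an integer >= 2", call. = FALSE)
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  seed <- resolve_seed(volume, seed, "world")
  R <- nrow(template$directions)
  Z <- as.integer(Z)

  radii <- seq_len(Z) * step
  # points: (r, z) flattened ray-major; row index = (r-1)*Z + z
  dirs <- template$directions[rep(seq_len(R), each = Z), , drop = FALSE]
  pts <- dirs * rep(radii, times = R)
  pts <- sweep(pts, 2L, seed, "+")
  smp <- interp_volume(volume, pts, method = method)

  structure(
    list(seed = seed, template = template, Z = Z, step = step,
         method = method,
         intensities = matrix(smp$values, nrow = R, ncol = Z, byrow = TRUE),
         oob = matrix(smp$oob, nrow = R, ncol = Z, byrow = TRUE)),
    class = "ray_grid"
  )
}

#' Compute the node cost field
#'
#' The cost of a node is the absolute difference between its sampled grey
#' value and the mean grey value estimated around the seed. Out-of-bounds
#' nodes receive a finite constant `OOB_COST` exceeding any attainable
#' in-bounds cost, which keeps the cut inside the volume without infinities
#' in the arithmetic.
#'
#' `OOB_COST = 1 + max(in-bounds intensity range, largest in-bounds cost)`.
#'
#' @param grid A `ray_grid` from [sample_rays()].
#' @param mean_estimate Scalar reference intensity (from [estimate_mean()]).
#' @return An object of class `cost_field`: list with `c` (R x Z non-negative
#'   matrix), `mean_estimate`, `oob_cost` and the originating `grid`.
#' @export
compute_costs <- function(grid, mean_estimate) {
  stopifnot(inherits(grid, "ray_grid"), is.finite(mean_estimate))
  inten <- grid$intensities
  cost <- abs(inten - mean_estimate)
  inb <- !grid$oob
  if (!any(inb)) stop("all ray samples fall outside the volume", call. = FALSE)
  rng <- range(inten[inb])
  oob_cost <- 1 + max(rng[2L] - rng[1L], max(cost[inb]))
  cost[grid$oob] <- oob_cost
  structure(list(c = cost, mean_estimate = mean_estimate,
                 oob_cost = oob_cost, grid = grid),
            class = "cost_field")
}

#' Build a cost field directly from a matrix (for testing and small studies)
#'
#' @param cmat R x Z non-negative matrix of node costs.
#' @param template Optional `spherical_template` consistent with `R`.
#' @return A `cost_field` without an attached ray grid.
#' @export
cost_field <- function(cmat, template = NULL) {
  cmat <- as.matrix(cmat)
  if (any(cmat < 0) || any(!is.finite(cmat))) {
    stop("costs must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(template) && nrow(cmat) != nrow(template$directions)) {
    stop("cost rows must match the template's ray count", call. = FALSE)
  }
  structure(list(c = cmat, mean_estimate = NA_real_, oob_cost = NA_real_,
                 grid = NULL),
            class = "cost_field")
}
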