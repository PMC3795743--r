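#' Segment a blob-like object from a single seed point
#'
#' Full pipeline: estimate the object's mean grey value around the seed,
#' cast rays from the seed through the template's surface points, compute
#' node costs, build the s-t graph, extract the minimum-cost closed set via
#' min-cut, and turn its upper envelope into a triangulated mesh and a
#' voxelized mask on the input grid. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param volume An `image_volume`.
#' @param seed Length-3 seed position inside the object.
#' @param seed_space `"world"` (mm, default) or `"voxel"` (0-based index).
#' @param subdivision_level Template subdivision level (default 3, 642 rays).
#' @param Z Samples per ray (default 60).
#' @param step Radial step in mm (default `min(spacing)`).
#' @param delta_r Smoothness parameter: neighbouring rays' boundary indices
#'   may differ by at most this many layers (default 2; 0 forces a sphere).
#' @param mean_radius_voxels Half-width of the cube used for the mean grey
#'   value estimate (default 3).
#' @param method Intensity lookup along rays, `"nearest"` (default) or
#'   `"linear"`; see [sample_rays()].
#' @param template Optionally a prebuilt `spherical_template` (overrides
#'   `subdivision_level`).
#' @return An object of class `raycut_result`: list with `mask`
#'   (`binary_mask`), `mesh` (`surface_mesh`), `surface` (`cut_surface`),
#'   `costs`, `grid`, and `report` (named list echoing the configuration
#'   plus `mean_estimate`, `total_cost` and a per-ray boundary summary).
#' @examples
#' ph <- make_phantom(radius = 8, dims = c(40, 40, 40), rng_seed = 1)
#' res <- segment(ph$volume, seed = ph$center, subdivision_level = 2,
#'                Z = 15, delta_r = 1)
#' dice(res$mask, ph$truth)
#' @export
segment <- function(volume, seed, seed_space = c("world", "voxel"),
                    subdivision_level = 3L, Z = 60L,
                    step = min(volume$spacing), delta_r = 2L,
                    mean_radius_voxels = 3L,
                    method = c("nearest", "linear"), template = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  seed_space <- match.arg(seed_space)
  method <- match.arg(method)
  seed_world <- resolve_seed(volume, seed, seed_space)
  if (is.null(template)) template <- build_template(subdivision_level)

  mu <- estimate_mean(volume, seed_world, radius_voxels = mean_radius_voxels)
  grid <- sample_rays(volume, seed_world, template, Z = Z, step = step,
                      method = method)
  costs <- compute_costs(grid, mu)
  weights <- node_weights(costs)
  graph <- build_graph(weights, template, delta_r = delta_r)
  surface <- min_cut_surface(graph, costs)
  mesh <- surface_to_mesh(surface, grid)
  mask <- voxelize(surface, grid, volume)

  report <- list(
    seed_world_mm = seed_world,
    seed_space = seed_space,
    subdivision_level = template$subdivision_level,
    n_rays = nrow(template$directions),
    Z = grid$Z,
    step_mm = grid$step,
    delta_r = as.integer(delta_r),
    mean_radius_voxels = as.integer(mean_radius_voxels),
    method = method,
    mean_estimate = mu,
    total_cost = surface$total_cost,
    boundary_layers = list(min = min(surface$k), max = max(surface$k),
                           mean = mean(surface$k)),
    mask_voxels = mask_volume(mask)$voxels,
    mask_mm3 = mask_volume(mask)$mm3
  )
  structure(list(mask = mask, mesh = mesh, surface = surface, costs = costs,
                 grid = grid, report = report),
            class = "raycut_result")
}

#' @export
print.raycut_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<raycut_result> %d rays x %d samples, delta_r = %d\n  mean estimate %.3f, total cost %.4f\n  mask: %d voxels (%.1f mm^3)\n",
    r$n_rays, r$Z, r$delta_r, r$mean_estimate, r$total_cost,
    r$mask_voxels, r$mask_mm3))
  invisible(x)
}
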