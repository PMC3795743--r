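#' Triangulated surface mesh from a cut surface
#'
#' Places each template vertex at its ray's cut node, i.e. at distance
#' `k[r] * step` from the seed along direction `r`, and copies the template
#' triangulation. The mesh is closed because the template is.
#'
#' @param surface A `cut_surface`.
#' @param grid The `ray_grid` the surface was computed on (supplies seed,
#'   step and template).
#' @return An object of class `surface_mesh`: list with `vertices` (R x 3,
#'   world mm), `triangles` (F x 3 indices) and `seed`.
#' @export
surface_to_mesh <- function(surface, grid) {
  stopifnot(inherits(surface, "cut_surface"), inherits(grid, "ray_grid"))
  tpl <- grid$template
  if (length(surface$k) != nrow(tpl$directions) || surface$Z != grid$Z) {
    stop("cut surface and ray grid come from different configurations",
         call. = FALSE)
  }
  radii <- surface$k * grid$step
  verts <- tpl$directions * radii
  verts <- sweep(verts, 2L, grid$seed, "+")
  structure(list(vertices = verts, triangles = tpl$triangles,
                 seed = grid$seed),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh>", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Voxelize a cut surface onto the image grid
#'
#' The cut surface is star-shaped about the seed, so the inside test is
#' radial: a voxel is inside iff its centre's distance from the seed does not
#' exceed the surface radius interpolated in its direction. The radius
#' function is the barycentric interpolation of the three incident rays' cut
#' radii `k[r] * step` over the template triangle containing the direction;
#' the seed voxel itself is always inside.
#'
#' @param surface A `cut_surface`.
#' @param grid The matching `ray_grid`.
#' @param volume The `image_volume` that was segmented (supplies the output
#'   grid geometry).
#' @return A `binary_mask` on the input grid.
#' @export
voxelize <- function(surface, grid, volume) {
  stopifnot(inherits(surface, "cut_surface"), inherits(grid, "ray_grid"),
            inherits(volume, "image_volume"))
  tpl <- grid$template
  if (length(surface$k) != nrow(tpl$directions)) {
    stop("cut surface and ray grid come from different configurations",
         call. = FALSE)
  }
  radii <- surface$k * grid$step
  d <- dim(volume$voxels)
  seed <- grid$seed

  idx <- as.matrix(expand.grid(i = 0:(d[1L] - 1L), j = 0:(d[2L] - 1L),
                               k = 0:(d[3L] - 1L)))
  ctr <- index_to_world(volume, idx)
  rel <- sweep(ctr, 2L, seed, "-")
  rho <- sqrt(rowSums(rel^2))

  inside <- rho <= min(radii) + 1e-9          # trivially inside
  todo <- which(!inside & rho <= max(radii) + 1e-9)

  if (length(todo)) {
    u <- rel[todo, , drop = FALSE] / rho[todo]
    s_u <- surface_radius(tpl, radii, u)
    inside[todo] <- rho[todo] <= s_u + 1e-9
  }

  mask <- array(inside, dim = d)
  binary_mask(mask, geometry = volume)
}

#' Interpolated surface radius in given directions
#'
#' For each unit direction, finds the template triangle whose cone contains
#' it (candidates taken from the triangles incident to the nearest template
#' vertices; ties on edges resolved towards the lowest triangle index) and
#' interpolates the triangle's three vertex radii with the direction's
#' normalised cone coordinates.
#'
#' @param template A `spherical_template`.
#' @param radii Length-R numeric vector of per-ray radii.
#' @param u N x 3 matrix of unit directions.
#' @return Length-N numeric vector of interpolated radii.
#' @keywords internal
surface_radius <- function(template, radii, u) {
  dirs <- template$directions
  tri <- template$triangles
  n <- nrow(u)

  # triangles incident to each vertex
  vt <- vector("list", nrow(dirs))
  for (f in seq_len(nrow(tri))) {
    for (v in tri[f, ]) vt[[v]] <- c(vt[[v]], f)
  }

  # nearest template vertex by direction cosine (chunked to bound memory)
  nearest <- integer(n)
  chunk <- 65536L
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(n, start + chunk - 1L)
    nearest[sel] <- max.col(u[sel, , drop = FALSE] %*% t(dirs),
                            ties.method = "first")
  }

  # per-triangle inverse of the direction matrix for cone coordinates
  tri_inv <- lapply(seq_len(nrow(tri)), function(f) {
    solve(t(dirs[tri[f, ], , drop = FALSE]))
  })

  out <- rep(NA_real_, n)
  groups <- split(seq_len(n), nearest)
  for (vname in names(groups)) {
    rows <- groups[[vname]]
    cand <- sort(vt[[as.integer(vname)]])
    uu <- t(u[rows, , drop = FALSE])
    # best-fitting candidate kept as fallback for directions that miss all
    # cones by more than the tolerance (only happens in degenerate geometry)
    fb_val <- rep(NA_real_, length(rows))
    fb_minl <- rep(-Inf, length(rows))
    for (f in cand) {
      lam <- tri_inv[[f]] %*% uu            # 3 x m cone coordinates
      minl <- apply(lam, 2L, min)
      wsum <- colSums(lam)
      val <- colSums(lam * radii[tri[f, ]]) / wsum
      hit <- which(minl >= -1e-9 & is.na(out[rows]))
      if (length(hit)) out[rows[hit]] <- val[hit]
      better <- which(minl > fb_minl)
      if (length(better)) {
        fb_minl[better] <- minl[better]
        fb_val[better] <- val[better]
      }
    }
    miss <- which(is.na(out[rows]))
    if (length(miss)) out[rows[miss]] <- fb_val[miss]
  }
  out
}
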