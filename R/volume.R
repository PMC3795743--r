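#' Construct an image volume
#'
#' A 3D scalar grid with world geometry: voxel centres sit at
#' `origin + direction %*% (spacing * index)` with 0-based indices, following
#' the NRRD/NIfTI header convention.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Positive length-3 numeric, mm per voxel along each axis.
#' @param origin Length-3 numeric, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix of axis direction cosines.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (any(dim(voxels) < 2L)) {
    stop("grid must have at least 2 voxels per axis", call. = FALSE)
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  }
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("`direction` must be a 3x3 orthonormal matrix", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' Construct a binary mask on an existing grid
#'
#' @param inside Logical 3D array (TRUE = object voxel).
#' @param geometry An `image_volume` or `binary_mask` supplying
#'   spacing/origin/direction, or NULL with explicit arguments.
#' @param spacing,origin,direction Grid geometry, used when `geometry` is NULL.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(inside, geometry = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.null(geometry)) {
    spacing <- geometry$spacing; origin <- geometry$origin
    direction <- geometry$direction
    if (!all(dim(inside) == dim(geometry$voxels))) {
      stop("mask dimensions do not match the reference grid", call. = FALSE)
    }
  }
  storage.mode(inside) <- "logical"
  structure(list(voxels = inside, spacing = spacing, origin = origin,
                 direction = direction),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume>", paste(dim(x$voxels), collapse = "x"),
      "spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", paste(dim(x$voxels), collapse = "x"), "-",
      sum(x$voxels), "voxels set\n")
  invisible(x)
}

#' Convert world coordinates to continuous 0-based voxel indices
#'
#' @param volume An `image_volume` or `binary_mask`.
#' @param points N x 3 matrix of world positions (mm).
#' @return N x 3 matrix of continuous voxel indices (0-based).
#' @export
world_to_index <- function(volume, points) {
  points <- rbind_points(points)
  rel <- sweep(points, 2L, volume$origin, "-") %*% volume$direction
  sweep(rel, 2L, volume$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param volume An `image_volume` or `binary_mask`.
#' @param index N x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @return N x 3 matrix of world positions (mm).
#' @export
index_to_world <- function(volume, index) {
  index <- rbind_points(index)
  sweep(sweep(index, 2L, volume$spacing, "*") %*% t(volume$direction),
        2L, volume$origin, "+")
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  stopifnot(ncol(p) == 3L)
  p
}

#' Is a world point strictly inside the sampled grid?
#'
#' A point is inside when its continuous index lies in `[0, dim - 1]` on all
#' axes, i.e. within the convex hull of voxel centres where interpolation is
#' defined.
#' @keywords internal
point_in_grid <- function(volume, points) {
  idx <- world_to_index(volume, points)
  d <- dim(volume$voxels)
  ok <- rep(TRUE, nrow(idx))
  for (a in 1:3) ok <- ok & idx[, a] >= 0 & idx[, a] <= d[a] - 1
  ok
}

#' Interpolate a volume at world positions
#'
#' @param volume An `image_volume`.
#' @param points N x 3 matrix of world positions (mm).
#' @param method `"nearest"` (value of the voxel containing the point) or
#'   `"linear"` (trilinear over the 8 surrounding voxel centres).
#' @return List with `values` (numeric, NA where out of bounds) and `oob`
#'   (logical).
#' @export
interp_volume <- function(volume, points, method = c("nearest", "linear")) {
  method <- match.arg(method)
  idx <- world_to_index(volume, points)
  d <- dim(volume$voxels)
  n <- nrow(idx)
  oob <- !point_in_grid(volume, points)
  values <- rep(NA_real_, n)
  ok <- which(!oob)
  if (length(ok)) {
    arr <- volume$voxels
    if (method == "nearest") {
      ijk <- round(idx[ok, , drop = FALSE])
      for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 0), d[a] - 1)
      values[ok] <- arr[cbind(ijk[, 1L] + 1, ijk[, 2L] + 1, ijk[, 3L] + 1)]
    } else {
      lo <- floor(idx[ok, , drop = FALSE])
      for (a in 1:3) lo[, a] <- pmin(pmax(lo[, a], 0), d[a] - 2)
      f <- idx[ok, , drop = FALSE] - lo
      f <- pmin(pmax(f, 0), 1)
      acc <- numeric(length(ok))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) f[, 1L] else 1 - f[, 1L]) *
             (if (dy) f[, 2L] else 1 - f[, 2L]) *
             (if (dz) f[, 3L] else 1 - f[, 3L])
        acc <- acc + w * arr[cbind(lo[, 1L] + dx + 1, lo[, 2L] + dy + 1,
                                   lo[, 3L] + dz + 1)]
      }
      values[ok] <- acc
    }
  }
  list(values = values, oob = oob)
}

#' Resolve a seed to world coordinates
#'
#' @param volume An `image_volume`.
#' @param seed Length-3 numeric position.
#' @param space `"world"` (mm) or `"voxel"` (0-based index).
#' @return Length-3 numeric world position (mm).
#' @export
resolve_seed <- function(volume, seed, space = c("world", "voxel")) {
  space <- match.arg(space)
  seed <- as.numeric(seed)
  if (length(seed) != 3L || any(!is.finite(seed))) {
    stop("seed must be 3 finite numbers", call. = FALSE)
  }
  pos <- if (space == "voxel") drop(index_to_world(volume, seed)) else seed
  if (!point_in_grid(volume, matrix(pos, ncol = 3L))) {
    stop("seed point lies outside the volume", call. = FALSE)
  }
  pos
}
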