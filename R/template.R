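#' Build a spherical template (icosphere)
#'
#' Constructs the spherical polyhedron whose surface points define the ray
#' directions of the segmentation graph. Starting from a regular icosahedron
#' in the canonical golden-ratio orientation, each triangle is subdivided
#' `subdivision_level` times (every edge midpoint projected back to the unit
#' sphere), giving `10 * 4^n + 2` near-uniformly distributed unit directions.
#' Two rays are neighbours when their vertices share a triangle edge.
#'
#' Construction is fully deterministic: the same `subdivision_level` always
#' yields a bitwise-identical template, so ray indices are stable across runs.
#'
#' @param subdivision_level Non-negative integer number of recursive
#'   subdivisions (0 = plain icosahedron with 12 rays; default 3 = 642 rays).
#'   Capped at 6 since ray counts grow as `4^n`.
#' @return An object of class `spherical_template` with elements
#'   \describe{
#'     \item{directions}{`R x 3` matrix of unit ray directions.}
#'     \item{triangles}{`F x 3` integer matrix of vertex indices (1-based).}
#'     \item{neighbor_pairs}{`E x 2` integer matrix, each row an unordered
#'       ray pair sharing a triangle edge, with `pair[1] < pair[2]`.}
#'     \item{subdivision_level}{the level used.}
#'   }
#' @examples
#' tpl <- build_template(0)
#' nrow(tpl$directions)  # 12
#' @export
build_template <- function(subdivision_level = 3L) {
  if (length(subdivision_level) != 1L || is.na(subdivision_level) ||
      subdivision_level != round(subdivision_level) || subdivision_level < 0) {
    stop("`subdivision_level` must be a single non-negative integer",
         call. = FALSE)
  }
  if (subdivision_level > 6) {
    stop("`subdivision_level` > 6 is not supported (ray count grows as 4^n)",
         call. = FALSE)
  }
  n <- as.integer(subdivision_level)

  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c( 1,  phi, 0), c(-1, -phi, 0), c( 1, -phi, 0),
    c(0, -1,  phi), c(0,  1,  phi), c(0, -1, -phi), c(0,  1, -phi),
    c( phi, 0, -1), c( phi, 0,  1), c(-phi, 0, -1), c(-phi, 0,  1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- 1L + rbind(
    c(0L, 11L, 5L), c(0L, 5L, 1L), c(0L, 1L, 7L), c(0L, 7L, 10L),
    c(0L, 10L, 11L), c(1L, 5L, 9L), c(5L, 11L, 4L), c(11L, 10L, 2L),
    c(10L, 7L, 6L), c(7L, 1L, 8L), c(3L, 9L, 4L), c(3L, 4L, 2L),
    c(3L, 2L, 6L), c(3L, 6L, 8L), c(3L, 8L, 9L), c(4L, 9L, 5L),
    c(2L, 4L, 11L), c(6L, 2L, 10L), c(8L, 6L, 7L), c(9L, 8L, 1L)
  )

  if (n > 0) {
    for (level in seq_len(n)) {
      nv <- nrow(verts)
      # midpoint cache keyed by the ordered vertex pair; iteration order over
      # faces is fixed, so new-vertex indices are deterministic
      cache <- new.env(hash = TRUE, parent = emptyenv())
      extra <- vector("list", nrow(faces) * 3L)
      n_extra <- 0L
      midpoint <- function(a, b) {
        key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
        idx <- cache[[key]]
        if (!is.null(idx)) return(idx)
        m <- verts[a, ] + verts[b, ]
        m <- m / sqrt(sum(m^2))
        n_extra <<- n_extra + 1L
        extra[[n_extra]] <<- m
        idx <- nv + n_extra
        cache[[key]] <- idx
        idx
      }
      new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
      for (f in seq_len(nrow(faces))) {
        v1 <- faces[f, 1L]; v2 <- faces[f, 2L]; v3 <- faces[f, 3L]
        a <- midpoint(v1, v2); b <- midpoint(v2, v3); c <- midpoint(v3, v1)
        new_faces[4L * f - 3L, ] <- c(v1, a, c)
        new_faces[4L * f - 2L, ] <- c(v2, b, a)
        new_faces[4L * f - 1L, ] <- c(v3, c, b)
        new_faces[4L * f, ] <- c(a, b, c)
      }
      verts <- rbind(verts, do.call(rbind, extra[seq_len(n_extra)]))
      faces <- new_faces
    }
  }

  edges <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  storage.mode(faces) <- "integer"
  dimnames(verts) <- NULL

  structure(
    list(directions = verts, triangles = faces, neighbor_pairs = edges,
         subdivision_level = n),
    class = "spherical_template"
  )
}

#' Neighbouring rays of a ray
#'
#' Rays are neighbours when their template vertices share a triangle edge
#' (i.e. belong to a common triangle of the icosphere triangulation). The
#' relation is symmetric; original icosahedron vertices have 5 neighbours,
#' subdivision-created vertices have 6.
#'
#' @param template A `spherical_template`.
#' @param r 1-based ray index.
#' @return Sorted integer vector of neighbouring ray indices.
#' @export
neighbors_of <- function(template, r) {
  stopifnot(inherits(template, "spherical_template"))
  R <- nrow(template$directions)
  if (length(r) != 1L || is.na(r) || r != round(r) || r < 1L || r > R) {
    stop("ray index out of range [1, ", R, "]", call. = FALSE)
  }
  e <- template$neighbor_pairs
  sort(unique(c(e[e[, 1L] == r, 2L], e[e[, 2L] == r, 1L])))
}

#' Adjacency list of a template
#'
#' @param template A `spherical_template`.
#' @return List of length `R`; element `r` holds the neighbour indices of ray `r`.
#' @keywords internal
template_adjacency <- function(template) {
  R <- nrow(template$directions)
  adj <- vector("list", R)
  e <- template$neighbor_pairs
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1L]; b <- e[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

#' @export
print.spherical_template <- function(x, ...) {
  cat("<spherical_template> level", x$subdivision_level, "-",
      nrow(x$directions), "rays,", nrow(x$triangles), "triangles,",
      nrow(x$neighbor_pairs), "edges\n")
  invisible(x)
}
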