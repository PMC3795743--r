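#' Terminal node weights from a cost field
#'
#' Telescopes the per-ray costs into s-t edge weights: the innermost node of
#' a ray carries its full cost, every other node carries the difference to
#' the next node inward, so that the prefix sum of weights along a ray
#' reproduces the cost of the outermost retained node. This makes the total
#' weight of a closed set equal to the cost of its upper envelope (the
#' candidate surface).
#'
#' @param costs A `cost_field`.
#' @return An object of class `node_weights`: list with `w` (R x Z matrix)
#'   and the originating `costs`.
#' @export
node_weights <- function(costs) {
  stopifnot(inherits(costs, "cost_field"))
  cmat <- costs$c
  w <- cmat
  if (ncol(cmat) > 1L) {
    w[, -1L] <- cmat[, -1L, drop = FALSE] -
      cmat[, -ncol(cmat), drop = FALSE]
  }
  structure(list(w = w, costs = costs), class = "node_weights")
}

#' Build the s-t segmentation graph
#'
#' Nodes are the `R x Z` ray samples plus a source `s` and sink `t`. Arcs:
#' \describe{
#'   \item{A_z (intra-ray)}{`(r,z) -> (r,z-1)` for `z >= 2`, infinite
#'     capacity: retaining a node forces all deeper nodes on its ray into the
#'     set, so retained sets are closed and the object interior is connected
#'     to the seed.}
#'   \item{A_r (inter-ray)}{`(r,z) -> (r', max(1, z - delta_r))` for every
#'     neighbouring ray pair, both directions, infinite capacity: the
#'     boundary indices of neighbouring rays may differ by at most `delta_r`
#'     (stiffness; `delta_r = 0` forces a sphere).}
#'   \item{base}{`s -> (r,1)`, infinite capacity: the innermost layer is
#'     always part of the object (the seed lies inside it).}
#'   \item{terminal}{`s -> (r,z)` with capacity `-w` when the node weight `w`
#'     is negative, else `(r,z) -> t` with capacity `w`.}
#' }
#' Infinite capacities are realised as a finite constant `BIG = sum(|w|) + 1`
#' which provably never saturates.
#'
#' @param weights A `node_weights`.
#' @param template The `spherical_template` the costs were sampled on.
#' @param delta_r Non-negative integer smoothness parameter (default 2).
#' @return An object of class `seg_graph` wrapping an igraph directed graph
#'   with a `capacity` edge attribute, node bookkeeping and `delta_r`.
#' @export
build_graph <- function(weights, template, delta_r = 2L) {
  stopifnot(inherits(weights, "node_weights"),
            inherits(template, "spherical_template"))
  if (length(delta_r) != 1L || is.na(delta_r) || delta_r < 0 ||
      delta_r != round(delta_r)) {
    stop("`delta_r` must be a single non-negative integer", call. = FALSE)
  }
  w <- weights$w
  R <- nrow(w); Z <- ncol(w)
  if (R != nrow(template$directions)) {
    stop("weights and template disagree on the number of rays", call. = FALSE)
  }
  delta_r <- as.integer(delta_r)
  big <- sum(abs(w)) + 1

  # vertex ids: 1 = s, 2 = t, node (r,z) = 2 + (r-1)*Z + z   (r, z 1-based)
  nid <- function(r, z) 2L + (r - 1L) * Z + z
  n_vertices <- 2L + R * Z

  rr <- rep(seq_len(R), each = Z - 1L)
  zz <- rep(2:Z, times = R)
  az_from <- nid(rr, zz)
  az_to <- nid(rr, zz - 1L)

  e <- template$neighbor_pairs
  pr <- c(e[, 1L], e[, 2L])
  ps <- c(e[, 2L], e[, 1L])
  zr <- rep(seq_len(Z), times = length(pr))
  ar_from <- nid(rep(pr, each = Z), zr)
  ar_to <- nid(rep(ps, each = Z), pmax(1L, zr - delta_r))

  base_to <- nid(seq_len(R), 1L)

  wt <- as.vector(t(w))            # ray-major: (r,z) at (r-1)*Z + z
  node_ids <- 2L + seq_len(R * Z)
  neg <- wt < 0
  term_from <- c(rep(1L, sum(neg)), node_ids[!neg & wt != 0])
  term_to <- c(node_ids[neg], rep(2L, sum(!neg & wt != 0)))
  term_cap <- c(-wt[neg], wt[!neg & wt != 0])

  from <- c(az_from, ar_from, rep(1L, R), term_from)
  to <- c(az_to, ar_to, base_to, term_to)
  cap <- c(rep(big, length(az_from) + length(ar_from) + R), term_cap)

  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n_vertices,
                          directed = TRUE)
  igraph::E(g)$capacity <- cap

  structure(list(graph = g, R = R, Z = Z, delta_r = delta_r, big = big,
                 s = 1L, t = 2L, weights = weights),
            class = "seg_graph")
}

#' Extract the optimal cut surface by s-t minimum cut
#'
#' Computes a maximum flow from source to sink; the minimum-cost closed set
#' is the source side of the minimum cut. Among equally cheap closed sets
#' the MAXIMAL one is returned (a node is retained unless the sink is still
#' reachable from it through unsaturated residual arcs), which on cost
#' plateaus — homogeneous object interiors — places the boundary at the
#' outermost optimal layer. The per-ray boundary index `k[r]` is the
#' outermost retained layer of ray `r` (1-based; the base layer is always
#' retained, so `k[r] >= 1`).
#'
#' @param graph A `seg_graph` from [build_graph()].
#' @param costs The `cost_field` the graph was built from (used to report
#'   the surface cost).
#' @return An object of class `cut_surface`: list with `k` (length-R integer,
#'   1-based layer indices), `total_cost` (= sum of `c[r, k[r]]`, the minimum
#'   over all feasible surfaces), `delta_r` and `Z`.
#' @export
min_cut_surface <- function(graph, costs = NULL) {
  stopifnot(inherits(graph, "seg_graph"))
  if (is.null(costs)) costs <- graph$weights$costs
  g <- graph$graph
  R <- graph$R; Z <- graph$Z
  fl <- igraph::max_flow(g, source = graph$s, target = graph$t,
                         capacity = igraph::E(g)$capacity)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  capv <- igraph::E(g)$capacity
  flow <- fl$flow
  # residual arcs: forward where spare capacity remains, backward where
  # positive flow can be cancelled (tolerance guards float arithmetic)
  eps <- 1e-9 * max(1, graph$big)
  fwd <- flow < capv - eps
  bwd <- flow > eps
  res_from <- c(ends[fwd, 1L], ends[bwd, 2L])
  res_to <- c(ends[fwd, 2L], ends[bwd, 1L])
  res <- igraph::make_graph(as.vector(rbind(res_from, res_to)),
                            n = igraph::vcount(g), directed = TRUE)
  # sink side of the maximal source set = vertices that still reach t
  reach_t <- as.integer(igraph::subcomponent(res, v = graph$t, mode = "in"))
  retained <- setdiff(seq_len(igraph::vcount(g)), reach_t)

  node_retained <- matrix(FALSE, nrow = R, ncol = Z)
  nodes <- retained[retained > 2L] - 2L
  r_of <- (nodes - 1L) %/% Z + 1L
  z_of <- (nodes - 1L) %% Z + 1L
  node_retained[cbind(r_of, z_of)] <- TRUE

  k <- apply(node_retained, 1L, function(row) max(which(row)))
  if (any(!node_retained[, 1L])) {
    stop("internal error: base layer escaped the closed set", call. = FALSE)
  }
  total <- sum(costs$c[cbind(seq_len(R), k)])
  structure(list(k = as.integer(k), total_cost = total,
                 delta_r = graph$delta_r, Z = Z),
            class = "cut_surface")
}

#' Exhaustive-search reference for the optimal cut surface
#'
#' Independent oracle for [min_cut_surface()]: enumerates boundary-index
#' assignments satisfying `|k[r] - k[r']| <= delta_r` on every neighbouring
#' ray pair by depth-first search over the rays (breadth-first vertex order,
#' infeasible prefixes pruned, optional cost bound), and returns an
#' assignment minimising the summed boundary cost. Ties are broken towards
#' the lexicographically largest `k`, which for this problem coincides with
#' the componentwise-maximal optimum returned by the min-cut route.
#'
#' Only small instances are accepted; the guard bounds the worst-case DFS
#' workload.
#'
#' @param costs A `cost_field`.
#' @param template The matching `spherical_template`.
#' @param delta_r Non-negative integer smoothness parameter.
#' @return A `cut_surface` (same shape as [min_cut_surface()]'s result).
#' @export
brute_force_surface <- function(costs, template, delta_r) {
  stopifnot(inherits(costs, "cost_field"),
            inherits(template, "spherical_template"))
  cmat <- costs$c
  R <- nrow(cmat); Z <- ncol(cmat)
  if (R != nrow(template$directions)) {
    stop("cost rows must match the template's ray count", call. = FALSE)
  }
  if (delta_r < 0 || delta_r != round(delta_r)) {
    stop("`delta_r` must be a non-negative integer", call. = FALSE)
  }
  delta_r <- as.integer(delta_r)

  if (delta_r >= Z - 1L) {
    # constraint vacuous: per-ray independent minima, largest index on ties
    k <- apply(cmat, 1L, function(row) max(which(row == min(row))))
    k <- as.integer(k)
    return(structure(list(k = k,
                          total_cost = sum(cmat[cbind(seq_len(R), k)]),
                          delta_r = delta_r, Z = Z),
                     class = "cut_surface"))
  }

  branch <- min(Z, 2L * delta_r + 1L)
  workload <- Z * branch^(R - 1)
  if (Z^R > 1e7 && workload > 1e10) {
    stop("instance too large for exhaustive search", call. = FALSE)
  }

  adj <- template_adjacency(template)
  res <- bf_surface_cpp(cmat, adj, delta_r)
  structure(list(k = as.integer(res$k), total_cost = res$total_cost,
                 delta_r = delta_r, Z = Z),
            class = "cut_surface")
}

#' Check the smoothness constraint of a cut surface
#'
#' @param surface A `cut_surface`.
#' @param template The matching `spherical_template`.
#' @return TRUE when `|k[r] - k[r']| <= delta_r` holds on every edge.
#' @export
surface_is_feasible <- function(surface, template) {
  e <- template$neighbor_pairs
  all(abs(surface$k[e[, 1L]] - surface$k[e[, 2L]]) <= surface$delta_r)
}

#' @export
print.cut_surface <- function(x, ...) {
  cat("<cut_surface>", length(x$k), "rays, layers",
      min(x$k), "-", max(x$k), "of", x$Z,
      ", total cost", signif(x$total_cost, 6), "\n")
  invisible(x)
}
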