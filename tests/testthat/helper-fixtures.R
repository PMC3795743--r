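# Small in-code fixtures shared across test files.

# volume whose intensity is an affine function a0 + g . x of world position
affine_volume <- function(dims = c(12L, 12L, 12L), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), direction = diag(3),
                          a0 = 5, g = c(0.5, -0.25, 1.25)) {
  geom <- image_volume(array(0, dims), spacing, origin, direction)
  idx <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                               0:(dims[3] - 1)))
  w <- index_to_world(geom, idx)
  vals <- a0 + as.vector(w %*% g)
  image_volume(array(vals, dims), spacing, origin, direction)
}

constant_volume <- function(value = 97, dims = c(10L, 10L, 10L),
                            spacing = c(1, 1, 1)) {
  image_volume(array(value, dims), spacing = spacing)
}

# independent exhaustive minimiser over all layer assignments (expand.grid),
# used as a from-first-principles check on tiny instances
enumerate_min <- function(cmat, pairs, delta) {
  R <- nrow(cmat); Z <- ncol(cmat)
  grids <- rep(list(seq_len(Z)), R)
  all_k <- as.matrix(do.call(expand.grid, grids))
  feas <- rep(TRUE, nrow(all_k))
  for (p in seq_len(nrow(pairs))) {
    feas <- feas & abs(all_k[, pairs[p, 1]] - all_k[, pairs[p, 2]]) <= delta
  }
  all_k <- all_k[feas, , drop = FALSE]
  tot <- apply(all_k, 1, function(k) sum(cmat[cbind(seq_len(R), k)]))
  min(tot)
}

random_cost_field <- function(template, Z, seed) {
  set.seed(seed)
  cost_field(matrix(runif(nrow(template$directions) * Z),
                    nrow(template$directions), Z), template)
}
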