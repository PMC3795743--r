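test_that("node weights telescope the cost field", {
  tpl <- build_template(0)
  cf <- cost_field(matrix(c(5, 3, 7), 12, 3, byrow = TRUE), tpl)
  w <- node_weights(cf)
  expect_equal(unname(w$w[1, ]), c(5, -2, 4))

  # constant along a ray -> base weight then zeros
  cfc <- cost_field(matrix(4.2, 12, 5), tpl)
  wc <- node_weights(cfc)
  expect_true(all(wc$w[, 1] == 4.2))
  expect_true(all(wc$w[, -1] == 0))

  # prefix sums reproduce arbitrary cost fields (property fuzz)
  set.seed(11)
  for (i in 1:25) {
    Z <- sample(2:9, 1)
    cm <- matrix(runif(12 * Z, 0, 100), 12, Z)
    w <- node_weights(cost_field(cm, tpl))$w
    expect_lt(max(abs(t(apply(w, 1, cumsum)) - cm)), 1e-9)
  }
})

test_that("graph arc counts match the construction", {
  tpl <- build_template(0)
  cf <- cost_field(matrix(runif(48), 12, 4), tpl)
  g <- build_graph(node_weights(cf), tpl, delta_r = 1)
  E <- nrow(tpl$neighbor_pairs)
  caps <- igraph::E(g$graph)$capacity
  n_big <- sum(caps == g$big)
  # A_z (12*3) + A_r (2*30*4) + base (12) all carry the BIG capacity
  expect_identical(n_big, 12L * 3L + 2L * E * 4L + 12L)
  # each node has at most one finite terminal arc
  n_term <- igraph::ecount(g$graph) - n_big
  expect_lte(n_term, 12L * 4L)
  expect_error(build_graph(node_weights(cf), tpl, delta_r = -1),
               "non-negative")
})

test_that("delta_r = 0 arcs connect equal layers and force a common boundary layer", {
  tpl <- build_template(0)
  set.seed(3)
  for (i in 1:10) {
    cm <- matrix(runif(12 * 6), 12, 6)
    cf <- cost_field(cm, tpl)
    s <- min_cut_surface(build_graph(node_weights(cf), tpl, 0), cf)
    expect_length(unique(s$k), 1L)
    expect_identical(unique(s$k), which.min(colSums(cm)))
    expect_equal(s$total_cost, min(colSums(cm)), tolerance = 1e-9)
  }
})

test_that("min-cut agrees with independent exhaustive enumeration on a 3-ray chain", {
  # three mutually adjacent rays: use three icosahedron rays forming a triangle
  tpl <- build_template(0)
  tri <- tpl$triangles[1, ]
  sub <- list(directions = tpl$directions[tri, ],
              triangles = matrix(1:3, 1, 3),
              neighbor_pairs = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
              subdivision_level = 0L)
  class(sub) <- "spherical_template"
  set.seed(123)
  cm <- matrix(runif(9), 3, 3)
  cf <- cost_field(cm, sub)
  s <- min_cut_surface(build_graph(node_weights(cf), sub, 1), cf)
  expect_equal(s$total_cost,
               enumerate_min(cm, sub$neighbor_pairs, 1),
               tolerance = 1e-9)
  b <- brute_force_surface(cf, sub, 1)
  expect_equal(b$total_cost, s$total_cost, tolerance = 1e-9)
  expect_identical(b$k, s$k)
})

test_that("zero costs give the outermost surface under maximal tie-breaking", {
  tpl <- build_template(0)
  cf <- cost_field(matrix(0, 12, 4), tpl)
  for (d in c(0L, 2L)) {
    s <- min_cut_surface(build_graph(node_weights(cf), tpl, d), cf)
    expect_true(all(s$k == 4L))
    expect_equal(s$total_cost, 0)
  }
  b <- brute_force_surface(cf, tpl, 1)
  expect_true(all(b$k == 4L))
})

test_that("min-cut equals the brute-force oracle and satisfies feasibility", {
  tpl <- build_template(0)
  seed_i <- 0L
  for (Z in 3:5) {
    for (d in 0:2) {
      for (rep in 1:4) {
        seed_i <- seed_i + 1L
        cf <- random_cost_field(tpl, Z, seed = 1000L + seed_i)
        s <- min_cut_surface(build_graph(node_weights(cf), tpl, d), cf)
        b <- brute_force_surface(cf, tpl, d)
        expect_equal(s$total_cost, b$total_cost, tolerance = 1e-9)
        expect_identical(s$k, b$k)
        expect_true(surface_is_feasible(s, tpl))
      }
    }
  }
})

test_that("unconstrained brute force reduces to per-ray minima with outermost ties", {
  tpl <- build_template(0)
  cm <- matrix(runif(12 * 4), 12, 4)
  cm[3, ] <- c(0.5, 0.1, 0.9, 0.1)  # tie on the minimum
  b <- brute_force_surface(cost_field(cm, tpl), tpl, delta_r = 4)
  expect_identical(b$k[3], 4L)
  expect_equal(b$total_cost, sum(apply(cm, 1, min)), tolerance = 1e-12)
})

test_that("total cost is non-increasing in delta_r and scales linearly with costs", {
  tpl <- build_template(0)
  set.seed(77)
  for (rep in 1:5) {
    cm <- matrix(runif(12 * 5), 12, 5)
    cf <- cost_field(cm, tpl)
    w <- node_weights(cf)
    costs_by_d <- vapply(c(0L, 1L, 2L, 5L), function(d) {
      min_cut_surface(build_graph(w, tpl, d), cf)$total_cost
    }, numeric(1))
    expect_true(all(diff(costs_by_d) <= 1e-9))

    # scale equivariance
    lam <- 3.7
    cf2 <- cost_field(lam * cm, tpl)
    s1 <- min_cut_surface(build_graph(node_weights(cf), tpl, 1), cf)
    s2 <- min_cut_surface(build_graph(node_weights(cf2), tpl, 1), cf2)
    expect_equal(s2$total_cost, lam * s1$total_cost, tolerance = 1e-9)
    expect_identical(s2$k, s1$k)
  }
})
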