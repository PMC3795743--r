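make_surface <- function(k, grid) {
  structure(list(k = as.integer(k), total_cost = 0,
                 delta_r = 0L, Z = grid$Z),
            class = "cut_surface")
}

test_that("mesh vertices sit at the cut radii along their rays", {
  tpl <- build_template(0)
  vol <- constant_volume(1, dims = c(30L, 30L, 30L))
  seed <- c(15, 15, 15)
  g <- sample_rays(vol, seed, tpl, Z = 10, step = 0.5)
  s <- make_surface(rep(6L, 12), g)
  mesh <- surface_to_mesh(s, g)
  expect_identical(dim(mesh$vertices), c(12L, 3L))
  expect_identical(mesh$triangles, tpl$triangles)
  radii <- sqrt(rowSums(sweep(mesh$vertices, 2, seed)^2))
  expect_equal(radii, rep(6 * 0.5, 12), tolerance = 1e-12)

  # varying k: vertex r at distance k[r]*step
  k <- rep(c(5L, 6L), 6)
  mesh <- surface_to_mesh(make_surface(k, g), g)
  radii <- sqrt(rowSums(sweep(mesh$vertices, 2, seed)^2))
  expect_equal(radii, k * 0.5, tolerance = 1e-12)
})

test_that("a constant-radius surface voxelizes to a ball of the analytic volume", {
  tpl <- build_template(3)
  vol <- constant_volume(1, dims = c(40L, 40L, 40L))
  seed <- c(19.5, 19.5, 19.5)
  g <- sample_rays(vol, seed, tpl, Z = 15, step = 1)
  s <- make_surface(rep(12L, nrow(tpl$directions)), g)
  mask <- voxelize(s, g, vol)
  n <- mask_volume(mask)$voxels
  expect_lt(abs(n - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.05)

  # no voxel outside the ball (convexity up to voxelization)
  idx <- which(mask$voxels, arr.ind = TRUE) - 1
  ctr <- index_to_world(vol, idx)
  rho <- sqrt(rowSums(sweep(ctr, 2, seed)^2))
  expect_lte(max(rho), 12 + 1e-6)

  # seed voxel always inside
  seed_idx <- round(drop(world_to_index(vol, seed))) + 1
  expect_true(mask$voxels[seed_idx[1], seed_idx[2], seed_idx[3]])
})

test_that("masked voxels stay within the maximum cut radius plus a voxel diagonal", {
  tpl <- build_template(2)
  vol <- constant_volume(1, dims = c(36L, 36L, 36L))
  seed <- c(17, 17, 17)
  g <- sample_rays(vol, seed, tpl, Z = 12, step = 1)
  set.seed(5)
  base <- sample(7:9, 1)
  k <- pmax(1L, pmin(12L, base + sample(-1:1, nrow(tpl$directions),
                                        replace = TRUE)))
  s <- make_surface(k, g)
  mask <- voxelize(s, g, vol)
  idx <- which(mask$voxels, arr.ind = TRUE) - 1
  ctr <- index_to_world(vol, idx)
  rho <- sqrt(rowSums(sweep(ctr, 2, seed)^2))
  expect_lte(max(rho), max(k) * 1 + sqrt(3))

  # mesh vertices lie on the mask boundary within one voxel diagonal
  mesh <- surface_to_mesh(s, g)
  vr <- sqrt(rowSums(sweep(mesh$vertices, 2, seed)^2))
  expect_true(all(vr <= max(rho) + sqrt(3)))
})

test_that("voxelization honours anisotropic spacing", {
  tpl <- build_template(2)
  vol <- image_volume(array(1, c(60L, 60L, 24L)), spacing = c(0.5, 0.5, 1.5))
  seed <- c(14.75, 14.75, 17.25)
  g <- sample_rays(vol, seed, tpl, Z = 20, step = 0.5)
  s <- make_surface(rep(16L, nrow(tpl$directions)), g)  # radius 8 mm
  mask <- voxelize(s, g, vol)
  v <- mask_volume(mask)
  expect_equal(v$mm3, v$voxels * 0.5 * 0.5 * 1.5)
  expect_lt(abs(v$mm3 - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.1)
})

test_that("mismatched surface and grid are rejected", {
  tpl <- build_template(0)
  vol <- constant_volume(1, dims = c(20L, 20L, 20L))
  g <- sample_rays(vol, c(10, 10, 10), tpl, Z = 5, step = 1)
  bad <- structure(list(k = rep(2L, 42), total_cost = 0, delta_r = 0L,
                        Z = 5L),
                   class = "cut_surface")
  expect_error(surface_to_mesh(bad, g), "different configurations")
  expect_error(voxelize(bad, g, vol), "different configurations")
})
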