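test_that("mean grey value estimation averages the seed-centred cube, clipped to the grid", {
  vol <- constant_volume(97)
  expect_equal(estimate_mean(vol, c(5, 5, 5), 3), 97)

  # 3x3x3 neighbourhood holding 0..26
  arr <- array(100, c(9, 9, 9))
  arr[4:6, 4:6, 4:6] <- array(0:26, c(3, 3, 3))
  vol <- image_volume(arr)
  expect_equal(estimate_mean(vol, c(4, 4, 4), 1), 13)

  # seed at a corner voxel: only the 8 in-bounds voxels count
  arr <- array(0, c(6, 6, 6))
  arr[1:2, 1:2, 1:2] <- 1:8
  vol <- image_volume(arr)
  expect_equal(estimate_mean(vol, c(0, 0, 0), 1), mean(1:8))

  expect_error(estimate_mean(constant_volume(), c(50, 0, 0)), "outside")
})

test_that("ray samples sit at seed + z*step*direction and flag out-of-bounds", {
  tpl <- build_template(1)
  vol <- constant_volume(7, dims = c(10L, 10L, 10L))
  g <- sample_rays(vol, c(4.5, 4.5, 4.5), tpl, Z = 4, step = 1)
  expect_true(all(g$intensities[!g$oob] == 7))

  # trilinear sampling reproduces an affine intensity field exactly
  vol <- affine_volume(dims = c(14L, 14L, 14L), spacing = c(0.7, 1.1, 0.9))
  seed <- c(4.5, 6.2, 5.4)
  g <- sample_rays(vol, seed, tpl, Z = 3, step = 0.8, method = "linear")
  for (r in c(1L, 5L, 20L)) {
    for (z in 1:3) {
      if (!g$oob[r, z]) {
        p <- seed + z * 0.8 * tpl$directions[r, ]
        expect_equal(g$intensities[r, z], 5 + sum(p * c(0.5, -0.25, 1.25)),
                     tolerance = 1e-6)
      }
    }
  }

  # seed 1 mm from the boundary: outward rays leave the 10^3 grid quickly
  vol <- constant_volume(1, dims = c(10L, 10L, 10L))
  g <- sample_rays(vol, c(1, 4.5, 4.5), tpl, Z = 5, step = 1)
  outward <- which(tpl$directions[, 1] < -0.9)
  expect_true(all(g$oob[outward, 2:5]))
  expect_error(sample_rays(vol, c(-3, 0, 0), tpl), "outside")
  expect_error(sample_rays(vol, c(4, 4, 4), tpl, Z = 1), "Z")
  expect_error(sample_rays(vol, c(4, 4, 4), tpl, step = 0), "step")
})

test_that("node costs are absolute deviations from the mean, with a dominating OOB cost", {
  tpl <- build_template(0)
  vol <- constant_volume(100, dims = c(40L, 40L, 40L))
  g <- sample_rays(vol, c(20, 20, 20), tpl, Z = 5, step = 1)
  cf <- compute_costs(g, 100)
  expect_true(all(cf$c == 0))
  cf <- compute_costs(g, 88)
  expect_true(all(cf$c == 12))

  # oob nodes cost more than any attainable in-bounds cost; with sampled
  # intensities spanning roughly [0, 255] and mean 100 the constant clears 155
  dims <- c(40L, 40L, 40L)
  grad <- array(rep(255 * (0:39) / 39, times = 40 * 40), dims)
  vol <- image_volume(grad)
  g <- sample_rays(vol, c(20, 20, 20), tpl, Z = 30, step = 1)
  cf <- compute_costs(g, 100)
  expect_true(any(g$oob))
  expect_gt(cf$oob_cost, 155)
  expect_true(all(cf$c[g$oob] > max(cf$c[!g$oob])))
})

test_that("costs are invariant under a common intensity shift", {
  tpl <- build_template(1)
  ph <- make_phantom(radius = 6, dims = c(24L, 24L, 24L), noise_sd = 3,
                     rng_seed = 9)
  g1 <- sample_rays(ph$volume, ph$center, tpl, Z = 8, step = 1)
  shifted <- ph$volume
  shifted$voxels <- shifted$voxels + 500
  g2 <- sample_rays(shifted, ph$center, tpl, Z = 8, step = 1)
  c1 <- compute_costs(g1, 150)
  c2 <- compute_costs(g2, 650)
  expect_equal(c1$c, c2$c, tolerance = 1e-12)
})

test_that("a radially symmetric smooth field gives ray-independent costs", {
  dims <- c(41L, 41L, 41L)
  geom <- image_volume(array(0, dims))
  idx <- as.matrix(expand.grid(0:40, 0:40, 0:40))
  rho <- sqrt(rowSums(sweep(idx, 2, c(20, 20, 20))^2))
  vol <- image_volume(array(100 + rho^2, dims))  # quadratic radial field
  tpl <- build_template(2)
  g <- sample_rays(vol, c(20, 20, 20), tpl, Z = 6, step = 1,
                   method = "linear")
  cf <- compute_costs(g, 100)
  # per-layer spread across rays stays small relative to the layer cost
  for (z in 1:6) {
    spread <- diff(range(cf$c[, z]))
    expect_lt(spread, 1.5)  # interpolation error bound on this phantom
  }
})
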