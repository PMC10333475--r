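test_that("the extracted centerline of a straight tube is its axis", {
  m <- voxelize(straight_tube_arch(radius = 5), spacing = 0.5)
  cl <- extract_centerline(m)
  expect_lt(max(abs(cl$y)), 0.5)      # within one voxel of the axis
  expect_lt(max(abs(cl$z)), 0.5)
  expect_equal(mean(cl$radius), 5, tolerance = 0.15)
})

test_that("extraction recovers the arch centerline to sub-voxel accuracy", {
  arch <- build_arch(group_mean_params("gothic"))
  m <- voxelize(arch, spacing = 0.5)
  path <- extract_centerline(m)
  truth <- arch$centerline
  idx <- seq(1, nrow(path), by = 4)
  d <- vapply(idx, function(i)
    min(sqrt((truth$x - path$x[i])^2 + (truth$y - path$y[i])^2 +
               (truth$z - path$z[i])^2)), numeric(1))
  expect_lt(mean(d), 0.5)
  # endpoints preserved (snapped to the landmark-adjacent voxels)
  expect_lt(sqrt(sum((unlist(path[1, c("x", "y", "z")]) -
                        arch$landmarks$ascending_end$xyz)^2)), 1)
})

test_that("disconnected masks are rejected", {
  g <- array(0L, c(20, 10, 10))
  g[2:5, 4:6, 4:6] <- 1L
  g[14:18, 4:6, 4:6] <- 1L
  m <- voxel_mask(g, 0.5,
                  landmarks = list(ascending_end = list(xyz = c(1, 2, 2)),
                                   descending_end = list(xyz = c(8, 2, 2))))
  expect_error(extract_centerline(m), "components")
})
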