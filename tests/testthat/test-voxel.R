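test_that("a voxelized cylinder has the right inscribed diameter", {
  m <- voxelize(straight_tube_arch(radius = 5), spacing = 0.5)
  dt <- coarckit:::cpp_edt(as.integer(m$grid), dim(m$grid), m$spacing)
  expect_lt(abs(2 * max(dt) - 10), 2 * 0.5)   # within one voxel
  lab <- coarckit:::cpp_components6(as.integer(m$grid), dim(m$grid))
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("too-coarse spacing is rejected with advice", {
  expect_error(voxelize(straight_tube_arch(radius = 4), spacing = 10),
               "spacing")
})

test_that("landmark world coordinates survive voxelization unchanged", {
  arch <- build_arch(group_mean_params("gothic"))
  m <- voxelize(arch, spacing = 0.6)
  for (nm in names(arch$landmarks))
    expect_identical(m$landmarks[[nm]]$xyz, arch$landmarks[[nm]]$xyz)
})

test_that("masks round-trip through NIfTI bit-exactly", {
  set.seed(5)
  g <- array(0L, c(16, 16, 16))
  g[sample(length(g), 300)] <- 1L
  # keep one voxel-connected component irrelevant here; IO only
  m <- voxel_mask(g, spacing = c(0.4, 0.4, 0.8), origin = c(-3, 2, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_mask(m, f, landmark_path = NA)
  m2 <- read_mask(f)
  expect_identical(m2$grid, m$grid)
  expect_equal(m2$spacing, c(0.4, 0.4, 0.8))
  expect_equal(m2$origin, c(-3, 2, 1))
})

test_that("non-binary volumes are rejected", {
  expect_error(voxel_mask(array(2L, c(4, 4, 4)), 0.5), "binary")
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(seq_len(64) / 10, c(4, 4, 4)))
  RNifti::writeNifti(img, f)
  expect_error(read_mask(f), "binary")
})

test_that("centerline CSV and landmark JSON round-trip", {
  arch <- build_arch(group_mean_params("romanesque"))
  f <- tempfile(fileext = ".csv")
  write_centerline(arch, f)
  back <- read_centerline(f)
  expect_equal(back$centerline$x, arch$centerline$x, tolerance = 1e-12)
  expect_equal(back$centerline$radius, arch$centerline$radius,
               tolerance = 1e-12)
  expect_equal(back$landmarks$arch_apex$xyz, arch$landmarks$arch_apex$xyz,
               tolerance = 1e-12)
})
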