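test_that("generator round trip recovers all quantities on random arches", {
  # the module's core oracle: 100 random feasible parameter sets
  set.seed(101)
  n_ok <- 0
  while (n_ok < 100) {
    p <- try(arch_params(
      arch_type = sample(c("gothic", "crenel", "romanesque"), 1),
      height_A = runif(1, 20, 42), width_T = runif(1, 42, 60),
      aao_dao_angle = runif(1, 12, 45),
      tao_dao_angle = runif(1, 100, 122),
      level_diameters = c(AOA = 12, D1 = runif(1, 6, 9),
                          D2 = runif(1, 5.5, 8), D3 = runif(1, 3, 7),
                          D4 = runif(1, 7, 9.5), D5 = runif(1, 6.5, 9))),
      silent = TRUE)
    arch <- try(build_arch(p), silent = TRUE)
    if (inherits(arch, "try-error")) next
    n_ok <- n_ok + 1
    m <- measure_arch(arch)
    expect_equal(m$height_A, p$height_A, tolerance = 1e-6)
    expect_equal(m$width_T, p$width_T, tolerance = 1e-6)
    expect_equal(m$at_ratio, p$height_A / p$width_T, tolerance = 1e-6)
    expect_equal(m$aao_dao_angle, p$aao_dao_angle, tolerance = 1e-6)
    expect_equal(m$tao_dao_angle, p$tao_dao_angle, tolerance = 1e-6)
    expect_equal(unname(m$diameters), unname(p$level_diameters),
                 tolerance = 1e-6)
  }
})

test_that("level diameters at the group means give the published ratios", {
  p <- arch_params(level_diameters = c(AOA = 12, D1 = 7.6, D2 = 6.5,
                                       D3 = 3.5, D4 = 8.5, D5 = 7.7))
  d <- measure_diameters(build_arch(p))
  expect_equal(unname(d[["AOA"]]), 12, tolerance = 1e-9)
  expect_equal(unname(d[["D3"]]), 3.5, tolerance = 1e-9)
  # constant-radius tube: every level identical
  du <- measure_diameters(
    build_arch(arch_params(level_diameters = c(AOA = 8, D1 = 8, D2 = 8,
                                               D3 = 8, D4 = 8, D5 = 8))))
  expect_true(all(abs(du - 8) < 1e-9))
})

test_that("morphometry is invariant to rigid motion and scaling", {
  arch <- build_arch(group_mean_params("gothic"))
  g0 <- compute_arch_geometry(arch)
  m0 <- measure_arch(arch$centerline, arch$landmarks, window = 2.5)
  th <- 0.73; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(xy, k = 1) as.numeric(k * (R %*% xy)) + c(17, -40)
  cl <- arch$centerline
  for (k in c(1, 2.5)) {
    xy <- t(apply(cbind(cl$x, cl$y), 1, move, k = k))
    cl_k <- data.frame(s = cl$s * k, x = xy[, 1], y = xy[, 2], z = 0,
                       radius = cl$radius * k)
    lm_k <- lapply(arch$landmarks, function(l)
      list(xyz = c(move(l$xyz[1:2], k), 0), s = l$s * k))
    g <- compute_arch_geometry(cl_k, lm_k)
    expect_equal(g$at_ratio, g0$at_ratio, tolerance = 1e-9)
    expect_equal(g$aao_dao_angle, g0$aao_dao_angle, tolerance = 1e-9)
    expect_equal(g$tao_dao_angle, g0$tao_dao_angle, tolerance = 1e-9)
    expect_equal(g$height_A, k * g0$height_A, tolerance = 1e-9)
    m <- measure_arch(cl_k, lm_k, window = 2.5 * k)
    expect_equal(unname(m$ratios), unname(m0$ratios), tolerance = 1e-6)
    expect_identical(m$arch_class, m0$arch_class)
    expect_identical(m$haa_flags, m0$haa_flags)
  }
})

test_that("raising the arch at fixed width strictly raises measured A/T", {
  at <- vapply(seq(22, 38, by = 4), function(A)
    compute_arch_geometry(build_arch(
      arch_params(height_A = A, width_T = 50,
                  tao_dao_angle = 103)))$at_ratio, numeric(1))
  expect_true(all(diff(at) > 0))
})

test_that("classification has exactly two breakpoints at 0.6 and 0.8", {
  expect_identical(classify_arch(0.85), "gothic")
  expect_identical(classify_arch(0.70148), "romanesque")
  expect_identical(classify_arch(0.49028), "crenel")
  # boundary values fall in the middle class
  expect_identical(classify_arch(c(0.6, 0.8)),
                   c("romanesque", "romanesque"))
  expect_identical(classify_arch(c(0.5999999, 0.8000001)),
                   c("crenel", "gothic"))
  # piecewise constant: a fine sweep takes exactly three values in order
  sweep <- classify_arch(seq(0.2, 1.4, by = 1e-3))
  expect_identical(rle(sweep)$values, c("crenel", "romanesque", "gothic"))
  expect_error(classify_arch(0), "positive")
  expect_error(classify_arch(-1), "positive")
})

test_that("hypoplasia and coarctation criteria follow the cutoffs", {
  d <- c(AOA = 12, D1 = 12 * 0.2896, D2 = 6, D3 = 12 * 0.2896, D4 = 8.5,
         D5 = 7.7)
  cr <- evaluate_criteria(d)
  expect_true(cr$haa_flags[["isthmus"]])    # 0.2896 < 0.40
  expect_true(cr$haa_flags[["proximal"]])   # 0.2896 < 0.60
  expect_true(cr$coa_flag)                  # 3.48 <= 0.5 * 8.5
  # boundary: exactly at a cutoff does not flag (strict inequality)
  d2 <- c(AOA = 10, D1 = 6.0, D2 = 5.0, D3 = 4.0, D4 = 8, D5 = 8)
  cr2 <- evaluate_criteria(d2)
  expect_false(any(cr2$haa_flags))
  # unstenosed uniform tube: nothing flags
  d3 <- c(AOA = 10, D1 = 10, D2 = 10, D3 = 10, D4 = 10, D5 = 10)
  cr3 <- evaluate_criteria(d3)
  expect_false(any(cr3$haa_flags))
  expect_false(cr3$coa_flag)
})

test_that("degenerate flat centerlines measure A/T of zero", {
  s <- seq(0, 60, by = 0.5)
  flat <- data.frame(s = s, x = s, y = 0, z = 0)
  lm <- list(ascending_end = list(xyz = c(0, 0, 0), s = 0),
             brachiocephalic_anterior = list(xyz = c(15, 0, 0), s = 15),
             lsca_posterior = list(xyz = c(40, 0, 0), s = 40),
             descending_mid = list(xyz = c(50, 0, 0), s = 50),
             descending_end = list(xyz = c(60, 0, 0), s = 60))
  g <- compute_arch_geometry(flat, lm)
  expect_equal(g$at_ratio, 0)
  # perpendicular synthetic chords
  lm2 <- lm
  lm2$brachiocephalic_anterior$xyz <- c(0, 20, 0)
  g2 <- compute_arch_geometry(flat, lm2)
  expect_equal(g2$aao_dao_angle, 90, tolerance = 1e-9)
})

test_that("degenerate chords raise errors", {
  arch <- build_arch(group_mean_params("gothic"))
  lm <- arch$landmarks
  lm$brachiocephalic_anterior <- lm$ascending_end
  expect_error(compute_arch_geometry(arch$centerline, lm), "degenerate")
})
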