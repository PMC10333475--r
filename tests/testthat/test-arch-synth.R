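test_that("constructed arches reproduce their headline parameters exactly", {
  for (group in c("gothic", "crenel", "romanesque")) {
    p <- group_mean_params(group)
    g <- compute_arch_geometry(build_arch(p))
    expect_equal(g$height_A, p$height_A, tolerance = 1e-9)
    expect_equal(g$width_T, p$width_T, tolerance = 1e-9)
    expect_equal(g$at_ratio, p$height_A / p$width_T, tolerance = 1e-9)
    expect_equal(g$aao_dao_angle, p$aao_dao_angle, tolerance = 1e-9)
    expect_equal(g$tao_dao_angle, p$tao_dao_angle, tolerance = 1e-9)
  }
})

test_that("A/T follows directly from the height and width arguments", {
  g <- compute_arch_geometry(build_arch(arch_params(height_A = 35,
                                                    width_T = 50)))
  expect_equal(g$at_ratio, 0.700, tolerance = 1e-9)
  # a half-circle shape: height half the width
  g2 <- compute_arch_geometry(
    build_arch(arch_params(arch_type = "romanesque", height_A = 25,
                           width_T = 50, aao_dao_angle = 20,
                           tao_dao_angle = 100)))
  expect_equal(g2$at_ratio, 0.5, tolerance = 1e-9)
})

test_that("zero severity leaves the radius profile unstenosed", {
  p0 <- arch_params(stenosis_severity = 0)
  p1 <- arch_params(stenosis_severity = 0.6)
  a0 <- build_arch(p0); a1 <- build_arch(p1)
  expect_equal(a0$centerline$radius,
               coarckit:::eval_radius(a0$centerline$s, a0$radius_knots,
                                      list(severity = 0, center = 0,
                                           length = 8)))
  # throat of the stenosed arch is reduced by exactly (1 - severity)
  expect_equal(arch_radius(a1, a1$stenosis$center),
               (1 - 0.6) * arch_radius(a0, a1$stenosis$center),
               tolerance = 1e-9)
})

test_that("infeasible parameter combinations raise named errors", {
  expect_error(build_arch(arch_params(height_A = 60, width_T = 50,
                                      aao_dao_angle = 70)),
               "infeasible")
  expect_error(build_arch(arch_params(tao_dao_angle = 170)),
               "tao_dao_angle")
  expect_error(arch_params(stenosis_severity = 1), "severity")
  expect_error(arch_params(aao_dao_angle = 95), "aao_dao_angle")
})

test_that("cohort sampling is seed-deterministic and degenerate at sem 0", {
  s <- table1_summaries()
  c1 <- sample_cohort(s, seed = 11)
  c2 <- sample_cohort(s, seed = 11)
  expect_identical(c1, c2)
  expect_length(c1, 95)
  counts <- table(vapply(c1, attr, character(1), "group"))
  expect_equal(as.integer(counts[c("crenel", "gothic", "romanesque")]),
               c(25, 27, 43))
  # sem = 0 collapses every draw onto the mean
  g0 <- group_summary("gothic", 5, list(
    A_T = c(mean = 0.7, sem = 0), AAO_DAO = c(mean = 26.7, sem = 0),
    TAO_DAO = c(mean = 109.8, sem = 0), D1_AOA = c(mean = 0.63, sem = 0),
    D2_AOA = c(mean = 0.53, sem = 0), D3_AOA = c(mean = 0.29, sem = 0),
    D4_AOA = c(mean = 0.71, sem = 0), D5_AOA = c(mean = 0.64, sem = 0)))
  cc <- sample_cohort(list(g0), seed = 3)
  expect_true(all(vapply(cc, function(p) p$height_A, numeric(1)) == 35))
  expect_true(all(vapply(cc, function(p) p$aao_dao_angle,
                         numeric(1)) == 26.7))
})

test_that("sampled group means converge to the published means", {
  # Monte-Carlo mean-consistency: ~1e4 draws of the gothic group
  ats <- unlist(lapply(1:371, function(i)
    vapply(sample_cohort(table1_summaries()["gothic"], seed = i),
           function(p) p$height_A / p$width_T, numeric(1))))
  expect_gt(length(ats), 1e4 - 50)
  expect_lt(abs(mean(ats) - 0.70148), 0.005)
})

test_that("the default network case is a buildable gothic arch", {
  p <- default_network_case()
  expect_identical(p$arch_type, "gothic")
  expect_gte(p$height_A / p$width_T, 0.7)
  expect_s3_class(build_arch(p), "analytic_arch")
})
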