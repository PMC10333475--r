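# Shared fixtures: group-mean parameter sets, straight-tube phantoms and
# small networks used across the suite.

group_mean_params <- function(group = c("gothic", "crenel", "romanesque")) {
  group <- match.arg(group)
  at <- c(gothic = 0.70148, crenel = 0.49028, romanesque = 0.58212)[[group]]
  aao <- c(gothic = 26.74, crenel = 34.56, romanesque = 31.88)[[group]]
  tao <- c(gothic = 109.81, crenel = 112.40, romanesque = 108.57)[[group]]
  arch_params(arch_type = group, height_A = at * 50, width_T = 50,
              aao_dao_angle = aao, tao_dao_angle = tao)
}

# a straight horizontal tube dressed up as an analytic arch (for voxel and
# centerline tests)
straight_tube_arch <- function(length = 60, radius = 5, ds = 0.25) {
  s <- seq(0, length, by = ds)
  cl <- data.frame(s = s, x = s, y = 0, z = 0, radius = radius)
  structure(list(centerline = cl, branch_stubs = list(),
                 landmarks = list(
                   ascending_end = list(xyz = c(0, 0, 0), s = 0),
                   descending_end = list(xyz = c(length, 0, 0), s = length)),
                 radius_knots = list(s = c(0, length), r = rep(radius, 2)),
                 stenosis = list(severity = 0, center = length / 2,
                                 length = 8),
                 params = list(arch_type = "tube")),
            class = "analytic_arch")
}

single_tube_network <- function(length_mm = 100, d_mm = 6,
                                d_dist_mm = d_mm) {
  arterial_network(list(vessel_segment("tube", length_mm, d_mm, d_dist_mm)),
                   parents = c(tube = NA))
}

steady_bcs <- function(v, p_out = 80, exit_loss = 0, name = "tube") {
  boundary_conditions(peak_velocity = v, waveform = "constant",
                      outlet_pressures = stats::setNames(p_out, name),
                      exit_loss = exit_loss, entry_loss = exit_loss)
}

quick_settings <- function(...) solver_settings(max_cycles = 4, ...)

table1_f_oracle <- function(m, sem, n) {
  sdv <- sem * sqrt(n); N <- sum(n); k <- length(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * sdv^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}
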