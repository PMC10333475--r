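# Clinical pressure-gradient calculators, the default gothic CoA network,
# axial profile extraction and stenosis calibration.

#' Bernoulli pressure gradient from jet velocity
#'
#' `mode = "simplified"` is the clinical Doppler formula
#' `dP (mmHg) = 4 (v_jet^2 - v_prox^2)` with velocities in m/s;
#' `mode = "full"` evaluates `rho/2 (v_jet^2 - v_prox^2)` in Pa and converts
#' at 1 mmHg = 133.322 Pa.  For blood the two differ by the constant factor
#' 4 / 3.938 = 1.016.
#'
#' @param v_jet Jet (stenotic) velocity, m/s.
#' @param v_prox Proximal velocity, m/s (default 0).
#' @param mode "simplified" or "full".
#' @param fluid A [fluid_props()] (used by the full form).
#' @return Pressure gradient in mmHg.
#' @examples
#' bernoulli_gradient(2)            # 16 mmHg
#' bernoulli_gradient(1, mode = "full")  # 525 Pa = 3.938 mmHg
#' @export
bernoulli_gradient <- function(v_jet, v_prox = 0,
                               mode = c("simplified", "full"),
                               fluid = fluid_props()) {
  mode <- match.arg(mode)
  if (any(v_jet < 0) || any(v_prox < 0))
    stop("velocities must be non-negative", call. = FALSE)
  if (any(v_jet < v_prox))
    stop("`v_jet` must be >= `v_prox`", call. = FALSE)
  if (mode == "simplified") 4 * (v_jet^2 - v_prox^2)
  else pa_to_mmhg(0.5 * fluid$density * (v_jet^2 - v_prox^2))
}

#' Jet velocity from flow continuity
#'
#' Mass conservation through an area contraction: `v_jet = v_in * (A0/As)`.
#'
#' @param v_in Unobstructed velocity, m/s.
#' @param area_ratio Contraction ratio `A0/As` (>= 1).
#' @return Jet velocity, m/s.
#' @export
jet_velocity <- function(v_in, area_ratio) {
  if (any(area_ratio < 1))
    stop("`area_ratio` (A0/As) must be >= 1", call. = FALSE)
  v_in * area_ratio
}

#' Coarctation diagnosis from the peak systolic pressure gradient
#'
#' TRUE when PSPG exceeds 20 mmHg, or exceeds 10 mmHg in the presence of
#' significant collateral circulation.
#'
#' @param pspg Peak systolic pressure gradient, mmHg (>= 0).
#' @param collaterals_present Logical.
#' @return Logical diagnosis flag.
#' @export
pspg_criteria <- function(pspg, collaterals_present = FALSE) {
  if (any(pspg < 0)) stop("`pspg` must be >= 0", call. = FALSE)
  pspg > 20 | (pspg > 10 & collaterals_present)
}

#' Default gothic coarctation network
#'
#' The reduced-order counterpart of the reference gothic CoA case: an
#' ascending aorta of 12 mm inlet diameter feeding the three arch branches
#' (brachiocephalic trunk, LCCA, LSCA) and a hypoplastic isthmus/descending
#' path, with the coarctation as a stenosis element on the isthmus segment.
#' Calibers follow the gothic-group morphometry at pediatric scale; branch
#' calibers are set so the default boundary conditions reproduce the
#' reported proximal flow of 1.2-1.7 m/s (see the methods vignette).
#'
#' @param throat_area_ratio Stenosis throat area ratio As/A0 in (0, 1\];
#'   1 gives an unstenosed network.
#' @return An [arterial_network()].
#' @export
gothic_coa_network <- function(throat_area_ratio = 0.25) {
  sten <- if (throat_area_ratio < 1)
    list(throat_area_ratio = throat_area_ratio, throat_length_mm = 8,
         position = 0.7)
  segs <- list(
    vessel_segment("ascending", 35, 12.0, 10.2),
    vessel_segment("brachiocephalic", 30, 7.2, 6.2),
    vessel_segment("arch_proximal", 10, 8.9, 7.9),
    vessel_segment("lcca", 30, 5.0, 4.4),
    vessel_segment("arch_distal", 10, 7.1, 6.8),
    vessel_segment("lsca", 30, 5.0, 4.4),
    vessel_segment("isthmus", 25, 6.8, 8.4, stenosis = sten),
    vessel_segment("descending", 80, 8.4, 7.7))
  arterial_network(segs,
                   parents = c(ascending = NA, brachiocephalic = "ascending",
                               arch_proximal = "ascending",
                               lcca = "arch_proximal",
                               arch_distal = "arch_proximal",
                               lsca = "arch_distal",
                               isthmus = "arch_distal",
                               descending = "isthmus"),
                   trunk_outlet = "descending")
}

#' Read an arterial network (and optional BCs) from YAML
#'
#' Layout: `segments: {name: {parent, length_mm, d_prox_mm, d_dist_mm,
#' stenosis: {throat_area_ratio, throat_length_mm, position}}}` plus an
#' optional `boundary` block (`peak_velocity, period_s, systolic_fraction,
#' waveform, outlet_pressures_mmHg`) and `solver` block (`dt_s, max_iter,
#' max_cycles`).
#'
#' @param path YAML file.
#' @return List with `network`, `bcs` (or NULL), `settings` (or NULL).
#' @export
read_network <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$segments))
  segs <- lapply(names(y$segments), function(nm) {
    s <- y$segments[[nm]]
    vessel_segment(nm, s$length_mm, s$d_prox_mm, s$d_dist_mm,
                   stenosis = s$stenosis)
  })
  parents <- vapply(y$segments, function(s)
    if (is.null(s$parent)) NA_character_ else s$parent, character(1))
  net <- arterial_network(segs, parents, trunk_outlet = y$trunk_outlet)
  bcs <- NULL
  if (!is.null(y$boundary)) {
    b <- y$boundary
    bcs <- boundary_conditions(
      peak_velocity = b$peak_velocity %||% 1.2,
      period = b$period_s %||% 0.8,
      systolic_fraction = b$systolic_fraction %||% 0.35,
      outlet_pressures = unlist(b$outlet_pressures_mmhg),
      waveform = b$waveform %||% "halfsine")
  }
  settings <- NULL
  if (!is.null(y$solver)) {
    s <- y$solver
    settings <- solver_settings(dt = s$dt_s %||% 0.005,
                                max_iter = s$max_iter %||% 200L,
                                max_cycles = s$max_cycles %||% 10L)
  }
  list(network = net, bcs = bcs, settings = settings)
}

#' Axial peak-systolic pressure profile and summary metrics
#'
#' Samples pressure and velocity along the inlet-to-descending trunk path
#' at peak systole (the time step of maximal inlet velocity).  Within the
#' stenosis throat the lumen area is the throat area, so the profile shows
#' the Bernoulli dip and the irreversible loss is deposited across the
#' throat.  Summary metrics: proximal plateau pressure (mean over the
#' pre-stenotic trunk), transstenotic pressure difference (pre-stenotic
#' arch station, i.e. the junction into the stenosis-bearing segment, minus
#' the mid-descending station), peak jet velocity over the whole cycle, the
#' proximal velocity range, and per-segment maximal Reynolds numbers.
#'
#' @param result A [solve_pulsatile()] result.
#' @return List with `profile` (data.frame `x_mm, P_mmHg, v_m_s, segment`),
#'   `delta_p`, `v_jet_peak`, `v_jet_systole`, `proximal_plateau`,
#'   `v_proximal_range`, `p_inlet`, `peak_time`, `re_max`.
#' @export
extract_profiles <- function(result) {
  stopifnot(inherits(result, "hemo_result"))
  net <- result$network
  fluid <- result$fluid
  k <- which.max(result$Q_in)
  dt <- result$settings$dt
  # path root -> trunk outlet
  path <- character(0); cur <- net$trunk_outlet
  while (!is.na(cur)) { path <- c(cur, path); cur <- net$parents[[cur]] }

  x0 <- 0
  P <- mmhg_to_pa(result$P_in[k])
  rows <- list()
  sten_seg <- NA_character_
  pre_sten_p <- NA_real_
  for (nm in path) {
    seg <- net$segments[[nm]]
    Q <- result$Q_seg[k, nm]
    k_prev <- if (k == 1) length(result$time) else k - 1
    dQdt <- (Q - result$Q_seg[k_prev, nm]) / dt
    st <- seg_sten(seg)
    if (!is.null(st) && is.na(sten_seg)) {
      sten_seg <- nm
      pre_sten_p <- P       # pressure at the junction into this segment
    }
    nc <- seg$cells
    f <- seq(0, 1, length.out = nc + 1)
    xs <- seg$length * f
    D <- seg_diam_at(seg, f)
    A <- seg_area(D)
    if (!is.null(st)) {
      x_c <- st$position * seg$length
      in_throat <- xs >= x_c - st$Ls / 2 & xs <= x_c + st$Ls / 2
      A[in_throat] <- st$As
      D[in_throat] <- sqrt(4 * st$As / pi)
    } else in_throat <- rep(FALSE, nc + 1)
    v <- Q / A
    Pv <- numeric(nc + 1)
    Pv[1] <- P
    for (i in seq_len(nc)) {
      dx <- xs[i + 1] - xs[i]
      Dm <- 0.5 * (D[i] + D[i + 1])
      dp <- 128 * fluid$viscosity * Q * dx / (pi * Dm^4) +
        0.5 * fluid$density * (v[i + 1]^2 - v[i]^2) * sign2(Q)^2 +
        fluid$density * dQdt * dx / seg_area(Dm)
      if (!is.null(st)) {
        # deposit the irreversible turbulent-expansion loss across the throat
        ov <- overlap_len(xs[i], xs[i + 1],
                          st$position * seg$length - st$Ls / 2,
                          st$position * seg$length + st$Ls / 2)
        if (ov > 0) {
          v0 <- Q / st$A0
          dp <- dp + (ov / st$Ls) *
            (0.5 * st$Kt * fluid$density * (st$A0 / st$As - 1)^2 *
               v0 * abs(v0) +
               st$Ku * fluid$density * st$Ls * dQdt / st$A0)
        }
      }
      Pv[i + 1] <- Pv[i] - dp
    }
    rows[[nm]] <- data.frame(x_mm = 1000 * (x0 + xs),
                             P_mmHg = pa_to_mmhg(Pv),
                             v_m_s = v, segment = nm,
                             in_throat = in_throat)
    x0 <- x0 + seg$length
    P <- Pv[nc + 1]
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL

  desc <- net$trunk_outlet
  desc_rows <- profile$segment == desc
  x_mid <- mean(range(profile$x_mm[desc_rows]))
  p_desc_mid <- stats::approx(profile$x_mm[desc_rows],
                              profile$P_mmHg[desc_rows], x_mid)$y
  pre_rows <- !profile$segment %in% c(sten_seg, desc) |
    is.na(sten_seg)
  if (!is.na(sten_seg)) {
    i_sten <- match(sten_seg, path)
    pre_segs <- path[seq_len(i_sten - 1)]
    pre_rows <- profile$segment %in% pre_segs
  }
  st <- if (!is.na(sten_seg)) seg_sten(net$segments[[sten_seg]]) else NULL
  # the clinical peak jet is the forward (systolic) jet; diastolic reverse
  # runoff through a mild stenosis is excluded
  v_jet_peak <- if (!is.null(st))
    max(pmax(result$Q_seg[, sten_seg], 0)) / st$As else NA_real_
  v_jet_systole <- if (!is.null(st))
    abs(result$Q_seg[k, sten_seg]) / st$As else NA_real_

  list(profile = profile,
       peak_time = result$time[k],
       p_inlet = result$P_in[k],
       proximal_plateau = mean(profile$P_mmHg[pre_rows]),
       delta_p = if (!is.na(sten_seg))
         pa_to_mmhg(pre_sten_p) - p_desc_mid else
           result$P_in[k] - p_desc_mid,
       v_jet_peak = v_jet_peak,
       v_jet_systole = v_jet_systole,
       v_proximal_range = range(abs(profile$v_m_s[pre_rows])),
       re_max = result$re_max)
}

overlap_len <- function(a0, a1, b0, b1) max(0, min(a1, b1) - max(a0, b0))

#' Calibrate the stenosis against a Doppler pressure-gradient target
#'
#' Bisects the throat area ratio `A0/As` until the simplified-Bernoulli
#' gradient computed from the solver's peak jet velocity matches
#' `target_pspg` within `tol` mmHg.  Returns the calibrated network
#' together with its full solution and profile metrics, including the
#' solver's own transstenotic pressure difference.
#'
#' @param network An [arterial_network()] with exactly one stenosis-bearing
#'   segment (its area ratio is the calibration parameter).
#' @param bcs,fluid,settings Passed to [solve_pulsatile()].
#' @param target_pspg Target peak systolic pressure gradient, mmHg (> 0).
#' @param tol Calibration tolerance on the Bernoulli gradient, mmHg.
#' @param bounds Search bracket on `A0/As`.
#' @param branch Which solution branch to calibrate on.  The jet velocity is
#'   not monotone in the contraction ratio: it rises while the throat still
#'   passes most of the descending flow and falls once the stenosis becomes
#'   flow-limiting.  `"severe"` (default) picks the flow-limited branch --
#'   the regime of a tight coarctation; `"mild"` picks the low-grade branch.
#' @return List with `network`, `result`, `profiles`, `area_ratio` (A0/As),
#'   `v_jet`, `bernoulli_pspg`, `delta_p`, `iterations` (solver runs).
#' @export
calibrate_stenosis <- function(network, bcs = boundary_conditions(),
                               fluid = fluid_props(),
                               settings = solver_settings(),
                               target_pspg = 57.2, tol = 0.1,
                               bounds = c(1.05, 50),
                               branch = c("severe", "mild")) {
  branch <- match.arg(branch)
  stopifnot_scalar_num(target_pspg, "target_pspg", 0, strict_lower = TRUE)
  sten_idx <- which(vapply(network$segments,
                           function(s) !is.null(s$stenosis), logical(1)))
  if (length(sten_idx) != 1)
    stop("network must carry exactly one stenosis-bearing segment",
         call. = FALSE)
  nm <- names(network$segments)[sten_idx]

  it <- 0L
  eval_ratio <- function(r) {
    net <- network
    net$segments[[nm]]$stenosis$throat_area_ratio <- 1 / r
    res <- solve_pulsatile(net, bcs, fluid, settings)
    pr <- extract_profiles(res)
    it <<- it + 1L
    list(net = net, res = res, pr = pr, r = r,
         g = bernoulli_gradient(pr$v_jet_peak) - target_pspg)
  }

  # coarse scan to locate the jet-velocity peak, then bisect one branch
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 7))
  scan <- lapply(grid, eval_ratio)
  gv <- vapply(scan, `[[`, numeric(1), "g")
  i_pk <- which.max(gv)
  if (max(gv) < 0)
    stop(sprintf(paste0("target PSPG %.1f mmHg unreachable within area-",
                        "ratio bounds [%g, %g] (max attainable Bernoulli ",
                        "gradient %.2f mmHg)"), target_pspg, bounds[1],
                 bounds[2], max(gv) + target_pspg), call. = FALSE)
  if (branch == "severe") {
    if (gv[length(gv)] > 0)
      stop("severe-branch calibration: gradient still above target at the ",
           "upper area-ratio bound", call. = FALSE)
    i_hi <- i_pk + which(gv[(i_pk + 1):length(gv)] < 0)[1]
    lo <- grid[i_hi - 1]; hi <- grid[i_hi]   # g(lo) > 0 > g(hi), decreasing
    sgn <- -1
    best <- if (abs(gv[i_hi - 1]) < abs(gv[i_hi])) scan[[i_hi - 1]] else
      scan[[i_hi]]
  } else {
    if (gv[1] > 0)
      stop("mild-branch calibration: gradient already above target at the ",
           "lower area-ratio bound", call. = FALSE)
    i_hi <- which(gv > 0)[1]
    lo <- grid[i_hi - 1]; hi <- grid[i_hi]   # g(lo) < 0 < g(hi), increasing
    sgn <- 1
    best <- if (abs(gv[i_hi - 1]) < abs(gv[i_hi])) scan[[i_hi - 1]] else
      scan[[i_hi]]
  }
  while (abs(best$g) > tol && it < 60L) {
    mid <- 0.5 * (lo + hi)
    e_mid <- eval_ratio(mid)
    if (abs(e_mid$g) < abs(best$g)) best <- e_mid
    if (sgn * e_mid$g > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-4) break
  }
  list(network = best$net, result = best$res, profiles = best$pr,
       area_ratio = best$r, v_jet = best$pr$v_jet_peak,
       bernoulli_pspg = bernoulli_gradient(best$pr$v_jet_peak),
       delta_p = best$pr$delta_p, iterations = it)
}
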