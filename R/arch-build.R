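# Closed-form construction of planar arch centerlines.
#
# The centerline lives in the oblique-sagittal plane (x horizontal, y
# vertical, z = 0).  It starts at the ascending end P0 = (0, 0), climbs the
# ascending limb (a straight segment tilted phi_a from vertical), crosses the
# top (one inscribed circular arc for gothic/romanesque, or two corner arcs
# joined by a flat top for crenel) and descends along a straight limb tilted
# phi_d, passing through the mid-descending landmark PT = (T, 0) and ending
# a configurable distance below it.  phi_a + phi_d equals the requested
# AAO-DAO angle, so the angle between the two limb *lines* reproduces it
# exactly; the top is placed so the apex sits exactly at height A above the
# line P0-PT, making A, T, and A/T exact by construction.

#' Build an analytic arch from parameters
#'
#' Constructs the planar centerline, radius profile, landmarks and branch
#' stubs for one synthetic aortic arch.  All headline quantities are exact by
#' construction: the apex sits at `height_A` above the chord between the
#' ascending end and the mid-descending landmark, that chord has length
#' `width_T`, the angle between the ascending and descending limb lines is
#' `aao_dao_angle`, the TAO chord is placed (by a one-dimensional root solve
#' on the LSCA landmark position) so the TAO-DAO angle is `tao_dao_angle`,
#' and the radius interpolant passes through `level_diameters/2` at the six
#' stations.
#'
#' @param params An [arch_params()] object.
#' @param ds Centerline sampling step in mm.
#' @return An object of class `analytic_arch` with components
#'   `centerline` (data.frame `s, x, y, z, radius` in mm),
#'   `landmarks` (named list of `list(xyz, s)`),
#'   `branch_stubs`, `radius_knots`, and the originating `params`.
#' @examples
#' arch <- build_arch(arch_params(height_A = 35, width_T = 50))
#' compute_arch_geometry(arch)$at_ratio  # 0.700 exactly
#' @export
build_arch <- function(params, ds = 0.25) {
  stopifnot(inherits(params, "arch_params"))
  A <- params$height_A
  Tw <- params$width_T
  alpha <- deg2rad(params$aao_dao_angle)
  phi_a <- params$limb_split * alpha
  phi_d <- alpha - phi_a

  u1 <- c(sin(phi_a), cos(phi_a))    # ascending limb, upward
  u2 <- c(-sin(phi_d), cos(phi_d))   # descending limb line, upward
  P0 <- c(0, 0)
  PT <- c(Tw, 0)

  top <- if (params$arch_type == "crenel") {
    build_top_crenel(A, Tw, phi_a, phi_d,
                     rc = params$segment_lengths[["crenel_corner"]])
  } else {
    build_top_arc(A, Tw, phi_a, phi_d)
  }
  # top: list(Pb, Ps0, pieces) where pieces are arcs/lines from Pb to Ps0

  if (top$infeasible)
    stop(sprintf(paste0("infeasible arch geometry: height_A = %.3g, ",
                        "width_T = %.3g and aao_dao_angle = %.3g deg ",
                        "admit no %s top (%s)"),
                 A, Tw, params$aao_dao_angle, params$arch_type, top$why),
         call. = FALSE)

  Pb <- top$Pb      # brachiocephalic anterior border (start of the top)
  Ps0 <- top$Ps0    # where the top rejoins the descending line

  # Descending line: through PT, downward direction -u2.
  L_ext <- params$segment_lengths[["descending"]]
  P_end <- PT - L_ext * u2

  # TAO-DAO angle: realised by placing the branch landmarks on the straight
  # limbs (so the AAO and DAO chords stay exactly along the limb lines).
  # Large requested angles move the LSCA landmark down the descending limb
  # from its top-arc tangency; small ones instead move the brachiocephalic
  # landmark down the ascending limb.  The interior angle at the LSCA
  # landmark between the TAO chord and the downstream DAO direction is
  # solved to the requested value by a 1D root find on either position.
  t1 <- sum(Pb * u1)                      # Pb = t1 * u1 on the ascending limb
  t2 <- sum((Ps0 - PT) * u2)              # Ps0 = PT + t2 * u2, t2 > 0
  tau_s <- function(t) vec_angle(Pb - (PT + t * u2), -u2)
  tau_b <- function(t) vec_angle(t * u1 - Ps0, -u2)
  tau <- params$tao_dao_angle
  Ps <- Ps0
  if (tau >= tau_s(t2)) {
    lo <- min(0.5, t2 / 2)   # keep the LSCA landmark clear of descending_mid
    if (tau > tau_s(lo))
      stop(sprintf(paste0("infeasible arch geometry: tao_dao_angle = %.4g ",
                          "deg exceeds the feasible maximum %.2f deg for ",
                          "this height_A/width_T/aao_dao_angle"),
                   tau, tau_s(lo)), call. = FALSE)
    t_s <- stats::uniroot(function(t) tau_s(t) - tau, c(lo, t2),
                          tol = 1e-12)$root
    Ps <- PT + t_s * u2
  } else {
    tb_lo <- 0.1 * t1
    if (tau < tau_b(tb_lo))
      stop(sprintf(paste0("infeasible arch geometry: tao_dao_angle = %.4g ",
                          "deg is below the feasible minimum %.2f deg for ",
                          "this height_A/width_T/aao_dao_angle"),
                   tau, tau_b(tb_lo)), call. = FALSE)
    t_b <- stats::uniroot(function(t) tau_b(t) - tau, c(tb_lo, t1),
                          tol = 1e-12)$root
    Pb <- t_b * u1
  }

  # --- assemble sampled centerline ------------------------------------------
  # (top$Pb is the geometric start of the top section; the brachiocephalic
  # landmark Pb may sit lower on the same limb line)
  pieces <- c(list(list(type = "line", from = P0, to = top$Pb)),
              top$pieces,
              list(list(type = "line", from = Ps0, to = P_end)))
  cl <- sample_pieces(pieces, ds, force_points = list(top$apex, Ps, PT))
  s_of <- function(p) cl$s[which.min((cl$x - p[1])^2 + (cl$y - p[2])^2)]

  s_b <- s_of(Pb)
  s_apex <- s_of(top$apex)
  s_Ps <- s_of(Ps)
  s_PT <- s_of(PT)
  s_end <- cl$s[nrow(cl)]

  # Measurement stations (arc length).  The isthmus spans LSCA ->
  # mid-descending; D3 sits a quarter of the way down it, where the default
  # stenosis is also centered.
  s_AOA <- 0.5 * s_b
  s_D1 <- 0.5 * (s_b + s_apex)
  s_D2 <- 0.5 * (s_apex + s_Ps)
  s_D3 <- s_Ps + 0.25 * (s_PT - s_Ps)
  s_D4 <- s_PT
  s_D5 <- max(s_end - 2.5, 0.5 * (s_PT + s_end))
  s_sten <- s_Ps + params$stenosis_location * (s_PT - s_Ps)

  r <- params$level_diameters / 2
  knots_s <- c(0, s_AOA, s_D1, s_D2, s_D3, s_D4, s_D5, s_end)
  knots_r <- c(r[["AOA"]], r[["AOA"]], r[["D1"]], r[["D2"]], r[["D3"]],
               r[["D4"]], r[["D5"]], r[["D5"]])
  ok <- !duplicated(knots_s)
  knots <- list(s = knots_s[ok], r = knots_r[ok])

  sten <- list(severity = params$stenosis_severity,
               center = s_sten,
               length = params$segment_lengths[["stenosis"]])

  cl$radius <- eval_radius(cl$s, knots, sten)

  lm_point <- function(p, s) list(xyz = c(p, 0), s = s)
  station_point <- function(s) {
    i <- findInterval(s, cl$s, all.inside = TRUE)
    w <- (s - cl$s[i]) / max(cl$s[i + 1] - cl$s[i], 1e-12)
    list(xyz = c((1 - w) * cl$x[i] + w * cl$x[i + 1],
                 (1 - w) * cl$y[i] + w * cl$y[i + 1], 0), s = s)
  }
  landmarks <- list(
    ascending_end = lm_point(P0, 0),
    brachiocephalic_anterior = lm_point(Pb, s_b),
    arch_apex = lm_point(top$apex, s_apex),
    lsca_posterior = lm_point(Ps, s_Ps),
    descending_mid = lm_point(PT, s_PT),
    descending_end = lm_point(P_end, s_end),
    AOA = station_point(s_AOA), D1 = station_point(s_D1),
    D2 = station_point(s_D2), D3 = station_point(s_D3),
    D4 = station_point(s_D4), D5 = station_point(s_D5),
    stenosis_center = station_point(s_sten))

  rb <- params$branch_diameters / 2
  Lb <- params$segment_lengths[["branch"]]
  stub <- function(origin, dir, radius) {
    dir <- dir / sqrt(sum(dir^2))
    tt <- seq(0, Lb, by = ds)
    data.frame(s = tt,
               x = origin[1] + tt * dir[1],
               y = origin[2] + tt * dir[2],
               z = 0, radius = radius)
  }
  branch_stubs <- list(
    brachiocephalic = stub(Pb, c(-0.26, 0.97), rb[["brachiocephalic"]]),
    lcca = stub(top$apex, c(0, 1), rb[["lcca"]]),
    lsca = stub(Ps, c(0.26, 0.97), rb[["lsca"]]))

  structure(list(centerline = cl,
                 landmarks = landmarks,
                 branch_stubs = branch_stubs,
                 radius_knots = knots,
                 stenosis = sten,
                 params = params),
            class = "analytic_arch")
}

# Inscribed-circle top (gothic and romanesque families): circle tangent to
# both limb lines whose topmost point is exactly at height A.  Linear system,
# closed form.
build_top_arc <- function(A, Tw, phi_a, phi_d) {
  ca <- cos(phi_a); sa <- sin(phi_a)
  cd <- cos(phi_d); sd <- sin(phi_d)
  r <- (ca * (cd * Tw - sd * A) - cd * A * sa) /
       (cd * (1 - sa) + ca * (1 - sd))
  if (!is.finite(r) || r <= 0.5)
    return(list(infeasible = TRUE, why = "apex arc radius collapses"))
  cx <- (r * (1 - sa) + A * sa) / ca
  cy <- A - r
  cc <- c(cx, cy)
  u1 <- c(sa, ca); u2 <- c(-sd, cd)
  t1 <- sum(cc * u1)                       # tangency along ascending line
  Pb <- t1 * u1
  t2 <- sum((cc - c(Tw, 0)) * u2)          # tangency along descending line
  Ps0 <- c(Tw, 0) + t2 * u2
  if (t1 <= 0.5 || t2 <= 0.5 || Pb[2] >= A || Ps0[2] >= A)
    return(list(infeasible = TRUE, why = "limb tangency points degenerate"))
  th1 <- atan2(Pb[2] - cy, Pb[1] - cx)
  th2 <- atan2(Ps0[2] - cy, Ps0[1] - cx)
  # sweep from th1 (left side) through pi/2 (top) down to th2 (right side)
  if (th1 < pi / 2) th1 <- th1 + 2 * pi    # keep th1 > pi/2 > th2
  apex <- c(cx, A)
  pieces <- list(list(type = "arc", center = cc, radius = r,
                      from = th1, to = pi / 2),
                 list(type = "arc", center = cc, radius = r,
                      from = pi / 2, to = th2))
  list(infeasible = FALSE, Pb = Pb, Ps0 = Ps0, apex = apex, pieces = pieces)
}

# Flat-top crenel: two corner circles of radius rc tangent to a limb line and
# to the horizontal line y = A, joined by a straight flat top.
build_top_crenel <- function(A, Tw, phi_a, phi_d, rc) {
  try_rc <- function(rc) {
    ca <- cos(phi_a); sa <- sin(phi_a)
    cd <- cos(phi_d); sd <- sin(phi_d)
    cl_x <- (rc + sa * (A - rc)) / ca
    cr_x <- Tw - (rc + sd * (A - rc)) / cd
    if (cr_x - cl_x < 1) return(NULL)
    u1 <- c(sa, ca); u2 <- c(-sd, cd)
    ccl <- c(cl_x, A - rc); ccr <- c(cr_x, A - rc)
    t1 <- sum(ccl * u1)
    Pb <- t1 * u1
    t2 <- sum((ccr - c(Tw, 0)) * u2)
    Ps0 <- c(Tw, 0) + t2 * u2
    if (t1 <= 0.5 || t2 <= 0.5 || Pb[2] >= A || Ps0[2] >= A) return(NULL)
    th1 <- atan2(Pb[2] - ccl[2], Pb[1] - ccl[1])
    if (th1 < pi / 2) th1 <- th1 + 2 * pi
    th2 <- atan2(Ps0[2] - ccr[2], Ps0[1] - ccr[1])
    apex <- c(0.5 * (cl_x + cr_x), A)
    pieces <- list(
      list(type = "arc", center = ccl, radius = rc, from = th1, to = pi / 2),
      list(type = "line", from = c(cl_x, A), to = apex),
      list(type = "line", from = apex, to = c(cr_x, A)),
      list(type = "arc", center = ccr, radius = rc, from = pi / 2, to = th2))
    list(infeasible = FALSE, Pb = Pb, Ps0 = Ps0, apex = apex, pieces = pieces)
  }
  for (r_try in c(rc, rc / 2, rc / 4, 1)) {
    out <- try_rc(r_try)
    if (!is.null(out)) return(out)
  }
  list(infeasible = TRUE, why = "flat top shorter than corner arcs")
}

# Sample a list of line/arc pieces into an arc-length parameterised polyline,
# forcing exact inclusion of the given points (apex, landmarks).
sample_pieces <- function(pieces, ds, force_points = list()) {
  xs <- ys <- numeric(0)
  for (p in pieces) {
    if (p$type == "line") {
      len <- sqrt(sum((p$to - p$from)^2))
      n <- max(2L, ceiling(len / ds) + 1L)
      tt <- seq(0, 1, length.out = n)
      px <- p$from[1] + tt * (p$to[1] - p$from[1])
      py <- p$from[2] + tt * (p$to[2] - p$from[2])
    } else {
      len <- abs(p$to - p$from) * p$radius
      n <- max(2L, ceiling(len / ds) + 1L)
      th <- seq(p$from, p$to, length.out = n)
      px <- p$center[1] + p$radius * cos(th)
      py <- p$center[2] + p$radius * sin(th)
    }
    if (length(xs)) { px <- px[-1]; py <- py[-1] }
    xs <- c(xs, px); ys <- c(ys, py)
  }
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  keep <- c(TRUE, seg > 1e-9)
  xs <- xs[keep]; ys <- ys[keep]
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  data.frame(s = s, x = xs, y = ys, z = 0)
}

# Base radius interpolant (monotone cubic through the station knots) times
# the cosine-tapered stenosis factor.
eval_radius <- function(s, knots, sten) {
  f <- stats::splinefun(knots$s, knots$r, method = "monoH.FC")
  r <- f(pmin(pmax(s, min(knots$s)), max(knots$s)))
  if (sten$severity > 0) {
    d <- s - sten$center
    in_throat <- abs(d) <= sten$length / 2
    fac <- rep(1, length(s))
    fac[in_throat] <- 1 - sten$severity *
      0.5 * (1 + cos(2 * pi * d[in_throat] / sten$length))
    r <- r * fac
  }
  r
}

#' Evaluate the radius profile of an analytic arch
#'
#' @param arch An `analytic_arch`.
#' @param s Arc-length positions (mm).
#' @return Radii in mm (stenosis taper included).
#' @export
arch_radius <- function(arch, s) {
  stopifnot(inherits(arch, "analytic_arch"))
  eval_radius(s, arch$radius_knots, arch$stenosis)
}

#' @export
print.analytic_arch <- function(x, ...) {
  g <- compute_arch_geometry(x)
  cat(sprintf("<analytic_arch> %s  length %.1f mm, %d samples\n",
              x$params$arch_type, max(x$centerline$s), nrow(x$centerline)))
  cat(sprintf("  A=%.3f mm  T=%.3f mm  A/T=%.4f  AAO-DAO=%.2f  TAO-DAO=%.2f\n",
              g$height_A, g$width_T, g$at_ratio,
              g$aao_dao_angle, g$tao_dao_angle))
  if (x$stenosis$severity > 0)
    cat(sprintf("  stenosis severity %.2f at s=%.1f mm\n",
                x$stenosis$severity, x$stenosis$center))
  invisible(x)
}

#' @export
plot.analytic_arch <- function(x, show_radius = TRUE, ...) {
  cl <- x$centerline
  plot(cl$x, cl$y, type = "l", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
       main = sprintf("%s arch", x$params$arch_type), ...)
  if (show_radius) {
    i <- seq(1, nrow(cl), by = max(1L, nrow(cl) %/% 120))
    dx <- c(diff(cl$x), 0); dy <- c(diff(cl$y), 0)
    nn <- sqrt(dx^2 + dy^2); nn[nn == 0] <- 1
    nx <- -dy / nn; ny <- dx / nn
    graphics::segments(cl$x[i] - cl$radius[i] * nx[i],
                       cl$y[i] - cl$radius[i] * ny[i],
                       cl$x[i] + cl$radius[i] * nx[i],
                       cl$y[i] + cl$radius[i] * ny[i], col = "grey70")
  }
  for (b in x$branch_stubs) graphics::lines(b$x, b$y, col = "steelblue")
  lm <- do.call(rbind, lapply(x$landmarks, function(l) l$xyz[1:2]))
  graphics::points(lm[, 1], lm[, 2], pch = 20, col = "firebrick")
  invisible(x)
}
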