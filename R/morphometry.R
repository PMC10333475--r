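# CTA-style arch morphometry on centerline + radius geometry.
#
# All constructions are coordinate-free: "horizontal" means along the chord
# joining the ascending-end and mid-descending landmarks (the T-line) and
# "vertical" means perpendicular to it, so every output is invariant to
# rigid motions of the arch within its plane.

# Normalise input into list(cl = centerline data.frame, lm = landmarks).
as_arch_geometry <- function(arch, landmarks = NULL) {
  if (inherits(arch, "analytic_arch"))
    return(list(cl = arch$centerline, lm = arch$landmarks))
  stopifnot(is.data.frame(arch), all(c("x", "y", "z") %in% names(arch)))
  if (is.null(landmarks))
    stop("`landmarks` are required when `arch` is a bare centerline",
         call. = FALSE)
  lm <- lapply(landmarks, function(l) {
    if (is.list(l) && !is.null(l$xyz)) l else list(xyz = as.numeric(l), s = NA)
  })
  list(cl = arch, lm = lm)
}

require_landmarks <- function(lm, names) {
  miss <- setdiff(names, names(lm))
  if (length(miss))
    stop("missing landmarks: ", paste(miss, collapse = ", "), call. = FALSE)
  # anatomical ordering check where arc-length positions are known
  st <- c("AOA", "D1", "D2", "D3", "D4", "D5")
  pos <- vapply(lm[intersect(st, names(lm))],
                function(l) l$s %||% NA_real_, numeric(1))
  pos <- pos[!is.na(pos)]
  if (length(pos) > 1 && any(diff(pos) <= 0))
    stop("landmark stations must be in increasing arc-length order ",
         "(AOA < D1 < ... < D5)", call. = FALSE)
  invisible(lm)
}

# Best-fit plane projection (centerline plus landmarks, so the basis stays
# well-defined even for a collinear centerline); warns if badly non-planar.
project_to_plane <- function(cl, lm, tol_rms = 1) {
  P <- cbind(cl$x, cl$y, cl$z)
  L <- do.call(rbind, lapply(lm, function(l) l$xyz))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(rbind(Pc, sweep(L, 2, ctr)), nu = 0, nv = 3)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  rms <- sqrt(mean((Pc %*% nrm)^2))
  if (rms > tol_rms)
    warning(sprintf("centerline out-of-plane RMS %.2f mm; projecting to the ",
                    rms), "best-fit plane", call. = FALSE)
  list(pts = cbind(Pc %*% e1, Pc %*% e2),
       lm2 = lapply(lm, function(l) {
         v <- l$xyz - ctr
         c(sum(v * e1), sum(v * e2))
       }))
}

#' Arch height, width, A/T ratio and chord angles
#'
#' Implements the oblique-sagittal measurement constructions: the width `T`
#' is the distance between the ascending-end and mid-descending landmarks,
#' the height `A` is the maximal perpendicular distance from the centerline
#' to that chord (the T-line), the AAO and DAO chords join the ascending end
#' to the anterior border of the brachiocephalic trunk and the descending
#' end to the posterior border of the LSCA, and the TAO chord joins the two
#' branch landmarks.  The AAO-DAO angle is reported as the acute angle
#' between the two chord lines; the TAO-DAO angle as the interior angle at
#' the LSCA landmark.
#'
#' @param arch An [build_arch()] result, or a centerline data.frame with
#'   columns `x, y, z` (mm).
#' @param landmarks Named list of landmarks (each `list(xyz = , s = )` or a
#'   bare xyz vector); required for bare centerlines.  Needs
#'   `ascending_end`, `brachiocephalic_anterior`, `lsca_posterior`,
#'   `descending_mid` (plus optional `descending_end`).
#' @return List with `height_A`, `width_T`, `at_ratio`, `aao_dao_angle`,
#'   `tao_dao_angle` (mm / degrees).
#' @export
compute_arch_geometry <- function(arch, landmarks = NULL) {
  g <- as_arch_geometry(arch, landmarks)
  lm <- require_landmarks(g$lm, c("ascending_end", "brachiocephalic_anterior",
                                  "lsca_posterior", "descending_mid"))
  pr <- project_to_plane(g$cl, lm)
  pts <- pr$pts; lm2 <- pr$lm2

  p_asc <- lm2$ascending_end
  p_dmid <- lm2$descending_mid
  p_b <- lm2$brachiocephalic_anterior
  p_s <- lm2$lsca_posterior
  p_end <- if (!is.null(lm2$descending_end)) lm2$descending_end else
    pts[nrow(pts), ]

  chord <- p_dmid - p_asc
  width_T <- sqrt(sum(chord^2))
  if (width_T < 1e-9)
    stop("degenerate T-line: ascending_end and descending_mid coincide",
         call. = FALSE)
  e <- chord / width_T
  # perpendicular distance to the T-line, restricted to the arch body (points
  # projecting between the two T-line landmarks, which excludes the
  # descending aorta continuing below the mid-descending landmark)
  t_along <- (pts[, 1] - p_asc[1]) * e[1] + (pts[, 2] - p_asc[2]) * e[2]
  d <- (pts[, 1] - p_asc[1]) * (-e[2]) + (pts[, 2] - p_asc[2]) * e[1]
  body <- t_along >= -1e-9 & t_along <= width_T + 1e-9
  height_A <- if (any(body)) max(abs(d[body])) else 0

  dir_aao <- p_b - p_asc
  dir_dao <- p_s - p_end
  if (sqrt(sum(dir_aao^2)) < 1e-9 || sqrt(sum(dir_dao^2)) < 1e-9)
    stop("degenerate chord: coincident landmark points", call. = FALSE)
  aao_dao <- line_angle(dir_aao, dir_dao)
  tao_dao <- vec_angle(p_b - p_s, p_end - p_s)

  list(height_A = height_A, width_T = width_T,
       at_ratio = height_A / width_T,
       aao_dao_angle = aao_dao, tao_dao_angle = tao_dao)
}

#' Level diameters AOA, D1-D5
#'
#' On an analytic arch the radius interpolant is evaluated directly at each
#' station.  On an extracted centerline (with a `radius` column, e.g. from
#' [extract_centerline()]) each level diameter is twice the maximal inscribed
#' radius over a +/- `window` mm arc-length neighbourhood of the station,
#' with the station located by projecting the landmark onto the centerline.
#'
#' @inheritParams compute_arch_geometry
#' @param window Search half-window in mm (extracted-centerline path only).
#' @return Named numeric vector `AOA, D1, ..., D5` of diameters in mm.
#' @export
measure_diameters <- function(arch, landmarks = NULL, window = 2.5) {
  st <- c("AOA", "D1", "D2", "D3", "D4", "D5")
  if (inherits(arch, "analytic_arch")) {
    s <- vapply(arch$landmarks[st], function(l) l$s, numeric(1))
    return(stats::setNames(2 * arch_radius(arch, s), st))
  }
  g <- as_arch_geometry(arch, landmarks)
  lm <- require_landmarks(g$lm, st)
  cl <- g$cl
  if (is.null(cl$radius))
    stop("centerline must carry a `radius` column", call. = FALSE)
  if (is.null(cl$s))
    cl$s <- c(0, cumsum(sqrt(diff(cl$x)^2 + diff(cl$y)^2 + diff(cl$z)^2)))
  out <- vapply(st, function(nm) {
    l <- lm[[nm]]
    s0 <- l$s
    if (is.null(s0) || is.na(s0)) {
      i <- which.min((cl$x - l$xyz[1])^2 + (cl$y - l$xyz[2])^2 +
                     (cl$z - l$xyz[3])^2)
      s0 <- cl$s[i]
    }
    if (s0 - window < min(cl$s) || s0 + window > max(cl$s))
      warning(sprintf("measurement window at station %s clipped to the ",
                      nm), "centerline extent", call. = FALSE)
    sel <- cl$s >= s0 - window & cl$s <= s0 + window
    2 * max(cl$radius[sel])
  }, numeric(1))
  stats::setNames(out, st)
}

#' Classify an arch by its height-to-width ratio
#'
#' Gothic if `A/T > 0.8`, crenel if `A/T < 0.6`, romanesque in between
#' (boundary values classify as romanesque).
#'
#' @param at_ratio Height-to-width ratio(s), > 0.
#' @return Character vector of class labels.
#' @export
classify_arch <- function(at_ratio) {
  if (!is.numeric(at_ratio) || any(!is.finite(at_ratio)) ||
      any(at_ratio <= 0))
    stop("`at_ratio` must be positive and finite", call. = FALSE)
  ifelse(at_ratio > 0.8, "gothic",
         ifelse(at_ratio < 0.6, "crenel", "romanesque"))
}

#' Hypoplastic-arch and coarctation criteria
#'
#' Flags arch hypoplasia when the proximal arch, distal arch or isthmus
#' diameter falls below 60%, 50% or 40% of the ascending aorta respectively
#' (strict inequalities), and coarctation when the narrowest level diameter
#' is at most half the reference diameter (defaulting to D4, the
#' mid-descending aorta).
#'
#' @param m An `arch_measurements` object or a named vector with entries
#'   `AOA, D1, ..., D5` (mm).
#' @param reference_diameter Optional reference caliber in mm; defaults to
#'   the measured D4.
#' @return List with logical `haa_flags` (`proximal`, `distal`, `isthmus`)
#'   and `coa_flag`.
#' @export
evaluate_criteria <- function(m, reference_diameter = NULL) {
  d <- if (inherits(m, "arch_measurements")) m$diameters else unlist(m)
  need <- c("AOA", "D1", "D2", "D3", "D4", "D5")
  stopifnot(all(need %in% names(d)))
  haa <- c(proximal = unname(d[["D1"]] / d[["AOA"]]) < 0.60,
           distal = unname(d[["D2"]] / d[["AOA"]]) < 0.50,
           isthmus = unname(d[["D3"]] / d[["AOA"]]) < 0.40)
  ref <- reference_diameter %||% d[["D4"]]
  coa <- min(d[need != "AOA"]) <= 0.50 * ref
  list(haa_flags = haa, coa_flag = coa)
}

#' Full morphometric record for one arch
#'
#' Runs [measure_diameters()], [compute_arch_geometry()],
#' [classify_arch()] and [evaluate_criteria()] and assembles the per-case
#' measurement record.
#'
#' @inheritParams measure_diameters
#' @param reference_diameter Passed to [evaluate_criteria()].
#' @return An object of class `arch_measurements`.
#' @export
measure_arch <- function(arch, landmarks = NULL, window = 2.5,
                         reference_diameter = NULL) {
  d <- measure_diameters(arch, landmarks, window)
  geom <- compute_arch_geometry(arch, landmarks)
  ratios <- d[c("D1", "D2", "D3", "D4", "D5")] / d[["AOA"]]
  names(ratios) <- paste0(c("D1", "D2", "D3", "D4", "D5"), "_AOA")
  crit <- evaluate_criteria(d, reference_diameter)
  structure(c(list(diameters = d, ratios = ratios),
              geom,
              list(arch_class = classify_arch(geom$at_ratio),
                   haa_flags = crit$haa_flags, coa_flag = crit$coa_flag)),
            class = "arch_measurements")
}

#' @export
print.arch_measurements <- function(x, ...) {
  cat(sprintf("<arch_measurements> class: %s\n", x$arch_class))
  cat(sprintf("  A=%.3f T=%.3f A/T=%.4f  AAO-DAO=%.2f  TAO-DAO=%.2f\n",
              x$height_A, x$width_T, x$at_ratio, x$aao_dao_angle,
              x$tao_dao_angle))
  cat("  diameters (mm): ",
      paste(sprintf("%s=%.2f", names(x$diameters), x$diameters),
            collapse = " "), "\n", sep = "")
  cat("  Di/AOA: ",
      paste(sprintf("%s=%.3f", names(x$ratios), x$ratios), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  HAA proximal/distal/isthmus: %s/%s/%s  CoA: %s\n",
              x$haa_flags[["proximal"]], x$haa_flags[["distal"]],
              x$haa_flags[["isthmus"]], x$coa_flag))
  invisible(x)
}

#' Convert a cohort of measurements to a data frame
#'
#' @param measurements A list of `arch_measurements`.
#' @param group Optional group labels (recycled).
#' @return A data.frame with Table-1-style columns
#'   (`D1_AOA ... D5_AOA, A_T, AAO_DAO, TAO_DAO, arch_class`).
#' @export
measurements_to_df <- function(measurements, group = NULL) {
  rows <- lapply(measurements, function(m) {
    data.frame(AOA = m$diameters[["AOA"]],
               D1 = m$diameters[["D1"]], D2 = m$diameters[["D2"]],
               D3 = m$diameters[["D3"]], D4 = m$diameters[["D4"]],
               D5 = m$diameters[["D5"]],
               D1_AOA = m$ratios[["D1_AOA"]], D2_AOA = m$ratios[["D2_AOA"]],
               D3_AOA = m$ratios[["D3_AOA"]], D4_AOA = m$ratios[["D4_AOA"]],
               D5_AOA = m$ratios[["D5_AOA"]],
               A = m$height_A, T = m$width_T, A_T = m$at_ratio,
               AAO_DAO = m$aao_dao_angle, TAO_DAO = m$tao_dao_angle,
               arch_class = m$arch_class,
               coa_flag = m$coa_flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(group)) out$group <- rep_len(group, nrow(out))
  out
}
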