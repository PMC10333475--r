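#' Parametric description of a synthetic aortic arch
#'
#' Bundles every parameter needed to construct one synthetic arch: the shape
#' family, arch height `A` and width `T` (mm, measured in the oblique-sagittal
#' plane), the AAO-DAO and TAO-DAO chord angles (degrees), the level diameters
#' at the six measurement stations (AOA, D1-D5, mm), an optional coarctation
#' (fractional diameter reduction at a throat on the isthmus), branch calibers
#' and auxiliary segment lengths.
#'
#' The level diameters describe the *unstenosed* base caliber profile; the
#' stenosis, when present, multiplies the local radius by `1 - severity` at
#' the throat with a cosine taper.  Cohorts sampled from published group
#' summaries encode the coarctation directly in a small D3 and leave
#' `stenosis_severity = 0`.
#'
#' @param arch_type "gothic", "crenel" or "romanesque".
#' @param height_A Arch height A in mm (> 0).
#' @param width_T Arch width T in mm (> 0).
#' @param aao_dao_angle Angle between the AAO and DAO chords, degrees,
#'   in (0, 90).
#' @param tao_dao_angle Angle between the TAO and DAO chords, degrees,
#'   in (90, 180).
#' @param level_diameters Named numeric vector/list with entries
#'   `AOA, D1, D2, D3, D4, D5` (mm).
#' @param stenosis_severity Fraction of the local diameter removed at the
#'   throat, in \[0, 1).
#' @param stenosis_location Arc-length fraction along the isthmus
#'   (LSCA landmark to mid-descending) at which the throat sits, in \[0, 1\].
#' @param branch_diameters Named vector `brachiocephalic, lcca, lsca` (mm).
#' @param segment_lengths Named vector `descending, branch, stenosis,
#'   crenel_corner` (mm): descending extension below the mid-descending
#'   landmark, branch stub length, stenosis taper length, crenel corner
#'   radius.
#' @param limb_split Fraction of the AAO-DAO angle assigned to the ascending
#'   limb tilt (the rest tilts the descending limb).
#' @param seed Integer seed recorded with the parameter set.
#' @return An object of class `arch_params`.
#' @seealso [build_arch()], [sample_cohort()], [default_network_case()]
#' @export
arch_params <- function(arch_type = c("gothic", "crenel", "romanesque"),
                        height_A = 35,
                        width_T = 50,
                        aao_dao_angle = 26.74,
                        tao_dao_angle = 109.81,
                        level_diameters = c(AOA = 12, D1 = 7.6, D2 = 6.5,
                                            D3 = 7.2, D4 = 8.5, D5 = 7.7),
                        stenosis_severity = 0,
                        stenosis_location = 0.25,
                        branch_diameters = c(brachiocephalic = 6.5,
                                             lcca = 4.2, lsca = 4.2),
                        segment_lengths = c(descending = 30, branch = 12,
                                            stenosis = 8, crenel_corner = 8),
                        limb_split = 0.5,
                        seed = 1L) {
  arch_type <- match.arg(arch_type)
  stopifnot_scalar_num(height_A, "height_A", 0, strict_lower = TRUE)
  stopifnot_scalar_num(width_T, "width_T", 0, strict_lower = TRUE)
  stopifnot_scalar_num(aao_dao_angle, "aao_dao_angle", 0, 90,
                       strict_lower = TRUE)
  if (aao_dao_angle >= 90)
    stop("`aao_dao_angle` must be in (0, 90) degrees", call. = FALSE)
  stopifnot_scalar_num(tao_dao_angle, "tao_dao_angle", 90, 180,
                       strict_lower = TRUE)
  if (tao_dao_angle >= 180)
    stop("`tao_dao_angle` must be in (90, 180) degrees", call. = FALSE)
  stopifnot_scalar_num(stenosis_severity, "stenosis_severity", 0)
  if (stenosis_severity >= 1)
    stop("`stenosis_severity` must be in [0, 1)", call. = FALSE)
  stopifnot_scalar_num(stenosis_location, "stenosis_location", 0, 1)
  stopifnot_scalar_num(limb_split, "limb_split", 0.05, 0.95)

  ld <- unlist(level_diameters)
  need <- c("AOA", "D1", "D2", "D3", "D4", "D5")
  if (!all(need %in% names(ld)))
    stop("`level_diameters` must name AOA, D1, D2, D3, D4, D5", call. = FALSE)
  ld <- ld[need]
  bd <- unlist(branch_diameters)
  need_b <- c("brachiocephalic", "lcca", "lsca")
  if (!all(need_b %in% names(bd)))
    stop("`branch_diameters` must name brachiocephalic, lcca, lsca",
         call. = FALSE)
  bd <- bd[need_b]
  sl <- unlist(segment_lengths)
  need_s <- c("descending", "branch", "stenosis", "crenel_corner")
  if (!all(need_s %in% names(sl)))
    stop("`segment_lengths` must name descending, branch, stenosis, ",
         "crenel_corner", call. = FALSE)
  sl <- sl[need_s]
  if (any(c(ld, bd, sl) <= 0))
    stop("all diameters and lengths must be > 0", call. = FALSE)

  structure(list(arch_type = arch_type,
                 height_A = height_A, width_T = width_T,
                 aao_dao_angle = aao_dao_angle,
                 tao_dao_angle = tao_dao_angle,
                 level_diameters = ld,
                 stenosis_severity = stenosis_severity,
                 stenosis_location = stenosis_location,
                 branch_diameters = bd,
                 segment_lengths = sl,
                 limb_split = limb_split,
                 seed = as.integer(seed)),
            class = "arch_params")
}

#' @export
print.arch_params <- function(x, ...) {
  cat(sprintf("<arch_params> %s arch  A=%.2f mm  T=%.2f mm  A/T=%.4f\n",
              x$arch_type, x$height_A, x$width_T, x$height_A / x$width_T))
  cat(sprintf("  AAO-DAO %.2f deg  TAO-DAO %.2f deg\n",
              x$aao_dao_angle, x$tao_dao_angle))
  cat("  level diameters (mm): ",
      paste(sprintf("%s=%.2f", names(x$level_diameters), x$level_diameters),
            collapse = " "), "\n", sep = "")
  if (x$stenosis_severity > 0)
    cat(sprintf("  stenosis: severity %.2f at isthmus fraction %.2f\n",
                x$stenosis_severity, x$stenosis_location))
  invisible(x)
}

#' Default gothic coarctation case parameters
#'
#' Returns the parameter set of the reference gothic CoA case used by the
#' reduced-order hemodynamic model: a pediatric-scale gothic arch (ascending
#' aorta 12 mm, A/T = 0.70) whose stenosis severity is deliberately left at
#' zero -- severity (equivalently, the throat area ratio) is the free
#' parameter that [calibrate_stenosis()] tunes against a Doppler-style
#' pressure-gradient target.
#'
#' @return An `arch_params` object with `arch_type = "gothic"` and
#'   `A/T >= 0.7`.
#' @export
default_network_case <- function() {
  arch_params(arch_type = "gothic",
              height_A = 35.074, width_T = 50,
              aao_dao_angle = 26.74, tao_dao_angle = 109.81,
              level_diameters = c(AOA = 12, D1 = 7.6, D2 = 6.5,
                                  D3 = 7.2, D4 = 8.5, D5 = 7.7),
              stenosis_severity = 0,
              seed = 1L)
}
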