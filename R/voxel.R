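# Voxelized binary masks of synthetic arches, with NIfTI-1 and landmark IO.

#' Construct a voxel mask object
#'
#' @param grid 3D integer/logical array with foreground = 1.
#' @param spacing Voxel spacing per axis, mm (length 1 or 3, > 0).
#' @param origin World coordinate of voxel (1, 1, 1), mm.
#' @param landmarks Optional named list of landmarks (`list(xyz =, s =)`).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, spacing, origin = c(0, 0, 0),
                       landmarks = NULL) {
  stopifnot(length(dim(grid)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be > 0", call. = FALSE)
  vals <- unique(as.vector(grid))
  if (!all(vals %in% c(0, 1)))
    stop("mask must be binary {0, 1}", call. = FALSE)
  structure(list(grid = array(as.integer(grid), dim(grid)),
                 spacing = spacing,
                 origin = as.numeric(origin),
                 landmarks = landmarks),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, spacing %s mm, %d foreground\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x "),
              sum(x$grid)))
  invisible(x)
}

# world coordinates of a (possibly fractional) 1-based voxel index
voxel_to_world <- function(mask, ijk) {
  sweep(sweep(ijk - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

world_to_voxel <- function(mask, xyz) {
  sweep(sweep(xyz, 2, mask$origin, "-"), 2, mask$spacing, "/") + 1
}

#' Rasterize an analytic arch into a binary voxel mask
#'
#' Marks every voxel whose center lies inside the tube of radius
#' `radius_profile(s)` around the centerline (branch stubs included),
#' implemented as a union of spheres along a centerline resampled at half
#' the voxel spacing.  Landmark world coordinates are carried through
#' unchanged.
#'
#' @param arch An [build_arch()] result.
#' @param spacing Isotropic voxel spacing in mm, or a length-3 vector.  Must
#'   be at most half of the smallest tube radius (sampling guard).
#' @param margin Padding around the geometry, mm.
#' @return A [voxel_mask()].
#' @export
voxelize <- function(arch, spacing = 0.4, margin = 2) {
  stopifnot(inherits(arch, "analytic_arch"))
  spacing <- rep_len(as.numeric(spacing), 3L)
  parts <- c(list(arch$centerline[, c("s", "x", "y", "z")]),
             lapply(arch$branch_stubs, function(b) b[, c("s", "x", "y", "z")]))
  radii <- c(list(arch$centerline$radius),
             lapply(arch$branch_stubs, function(b) b$radius))
  rmin <- min(unlist(radii))
  if (max(spacing) > rmin / 2)
    stop(sprintf(paste0("spacing %.3g mm too coarse for minimum tube radius ",
                        "%.3g mm; use spacing <= %.3g mm"),
                 max(spacing), rmin, rmin / 2), call. = FALSE)

  dense <- mapply(function(p, r) {
    ds <- min(spacing) / 2
    si <- seq(min(p$s), max(p$s), by = ds)
    cbind(stats::approx(p$s, p$x, si)$y,
          stats::approx(p$s, p$y, si)$y,
          stats::approx(p$s, p$z, si)$y,
          stats::approx(p$s, r, si)$y)
  }, parts, radii, SIMPLIFY = FALSE)
  dense <- do.call(rbind, dense)

  lo <- apply(dense[, 1:3, drop = FALSE] - dense[, 4], 2, min) - margin
  hi <- apply(dense[, 1:3, drop = FALSE] + dense[, 4], 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  grid <- cpp_voxelize_tube(dense[, 1:3, drop = FALSE], dense[, 4],
                            dims, lo, spacing)
  dim(grid) <- dims
  voxel_mask(grid, spacing, lo, landmarks = arch$landmarks)
}

#' Write a voxel mask to NIfTI-1
#'
#' The grid is stored as uint8 with the spacing in `pixdim` and the origin
#' in the qform/sform translation, so `write_mask()` then [read_mask()] is
#' the identity on grid, spacing and origin.  Landmarks, if present, are
#' written to a JSON sidecar (same path with extension `.landmarks.json`)
#' unless `landmark_path` says otherwise.
#'
#' @param mask A [voxel_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param landmark_path Optional sidecar path, `NA` to skip.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, landmark_path = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  xf <- diag(4)
  xf[1, 1] <- mask$spacing[1]; xf[2, 2] <- mask$spacing[2]
  xf[3, 3] <- mask$spacing[3]
  xf[1:3, 4] <- mask$origin
  arr <- mask$grid
  attr(arr, "pixdim") <- mask$spacing
  attr(arr, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(arr, datatype = "uint8")
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(mask$landmarks) && !identical(landmark_path, NA)) {
    lp <- landmark_path %||% sub("\\.nii(\\.gz)?$", ".landmarks.json", path)
    write_landmarks(mask$landmarks, lp)
  }
  invisible(path)
}

#' Read a voxel mask from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param landmark_path Optional landmark JSON sidecar; the default looks
#'   for the `write_mask()` sidecar next to `path`.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path, landmark_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D",
         call. = FALSE)
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1)))
    stop("volume is not a binary mask (values other than {0, 1} present)",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  lp <- landmark_path %||% sub("\\.nii(\\.gz)?$", ".landmarks.json", path)
  lm <- if (file.exists(lp)) read_landmarks(lp) else NULL
  voxel_mask(arr, spacing, origin, landmarks = lm)
}

#' Write landmarks to JSON
#'
#' @param landmarks Named list of `list(xyz =, s =)` entries.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  out <- lapply(landmarks, function(l)
    list(xyz = as.numeric(l$xyz),
         s = if (!is.null(l$s) && is.finite(l$s)) l$s else NULL))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path JSON path written by [write_landmarks()].
#' @return Named list of `list(xyz =, s =)` entries.
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(l) list(xyz = as.numeric(l$xyz),
                               s = if (!is.null(l$s)) l$s else NA_real_))
}

#' Export an analytic arch centerline to CSV
#'
#' Columns `s_mm, x_mm, y_mm, z_mm, radius_mm`.
#'
#' @param arch An [build_arch()] result.
#' @param path CSV output path.
#' @param landmark_path Optional JSON sidecar (default alongside `path`).
#' @return `path`, invisibly.
#' @export
write_centerline <- function(arch, path, landmark_path = NULL) {
  stopifnot(inherits(arch, "analytic_arch"))
  cl <- arch$centerline
  utils::write.csv(data.frame(s_mm = cl$s, x_mm = cl$x, y_mm = cl$y,
                              z_mm = cl$z, radius_mm = cl$radius),
                   path, row.names = FALSE)
  lp <- landmark_path %||% sub("\\.csv$", ".landmarks.json", path)
  write_landmarks(arch$landmarks, lp)
  invisible(path)
}

#' Read a centerline CSV (plus landmark sidecar if present)
#'
#' @param path CSV written by [write_centerline()].
#' @param landmark_path Optional landmark JSON path.
#' @return List with `centerline` (data.frame `s, x, y, z, radius`) and
#'   `landmarks` (or NULL).
#' @export
read_centerline <- function(path, landmark_path = NULL) {
  df <- utils::read.csv(path)
  need <- c("s_mm", "x_mm", "y_mm", "z_mm", "radius_mm")
  if (!all(need %in% names(df)))
    stop("centerline CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lp <- landmark_path %||% sub("\\.csv$", ".landmarks.json", path)
  list(centerline = data.frame(s = df$s_mm, x = df$x_mm, y = df$y_mm,
                               z = df$z_mm, radius = df$radius_mm),
       landmarks = if (file.exists(lp)) read_landmarks(lp) else NULL)
}
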