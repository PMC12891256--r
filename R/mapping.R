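#' Construct a GCIPL thickness map
#'
#' A fovea-centred raster of GCIPL thickness on 100 um squares, 160 x 160 by
#' default (16 x 16 mm). Retinal coordinates: x positive temporal, y positive
#' superior retina, right-eye normalised. The centre of square (row i, col j),
#' 1-based with row 1 at the superior edge, lies at
#' x = (j - 0.5) * 0.1 - 8, y = 8 - (i - 0.5) * 0.1 mm.
#'
#' @param values Numeric matrix (um); `NA` marks invalid squares.
#' @param square_size_mm Side of a grid square, default 0.1 mm.
#' @param laterality `"OD"` or `"OS"` (stored; values are assumed already
#'   right-eye normalised).
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, square_size_mm = 0.1, laterality = "OD") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(values < 0, na.rm = TRUE)) stop("thickness values must be >= 0 where valid")
  structure(list(
    values = values,
    square_size_mm = square_size_mm,
    valid_mask = !is.na(values),
    n = nrow(values),
    laterality = match.arg(laterality, c("OD", "OS"))
  ), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("GCIPL thickness map: %d x %d squares of %.0f um, %.1f%% valid, mean %.1f um\n",
              x$n, x$n, 1000 * x$square_size_mm, 100 * mean(x$valid_mask),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# Square-centre coordinates (mm, fovea-centred) for an n x n raster.
raster_axes <- function(map) {
  half <- map$n * map$square_size_mm / 2
  xc <- (seq_len(map$n) - 0.5) * map$square_size_mm - half
  yc <- half - (seq_len(map$n) - 0.5) * map$square_size_mm
  list(x = xc, y = yc)
}

#' Convert visual angle to retinal distance
#'
#' Default model is linear Bennett-style scaling q = 0.01306 * (AL - 1.82)
#' mm/deg, where AL is axial length in mm. A user-supplied nonlinear
#' tangential-plane model may be plugged in as a function of
#' (angle_deg, axial_length_mm).
#'
#' @param angle_deg Signed visual angle (degrees).
#' @param axial_length_mm Axial length (mm); required, no emmetropic default.
#' @param model `"bennett"` or a function `(angle_deg, axial_length_mm) -> mm`.
#' @return Signed retinal distance (mm).
#' @export
degrees_to_mm <- function(angle_deg, axial_length_mm, model = "bennett") {
  if (missing(axial_length_mm) || is.null(axial_length_mm) || anyNA(axial_length_mm))
    stop("axial_length_mm is required")
  if (is.function(model)) return(model(angle_deg, axial_length_mm))
  stopifnot(identical(model, "bennett"))
  q <- 0.01306 * (axial_length_mm - 1.82)
  angle_deg * q
}

#' Eye biometry record
#' @param axial_length_mm Axial length (mm), typically 21-28.
#' @param age_years Age (years), >= 20 for the study population.
#' @param fovea_disc_tilt_deg Fovea-to-optic-disc tilt (degrees).
#' @return A list of class `eye_biometry`.
#' @export
eye_biometry <- function(axial_length_mm, age_years, fovea_disc_tilt_deg = 7) {
  stopifnot(axial_length_mm > 15, axial_length_mm < 35, age_years >= 0)
  structure(list(axial_length_mm = axial_length_mm, age_years = age_years,
                 fovea_disc_tilt_deg = fovea_disc_tilt_deg),
            class = "eye_biometry")
}

#' Project a 24-2 stimulus location onto the retina
#'
#' Field-to-retina projection flips both axes (the image is inverted), and the
#' stimulus footprint is a Goldmann III stimulus (0.43 deg diameter) plus a
#' microsaccade allowance added to the radius (default 0.5 deg, total angular
#' radius 0.715 deg), converted to mm with [degrees_to_mm()].
#'
#' @param x_deg,y_deg Field coordinates of the location.
#' @param biometry An [eye_biometry()].
#' @param stimulus_diameter_deg Default 0.43.
#' @param microsaccade_deg Allowance added to the radius; default 0.5.
#' @param model Magnification model passed to [degrees_to_mm()].
#' @return A `retinal_region`: list with `center_mm` (x, y), `radii_mm`
#'   (rx, ry) and the source field location.
#' @export
project_stimulus <- function(x_deg, y_deg, biometry,
                             stimulus_diameter_deg = 0.43,
                             microsaccade_deg = 0.5, model = "bennett") {
  stopifnot(inherits(biometry, "eye_biometry"))
  cx <- degrees_to_mm(-x_deg, biometry$axial_length_mm, model)
  cy <- degrees_to_mm(-y_deg, biometry$axial_length_mm, model)
  r_deg <- stimulus_diameter_deg / 2 + microsaccade_deg
  # local scale at the location's eccentricity (constant for the linear model)
  rr <- abs(degrees_to_mm(r_deg, biometry$axial_length_mm, model))
  structure(list(center_mm = c(x = unname(cx), y = unname(cy)),
                 radii_mm = c(rx = rr, ry = rr),
                 vf_location = c(x_deg = x_deg, y_deg = y_deg)),
            class = "retinal_region")
}

#' Henle-fibre (ganglion cell) displacement curve
#'
#' Radial displacement (mm) between a central photoreceptor and its ganglion
#' cells as a function of retinal eccentricity (mm). A smooth Drasdo-style
#' bump peaking near 0.4 mm displacement around 1 mm eccentricity and clamped
#' to zero beyond the maximum displacement zone (3.4 mm).
#'
#' @param ecc_mm Eccentricity from the fovea (mm), vectorised.
#' @param d_max Peak displacement (mm), default 0.37.
#' @param ecc_peak Eccentricity of the peak (mm), default 1.0.
#' @param ecc_zero Edge of the displacement zone (mm), default 3.4.
#' @return Displacement (mm), zero at and beyond `ecc_zero`.
#' @export
henle_displacement <- function(ecc_mm, d_max = 0.37, ecc_peak = 1.0, ecc_zero = 3.4) {
  # gamma-shaped bump rescaled so it reaches exactly 0 at ecc_zero
  shape <- function(r) {
    u <- pmax(r, 0) / ecc_peak
    u^2 * exp(2 * (1 - u))
  }
  base <- shape(ecc_mm) - shape(ecc_zero)
  d <- d_max * base / (1 - shape(ecc_zero))
  d[ecc_mm >= ecc_zero] <- 0
  pmax(d, 0)
}

# The 16 central 24-2 locations (|x| and |y| <= 9 deg).
is_central16 <- function(x_deg, y_deg) abs(x_deg) <= 9 & abs(y_deg) <= 9

#' Apply Henle-fibre displacement to a stimulus region
#'
#' For the central 16 24-2 locations only, the region's radial margins are
#' displaced outward from the fovea by the displacement curve evaluated at
#' each margin's own eccentricity; the new centre and radial radius follow
#' from the displaced margins. Other locations are returned unchanged.
#'
#' @param region A `retinal_region` from [project_stimulus()].
#' @param displacement_fn Displacement curve; default [henle_displacement()].
#'   Supplying `function(e) 0 * e` makes this the identity.
#' @return A displaced `retinal_region`.
#' @export
apply_henle_displacement <- function(region, displacement_fn = henle_displacement) {
  stopifnot(inherits(region, "retinal_region"))
  loc <- region$vf_location
  if (!is_central16(loc[["x_deg"]], loc[["y_deg"]])) return(region)
  cx <- region$center_mm[["x"]]; cy <- region$center_mm[["y"]]
  ecc <- sqrt(cx^2 + cy^2)
  if (ecc < .Machine$double.eps) return(region)
  rr <- region$radii_mm[["rx"]]          # radial half-extent
  e_in  <- max(ecc - rr, 0); e_out <- ecc + rr
  e_in2  <- e_in + displacement_fn(e_in)
  e_out2 <- e_out + displacement_fn(e_out)
  ecc2 <- (e_in2 + e_out2) / 2
  rr2  <- (e_out2 - e_in2) / 2
  u <- c(cx, cy) / ecc
  structure(list(center_mm = c(x = u[1] * ecc2, y = u[2] * ecc2),
                 radii_mm = c(rx = rr2, ry = region$radii_mm[["ry"]]),
                 vf_location = loc),
            class = "retinal_region")
}

#' Mean thickness over an elliptical stimulus region
#'
#' Averages raster values over valid squares whose centres fall inside the
#' region's ellipse (equal-area squares, so the mean is unweighted over
#' included squares). Coverage is the valid overlapped area divided by the
#' ellipse area, capped at 1.
#'
#' @param map A [thickness_map()].
#' @param region A `retinal_region`.
#' @return List with `mean_um` (`NA` when no valid square is overlapped) and
#'   `coverage` in \[0, 1\].
#' @export
sample_mean_thickness <- function(map, region) {
  stopifnot(inherits(map, "thickness_map"), inherits(region, "retinal_region"))
  ax <- raster_axes(map)
  cx <- region$center_mm[["x"]]; cy <- region$center_mm[["y"]]
  rx <- region$radii_mm[["rx"]]; ry <- region$radii_mm[["ry"]]
  stopifnot(rx > 0, ry > 0)
  jx <- which(abs(ax$x - cx) <= rx)
  iy <- which(abs(ax$y - cy) <= ry)
  if (!length(jx) || !length(iy))
    return(list(mean_um = NA_real_, coverage = 0))
  dx2 <- ((ax$x[jx] - cx) / rx)^2
  dy2 <- ((ax$y[iy] - cy) / ry)^2
  inside <- outer(dy2, dx2, "+") <= 1
  vals <- map$values[iy, jx, drop = FALSE]
  sel <- inside & map$valid_mask[iy, jx, drop = FALSE]
  n_valid <- sum(sel)
  if (n_valid == 0) return(list(mean_um = NA_real_, coverage = 0))
  area_sq <- map$square_size_mm^2
  list(mean_um = mean(vals[sel]),
       coverage = min(1, n_valid * area_sq / (pi * rx * ry)))
}

# ---- hemi-cluster assignment -------------------------------------------------

# Cluster-group labels ordered central -> peripheral.
cluster_group_levels <- function() c("C6-8", "C4-5", "C3", "C2", "C1")

#' Build the schematic hemi-cluster assignment
#'
#' Partitions the 52 analyzable 24-2 locations, per hemifield, into five
#' eccentricity-ordered cluster groups (central "C6-8" through peripheral
#' "C1") with per-hemifield sizes 2/4/7/9/4, and labels every raster square
#' within the 24-2 span by the hemi-cluster of its nearest projected location.
#' This ring template is a synthetic schematic standing in for a
#' normative-database cluster map; real analyses should supply their own map
#' via `grid_labels`.
#'
#' @param map A [thickness_map()] providing the raster geometry.
#' @param biometry Biometry used to project locations onto the raster
#'   (defaults to AL 24 mm).
#' @param sizes Per-hemifield group sizes central to peripheral; default
#'   `c(2, 4, 7, 9, 4)`.
#' @param grid_labels Optional user-supplied character matrix of hemi-cluster
#'   ids per raster square (`NA` outside the analysed span); overrides the
#'   schematic grid labelling.
#' @return A `cluster_assignment`: `vf_labels` (hemi-cluster id per analyzable
#'   location, e.g. `"C3.superior"`, hemifield in *field* space), `vf_group`,
#'   `vf_hemifield`, and `grid_labels` (matrix over the raster).
#' @export
build_cluster_assignment <- function(map, biometry = eye_biometry(24, 60),
                                     sizes = c(2, 4, 7, 9, 4),
                                     grid_labels = NULL) {
  grid <- vf_grid_analyzable()
  stopifnot(sum(sizes) * 2 == nrow(grid))
  ecc <- sqrt(grid$x_deg^2 + grid$y_deg^2)
  hemi <- vf_hemifield(grid$y_deg)
  group <- character(nrow(grid))
  for (h in c("superior", "inferior")) {
    idx <- which(hemi == h)
    # deterministic eccentricity ranking; ties broken by |x| then x then y
    o <- idx[order(ecc[idx], abs(grid$x_deg[idx]), grid$x_deg[idx], grid$y_deg[idx])]
    group[o] <- rep(cluster_group_levels(), times = sizes)
  }
  vf_labels <- paste(group, hemi, sep = ".")

  if (is.null(grid_labels)) {
    # label raster squares by nearest projected analyzable location, within
    # the retinal span of the 24-2 (plus one stimulus radius margin)
    proj_x <- degrees_to_mm(-grid$x_deg, biometry$axial_length_mm)
    proj_y <- degrees_to_mm(-grid$y_deg, biometry$axial_length_mm)
    ax <- raster_axes(map)
    X <- matrix(ax$x, nrow = map$n, ncol = map$n, byrow = TRUE)
    Y <- matrix(ax$y, nrow = map$n, ncol = map$n)
    margin <- abs(degrees_to_mm(3, biometry$axial_length_mm))
    # retinal hemifield is the flip of the field hemifield
    ret_sup <- proj_y > 0
    grid_labels <- matrix(NA_character_, map$n, map$n)
    for (side in c(TRUE, FALSE)) {
      pts <- which(ret_sup == side)
      sq <- which(if (side) Y > 0 else Y <= 0)
      d2 <- outer(X[sq], proj_x[pts], "-")^2 + outer(Y[sq], proj_y[pts], "-")^2
      nearest <- pts[max.col(-d2, ties.method = "first")]
      ok <- sqrt(apply(d2, 1, min)) <= margin
      grid_labels[sq[ok]] <- vf_labels[nearest[ok]]
    }
  } else {
    stopifnot(is.matrix(grid_labels), all(dim(grid_labels) == map$n))
    if (!all(stats::na.omit(unique(as.vector(grid_labels))) %in% vf_labels))
      stop("grid_labels contains hemi-cluster ids not present among VF labels")
  }
  if (anyNA(vf_labels)) stop("template left a VF location unlabelled")
  structure(list(vf_labels = vf_labels, vf_group = group, vf_hemifield = hemi,
                 grid_labels = grid_labels),
            class = "cluster_assignment")
}

#' Mirror hemi-cluster id across the horizontal midline
#' @param label Hemi-cluster id such as `"C3.superior"`.
#' @return The opposite-hemifield id.
#' @export
mirror_hemicluster <- function(label) {
  out <- sub("\\.superior$", ".SWAP", label)
  out <- sub("\\.inferior$", ".superior", out)
  sub("\\.SWAP$", ".inferior", out)
}
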