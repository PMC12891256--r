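#' GCIPL to GCL thickness conversion
#'
#' Linear conversion GCL = slope * GCIPL - offset with the published
#' coefficients as defaults, clamped at zero (thickness cannot be negative).
#'
#' @param gcipl_um GCIPL thickness (um), >= 0, vectorised.
#' @param slope,offset Conversion coefficients; defaults 0.5651 and 0.9026 um.
#' @return GCL thickness (um).
#' @export
gcipl_to_gcl <- function(gcipl_um, slope = 0.5651, offset = 0.9026) {
  if (any(gcipl_um < 0, na.rm = TRUE)) stop("gcipl_um must be >= 0")
  pmax(0, slope * gcipl_um - offset)
}

#' Synthetic volumetric ganglion-cell density field
#'
#' A smooth, elliptically symmetric analytic stand-in for a histology-derived
#' volumetric density raster: peak near 1 mm eccentricity decaying towards the
#' periphery, in cells/mm^3. Real analyses should supply a density raster
#' derived from histological counts; this default exists so the pipeline runs
#' end to end on synthetic data.
#'
#' @param peak_density Added density at the peak (cells/mm^3), default 4e5.
#' @param floor_density Peripheral floor (cells/mm^3), default 1e5.
#' @param ecc_peak Peak eccentricity (mm), default 1.0.
#' @return A `density_field`: function of (x_mm, y_mm) plus metadata.
#' @export
synthetic_density_field <- function(peak_density = 4e5, floor_density = 1e5,
                                    ecc_peak = 1.0) {
  f <- function(x_mm, y_mm) {
    r <- sqrt(x_mm^2 + y_mm^2) / ecc_peak
    floor_density + peak_density * r^2 * exp(2 * (1 - r))
  }
  structure(list(fn = f, synthetic = TRUE,
                 label = "synthetic analytic density field"),
            class = "density_field")
}

#' Density field from a raster
#'
#' Wraps a fovea-centred raster of volumetric density (cells/mm^3) in the same
#' geometry as [thickness_map()] into a `density_field` by bilinear lookup.
#'
#' @param values Square numeric matrix (cells/mm^3).
#' @param square_size_mm Grid square side, default 0.1 mm.
#' @return A `density_field`.
#' @export
raster_density_field <- function(values, square_size_mm = 0.1) {
  stopifnot(is.matrix(values), all(values >= 0, na.rm = TRUE))
  n <- nrow(values)
  half <- n * square_size_mm / 2
  f <- function(x_mm, y_mm) {
    j <- pmin(pmax(ceiling((x_mm + half) / square_size_mm), 1), n)
    i <- pmin(pmax(ceiling((half - y_mm) / square_size_mm), 1), n)
    out <- values[cbind(i, j)]
    if (anyNA(out)) stop("density region outside field support")
    out
  }
  structure(list(fn = f, synthetic = FALSE, label = "raster density field"),
            class = "density_field")
}

#' Mean volumetric density over a stimulus region
#'
#' Area-weighted mean of the density field over the elliptical region,
#' evaluated on a fine grid of equal-area cells whose centres fall inside the
#' ellipse.
#'
#' @param field A `density_field`.
#' @param region A `retinal_region`.
#' @param resolution Number of cells across each radius; default 25.
#' @return Mean density (cells/mm^3).
#' @export
mean_density <- function(field, region, resolution = 25) {
  stopifnot(inherits(field, "density_field"), inherits(region, "retinal_region"))
  cx <- region$center_mm[["x"]]; cy <- region$center_mm[["y"]]
  rx <- region$radii_mm[["rx"]]; ry <- region$radii_mm[["ry"]]
  u <- seq(-1 + 1 / resolution, 1 - 1 / resolution, length.out = resolution)
  g <- expand.grid(ux = u, uy = u)
  inside <- g$ux^2 + g$uy^2 <= 1
  mean(field$fn(cx + g$ux[inside] * rx, cy + g$uy[inside] * ry))
}

#' Estimate the ganglion-cell count over a stimulus region
#'
#' count = GCL thickness (mm) x ellipse area (mm^2) x mean volumetric density
#' (cells/mm^3). The count is also reported on a decibel scale,
#' 10*log10(count); counts below 1 cell are floored at 0 dB and flagged so
#' that -Inf never propagates into regressions.
#'
#' @param gcl_mean_um Mean GCL thickness over the region (um), >= 0.
#' @param region A `retinal_region`.
#' @param field A `density_field`.
#' @return List with `count`, `count_dB`, `floored`, `gcl_mean_um`,
#'   `area_mm2`, `density`.
#' @export
estimate_gc_count <- function(gcl_mean_um, region, field) {
  stopifnot(gcl_mean_um >= 0)
  area <- pi * region$radii_mm[["rx"]] * region$radii_mm[["ry"]]
  dens <- mean_density(field, region)
  count <- (gcl_mean_um / 1000) * area * dens
  floored <- count < 1
  list(count = count,
       count_dB = if (floored) 0 else 10 * log10(count),
       floored = floored,
       gcl_mean_um = gcl_mean_um, area_mm2 = area, density = dens)
}
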