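#' Synthetic cohort generator configuration
#'
#' Default parameters emulate the study population: cohort composition
#' 311 healthy / 268 suspect / 269 glaucoma eyes, ages ~55-67 years, axial
#' lengths ~24 mm, and a structure-function forward model whose segmented
#' parameters are the pooled non-defective and defective fits reported for
#' the clinical cohort (intercept/slope1/breakpoint/slope2 = 24.26 / 0.41 /
#' 17.8 / 0.14 and 10.85 / 0.51 / 17.31 / 1.00), with small threshold noise
#' at non-defective locations (2 dB) and large noise at defective locations
#' (9 dB), echoing the reported error contrast.
#'
#' @param n_healthy,n_suspect,n_glaucoma Cohort sizes.
#' @param seed Integer seed; every generated quantity is reproducible from it.
#' @param peak_um,ecc_peak_mm,floor_um Healthy GCIPL surface: peripheral floor
#'   plus a gamma-shaped annular peak (um / mm / um).
#' @param inter_eye_sd_um SD of the per-eye additive thickness offset.
#' @param age_effect_um_per_yr Thickness change per year (negative = thinning).
#' @param tilt_effect_um_per_deg Thickness change per degree of fovea-disc tilt.
#' @param noise_sd_um Per-square measurement noise SD.
#' @param defect_depth_um Range (min, max) of glaucomatous defect depth.
#' @param defect_pattern_probs Sampling probabilities for the arcuate,
#'   hemifield and paracentral defect patterns (in that order).
#' @param residual_floor_um Non-neural residual thickness floor under defects.
#' @param sf_nd,sf_d Segmented forward models (intercept, slope1, breakpoint,
#'   slope2) for non-defective and defective locations.
#' @param vf_noise_nd_sd,vf_noise_d_sd Threshold noise SDs (dB) by state.
#' @param two_vfs Generate a second same-visit VF per eye.
#' @param rocc_n_healthy,rocc_n_glaucoma ROCC-cohort sizes (healthy and
#'   perimetric glaucoma), defaults 119 and 90, capped at availability.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_healthy = 311, n_suspect = 268, n_glaucoma = 269,
                             seed = 1,
                             peak_um = 75, ecc_peak_mm = 1.1, floor_um = 25,
                             inter_eye_sd_um = 4,
                             age_effect_um_per_yr = -0.1,
                             tilt_effect_um_per_deg = 0.1,
                             noise_sd_um = 2,
                             defect_depth_um = c(20, 60),
                             defect_pattern_probs = c(arcuate = 0.5,
                                                      hemifield = 0.3,
                                                      paracentral = 0.2),
                             residual_floor_um = 15,
                             sf_nd = c(intercept = 24.26, slope1 = 0.41,
                                       breakpoint = 17.8, slope2 = 0.14),
                             sf_d = c(intercept = 10.85, slope1 = 0.51,
                                      breakpoint = 17.31, slope2 = 1.00),
                             vf_noise_nd_sd = 2, vf_noise_d_sd = 9,
                             two_vfs = FALSE,
                             rocc_n_healthy = 119, rocc_n_glaucoma = 90) {
  stopifnot(n_healthy >= 0, n_suspect >= 0, n_glaucoma >= 0,
            inter_eye_sd_um >= 0, noise_sd_um >= 0,
            vf_noise_nd_sd >= 0, vf_noise_d_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# Evaluate a segmented forward model (named vector) at GC count x (dB).
eval_segmented <- function(par, x) {
  par[["intercept"]] + par[["slope1"]] * x +
    (par[["slope2"]] - par[["slope1"]]) * pmax(x - par[["breakpoint"]], 0)
}

# Healthy GCIPL surface (um) at eccentricity r (mm).
healthy_surface <- function(r, config) {
  u <- r / config$ecc_peak_mm
  config$floor_um + config$peak_um * u^2 * exp(2 * (1 - u))
}

#' Generate a healthy GCIPL thickness map
#'
#' Smooth eccentricity-dependent surface plus a per-eye offset, linear age
#' and tilt effects, and i.i.d. measurement noise; values clamped to
#' \[0, 150\] um. Uses the current RNG state.
#'
#' @param config A [generator_config()].
#' @param biometry The eye's [eye_biometry()].
#' @param n Raster side, default 160.
#' @return List with `map` (the observed [thickness_map()]), `truth`
#'   (noiseless matrix, before measurement noise) and `offset_um`.
#' @export
generate_healthy_map <- function(config, biometry, n = 160) {
  sq <- 0.1
  half <- n * sq / 2
  xc <- (seq_len(n) - 0.5) * sq - half
  yc <- half - (seq_len(n) - 0.5) * sq
  R <- sqrt(outer(yc^2, xc^2, "+"))
  offset <- stats::rnorm(1, 0, config$inter_eye_sd_um)
  truth <- healthy_surface(R, config) + offset +
    config$age_effect_um_per_yr * (biometry$age_years - 60) +
    config$tilt_effect_um_per_deg * (biometry$fovea_disc_tilt_deg - 7)
  truth <- pmin(pmax(truth, 0), 150)
  obs <- truth + matrix(stats::rnorm(n * n, 0, config$noise_sd_um), n, n)
  obs <- pmin(pmax(obs, 0), 150)
  list(map = thickness_map(obs), truth = truth, offset_um = offset)
}

#' Inject a glaucomatous defect into a thickness map
#'
#' Reduces thickness within an arcuate, hemifield or paracentral region of
#' one retinal hemifield by the given depth with smooth (raised-cosine)
#' margins, never below the residual non-neural floor. The defect respects
#' the horizontal midline by construction.
#'
#' @param truth Noiseless thickness matrix (um).
#' @param pattern `"arcuate"`, `"hemifield"` or `"paracentral"`.
#' @param depth_um Maximum thinning (um).
#' @param hemifield_retina `"superior"` or `"inferior"` retinal hemifield.
#' @param floor_um Residual floor, default 15 um.
#' @param extent Scale factor (>0) on the region's size, default 1.
#' @return List with `values` (thinned matrix) and `weight` (thinning weight
#'   in \[0, 1\] per square; the defect mask is `weight > 0.5`).
#' @export
inject_defect <- function(truth, pattern = c("arcuate", "hemifield", "paracentral"),
                          depth_um, hemifield_retina = c("superior", "inferior"),
                          floor_um = 15, extent = 1) {
  pattern <- match.arg(pattern)
  hemifield_retina <- match.arg(hemifield_retina)
  n <- nrow(truth); sq <- 0.1; half <- n * sq / 2
  xc <- (seq_len(n) - 0.5) * sq - half
  yc <- half - (seq_len(n) - 0.5) * sq
  X <- matrix(xc, n, n, byrow = TRUE)
  Y <- matrix(yc, n, n)
  R <- sqrt(X^2 + Y^2)
  ysign <- if (hemifield_retina == "superior") 1 else -1
  # smooth half-plane weight with a 0.3 mm rolloff at the midline
  hemi_w <- pmin(pmax(ysign * Y / 0.3, 0), 1)
  cosw <- function(d, width) ifelse(abs(d) >= width, 0, 0.5 * (1 + cos(pi * d / width)))
  w <- switch(pattern,
    hemifield = hemi_w,
    arcuate = {
      theta <- atan2(ysign * Y, X)               # 0 at temporal horizontal
      # band wide enough (~2 mm at half depth) to straddle the 6-degree
      # spacing of projected 24-2 locations
      radial <- cosw(R - 2.7 * extent, 2.2 * extent)
      angular <- cosw(theta - pi / 2, pi / 2 * 1.3)
      radial * angular * hemi_w
    },
    paracentral = {
      cx <- -1.2 * extent; cy <- ysign * 1.0 * extent
      d <- sqrt((X - cx)^2 + (Y - cy)^2)
      cosw(d, 1.6 * extent) * hemi_w
    })
  if (depth_um < 0) stop("depth_um must be >= 0")
  thinned <- pmax(pmin(truth, 150) - depth_um * w, pmin(truth, floor_um))
  list(values = thinned, weight = w)
}

# Reference distributions of healthy TD/PD per location, simulated from the
# generator's own healthy process; used to grade probability categories.
vf_reference <- function(config, n_ref = 150,
                         field = synthetic_density_field()) {
  grid <- vf_grid_analyzable()
  td <- matrix(NA_real_, n_ref, nrow(grid))
  counts <- matrix(NA_real_, n_ref, nrow(grid))
  for (i in seq_len(n_ref)) {
    bio <- eye_biometry(stats::rnorm(1, 24, 1.1),
                        round(stats::rnorm(1, 60, 13)),
                        stats::rnorm(1, 7, 3.8))
    hm <- generate_healthy_map(config, bio)
    est <- project_and_estimate(hm$map, bio, field)
    counts[i, ] <- est$count_dB
    thr <- eval_segmented(config$sf_nd, est$count_dB) +
      stats::rnorm(nrow(grid), 0, config$vf_noise_nd_sd)
    td[i, ] <- thr
  }
  # long eyes can project peripheral locations off the raster -> NA counts
  mean_thr <- colMeans(td, na.rm = TRUE)
  td_dev <- sweep(td, 2, mean_thr)
  pd_dev <- td_dev - apply(td_dev, 1, stats::quantile, 0.85, type = 7, na.rm = TRUE)
  qs <- c(0.005, 0.01, 0.02, 0.05)
  list(mean_threshold = mean_thr,
       td_cut = apply(td_dev, 2, stats::quantile, qs, type = 7, na.rm = TRUE),
       pd_cut = apply(pd_dev, 2, stats::quantile, qs, type = 7, na.rm = TRUE),
       mean_count_dB = colMeans(counts, na.rm = TRUE))
}

# Grade deviations into ordinal probability categories given per-location
# cutoff matrix (4 x n_loc for p<0.5/1/2/5).
grade_probs <- function(dev, cuts) {
  lv <- vf_prob_levels()
  out <- rep(lv[5], length(dev))
  for (k in 4:1) out[dev < cuts[k, ]] <- lv[k]
  out
}

#' Simulate a 24-2 visual field from estimated GC counts
#'
#' Thresholds follow the state-dependent segmented forward model plus
#' Gaussian noise (small at non-defective, large at defective locations),
#' clamped to \[0, 40\] dB. Total deviation is graded against the generator's
#' own healthy reference distribution; pattern deviation re-zeroes total
#' deviation at its 85th percentile, mirroring perimeter convention. MD and
#' PSD are the mean and SD of total deviation. Uses the current RNG state.
#'
#' @param count_dB GC count (dB) per analyzable location.
#' @param defective Logical state per location.
#' @param config A [generator_config()].
#' @param reference Output of the internal healthy-reference simulation
#'   (built by [generate_cohort()]).
#' @return A [vf_result()].
#' @export
vf_from_structure <- function(count_dB, defective, config, reference) {
  n <- length(count_dB)
  stopifnot(n == 52, length(defective) == n)
  if (anyNA(count_dB)) {
    # off-raster locations: fall back to the healthy reference mean count
    count_dB <- ifelse(is.na(count_dB), reference$mean_count_dB, count_dB)
  }
  mu <- ifelse(defective,
               eval_segmented(config$sf_d, count_dB),
               eval_segmented(config$sf_nd, count_dB))
  sd <- ifelse(defective, config$vf_noise_d_sd, config$vf_noise_nd_sd)
  thr <- pmin(pmax(mu + stats::rnorm(n, 0, sd), 0), 40)
  td <- thr - reference$mean_threshold
  pd <- td - stats::quantile(td, 0.85, type = 7, names = FALSE)
  md <- mean(td)
  psd <- stats::sd(td)
  pd_available <- md > -20
  vf_result(
    thresholds_dB = thr,
    total_deviation_dB = td,
    pattern_deviation_dB = pd,
    td_prob = grade_probs(td, reference$td_cut),
    pd_prob = if (pd_available) grade_probs(pd, reference$pd_cut) else NULL,
    md_dB = md, psd_dB = psd,
    false_positive_rate = stats::rbeta(1, 2, 38),
    pd_map_available = pd_available
  )
}

#' Generate a complete synthetic cohort
#'
#' Produces healthy, glaucoma-suspect and glaucoma eyes with coupled
#' structure and function: healthy surfaces with age/tilt effects and noise;
#' suspects with borderline diffuse or shallow focal thinning below
#' treatment-level defects; glaucoma eyes with arcuate, hemifield or
#' paracentral defects of configurable depth; and visual fields generated
#' from each eye's estimated GC counts through the state-dependent segmented
#' forward model. Ground truth (noiseless maps, defect weights, per-location
#' counts and states) is stored alongside the observables.
#'
#' @param config A [generator_config()].
#' @param field Density field used for GC counts; default
#'   [synthetic_density_field()].
#' @param n_reference Internal healthy replicates for the TD/PD reference
#'   distributions, default 150.
#' @return A `synthetic_cohort`: `eyes` (list of synthetic eyes), `split`
#'   (`rocc_ids`, `test_ids`), `reference`, `config`.
#' @export
generate_cohort <- function(config, field = synthetic_density_field(),
                            n_reference = 150) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  reference <- vf_reference(config, n_reference, field)
  diagnoses <- rep(c("healthy", "suspect", "glaucoma"),
                   c(config$n_healthy, config$n_suspect, config$n_glaucoma))
  eyes <- vector("list", length(diagnoses))
  for (i in seq_along(diagnoses)) {
    dg <- diagnoses[i]
    bio <- eye_biometry(
      axial_length_mm = min(max(stats::rnorm(1, 24, 1.1), 21.03), 27.60),
      age_years = round(min(max(stats::rnorm(1, switch(dg, healthy = 55, suspect = 62, 65),
                                             13), 20), 95)),
      fovea_disc_tilt_deg = stats::rnorm(1, 7, 3.8))
    hm <- generate_healthy_map(config, bio)
    truth <- hm$truth
    weight <- matrix(0, nrow(truth), ncol(truth))
    depth <- 0
    pattern <- NA_character_
    if (dg == "glaucoma") {
      pattern <- sample(c("arcuate", "hemifield", "paracentral"), 1,
                        prob = config$defect_pattern_probs)
      depth <- stats::runif(1, config$defect_depth_um[1], config$defect_depth_um[2])
      dj <- inject_defect(truth, pattern, depth,
                          sample(c("superior", "inferior"), 1),
                          config$residual_floor_um,
                          extent = stats::runif(1, 0.8, 1.3))
      truth <- dj$values; weight <- dj$weight
    } else if (dg == "suspect") {
      truth <- pmax(truth - stats::runif(1, 0, 6), 0)  # mild diffuse thinning
      if (stats::runif(1) < 0.5) {
        dj <- inject_defect(truth, "paracentral", stats::runif(1, 3, 10),
                            sample(c("superior", "inferior"), 1),
                            config$residual_floor_um,
                            extent = stats::runif(1, 0.6, 1.0))
        truth <- dj$values; weight <- dj$weight
      }
    }
    obs <- truth + matrix(stats::rnorm(length(truth), 0, config$noise_sd_um),
                          nrow(truth), ncol(truth))
    map <- thickness_map(pmin(pmax(obs, 0), 150))
    truth_map <- thickness_map(truth)
    est_truth <- project_and_estimate(truth_map, bio, field)
    # a location is functionally defective when the defect substantially
    # covers its (undisplaced) projected region
    grid <- vf_grid_analyzable()
    wmap <- thickness_map(weight * 150)  # reuse the region sampler on weights
    state <- vapply(seq_len(nrow(grid)), function(k) {
      reg <- project_stimulus(grid$x_deg[k], grid$y_deg[k], bio)
      s <- sample_mean_thickness(wmap, reg)
      !is.na(s$mean_um) && (s$mean_um / 150) >= 0.25 && depth > 5
    }, logical(1))
    vf <- vf_from_structure(est_truth$count_dB, state, config, reference)
    vf2 <- if (config$two_vfs)
      vf_from_structure(est_truth$count_dB, state, config, reference) else NULL
    eyes[[i]] <- structure(list(
      id = sprintf("eye%04d", i), diagnosis = dg, biometry = bio,
      map = map, truth = truth, defect_weight = weight,
      defect_mask = weight > 0.5, defect_depth_um = depth,
      defect_pattern = pattern,
      gc_truth = est_truth, vf_state = state, vf = vf, vf2 = vf2
    ), class = "synthetic_eye")
  }
  ids <- vapply(eyes, `[[`, character(1), "id")
  perimetric <- vapply(eyes, function(e) any(classify_defect_locations(e$vf)),
                       logical(1))
  healthy_ids <- ids[diagnoses == "healthy"]
  pg_ids <- ids[diagnoses == "glaucoma" & perimetric]
  rocc_ids <- c(
    sample(healthy_ids, min(config$rocc_n_healthy, length(healthy_ids))),
    sample(pg_ids, min(config$rocc_n_glaucoma, length(pg_ids)))
  )
  split <- list(rocc_ids = rocc_ids, test_ids = setdiff(ids, rocc_ids))
  structure(list(eyes = eyes, split = split, reference = reference,
                 config = config),
            class = "synthetic_cohort")
}

#' High-coupling validation configuration
#'
#' A cohort condition with strong structure-function coupling and low noise,
#' used to validate that the classification pipeline recovers near-perfect
#' discrimination when the generative link is strong: deep (60-80 um)
#' hemifield defects (the pattern whose spatial footprint aligns exactly
#' with the hemi-cluster aggregation), halved inter-eye variability, small
#' state-dependent VF noise (1 / 1.5 dB) and two VFs per eye so defects can
#' be required to be repeatable.
#'
#' @param seed Integer seed.
#' @param n_healthy,n_glaucoma Cohort sizes, defaults 100 / 80.
#' @param rocc_n_healthy,rocc_n_glaucoma ROCC-cohort sizes, defaults 80 / 60.
#' @return A [generator_config()].
#' @export
high_coupling_config <- function(seed = 1, n_healthy = 100, n_glaucoma = 80,
                                 rocc_n_healthy = 80, rocc_n_glaucoma = 60) {
  generator_config(
    n_healthy = n_healthy, n_suspect = 0, n_glaucoma = n_glaucoma, seed = seed,
    inter_eye_sd_um = 2, noise_sd_um = 2,
    vf_noise_nd_sd = 1, vf_noise_d_sd = 1.5,
    defect_depth_um = c(60, 80),
    defect_pattern_probs = c(arcuate = 0, hemifield = 1, paracentral = 0),
    two_vfs = TRUE,
    rocc_n_healthy = rocc_n_healthy, rocc_n_glaucoma = rocc_n_glaucoma
  )
}

#' Generate normative reference eyes (maps and biometry only)
#'
#' Healthy thickness maps with matching biometry, without the visual-field
#' simulation, for building normative models.
#'
#' @param config A [generator_config()] (its healthy-surface, age/tilt and
#'   noise parameters are used).
#' @param n Number of reference eyes.
#' @param seed Seed for this reference set.
#' @return List of eyes, each with `map`, `biometry`, `truth`.
#' @export
generate_reference_eyes <- function(config, n, seed = config$seed + 1000003L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    bio <- eye_biometry(min(max(stats::rnorm(1, 24, 1.1), 21.03), 27.60),
                        round(min(max(stats::rnorm(1, 55, 13), 20), 95)),
                        stats::rnorm(1, 7, 3.8))
    hm <- generate_healthy_map(config, bio)
    list(map = hm$map, biometry = bio, truth = hm$truth)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  dg <- table(vapply(x$eyes, `[[`, character(1), "diagnosis"))
  cat("Synthetic cohort:", paste(names(dg), dg, sep = "=", collapse = ", "),
      sprintf("| ROCC %d / test %d, seed %d\n",
              length(x$split$rocc_ids), length(x$split$test_ids),
              x$config$seed))
  invisible(x)
}
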