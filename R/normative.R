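#' Build a grid-square normative model
#'
#' For every raster square, fits a linear adjustment of GCIPL thickness on age
#' and fovea-disc tilt across the reference eyes and stores the residuals, so
#' that an individual measurement can later be compared to the age/tilt-
#' matched reference distribution for the same square. Squares valid in fewer
#' than `min_reference` eyes are masked out of the model.
#'
#' The per-square regressions share one design matrix, so the whole raster is
#' fitted in a single multi-response least-squares solve.
#'
#' @param maps List of [thickness_map()] reference eyes.
#' @param biometries List of [eye_biometry()], same length and order.
#' @param min_reference Minimum reference eyes per square, default 20.
#' @return A `normative_model`: `coef` (3 x n^2 matrix: intercept, age, tilt),
#'   `residuals` (n_ref x n^2), `model_mask` (n x n logical), `n`,
#'   `mean_age`, `mean_tilt`.
#' @export
build_normative_db <- function(maps, biometries, min_reference = 20) {
  stopifnot(length(maps) == length(biometries), length(maps) >= min_reference)
  n <- maps[[1]]$n
  nref <- length(maps)
  Y <- vapply(maps, function(m) {
    stopifnot(m$n == n)
    as.vector(m$values)
  }, numeric(n * n))
  Y <- t(Y)  # nref x n^2
  age <- vapply(biometries, `[[`, numeric(1), "age_years")
  tilt <- vapply(biometries, `[[`, numeric(1), "fovea_disc_tilt_deg")
  X <- cbind(1, age - mean(age), tilt - mean(tilt))
  n_ok <- colSums(!is.na(Y))
  usable <- n_ok >= min_reference
  coef <- matrix(NA_real_, 3, n * n)
  resid <- matrix(NA_real_, nref, n * n)
  complete <- colSums(is.na(Y)) == 0
  if (any(complete & usable)) {
    idx <- which(complete & usable)
    f <- stats::lm.fit(X, Y[, idx, drop = FALSE])
    coef[, idx] <- f$coefficients
    resid[, idx] <- f$residuals
  }
  # squares with scattered missing eyes: fit individually
  for (j in which(usable & !complete)) {
    ok <- !is.na(Y[, j])
    f <- stats::lm.fit(X[ok, , drop = FALSE], Y[ok, j])
    coef[, j] <- f$coefficients
    resid[ok, j] <- f$residuals
  }
  # rank-deficient covariates (e.g. constant age) contribute no adjustment
  coef[is.na(coef) & rep(usable, each = 3)] <- 0
  structure(list(coef = coef, residuals = resid,
                 model_mask = matrix(usable, n, n), n = n,
                 n_reference = nref,
                 mean_age = mean(age), mean_tilt = mean(tilt)),
            class = "normative_model")
}

# Age/tilt-adjusted normative mean raster for one eye.
adjusted_mean_raster <- function(norm, biometry) {
  x <- c(1, biometry$age_years - norm$mean_age,
         biometry$fovea_disc_tilt_deg - norm$mean_tilt)
  matrix(crossprod(norm$coef, x), norm$n, norm$n)
}

#' Percentile deviation flag map
#'
#' Flags a raster square when the eye's measurement falls strictly below the
#' `pct` quantile (type-7 linear interpolation) of the normative residual
#' distribution around the age/tilt-adjusted mean for that square.
#'
#' @param map A [thickness_map()].
#' @param biometry The eye's [eye_biometry()].
#' @param norm A `normative_model`.
#' @param pct Flagging percentile as a fraction, default 0.05.
#' @param q_raster Optional precomputed residual-quantile raster from
#'   [norm_quantile_raster()] (saves recomputing it per eye).
#' @return Logical matrix; `NA` where the square is invalid in the eye or
#'   masked in the model.
#' @export
percentile_flag_map <- function(map, biometry, norm, pct = 0.05,
                                q_raster = NULL) {
  stopifnot(inherits(map, "thickness_map"), inherits(norm, "normative_model"),
            map$n == norm$n)
  mu <- adjusted_mean_raster(norm, biometry)
  if (is.null(q_raster)) q_raster <- norm_quantile_raster(norm, pct)
  flags <- (map$values - mu) < q_raster
  flags[!map$valid_mask | !norm$model_mask] <- NA
  flags
}

#' Residual-quantile raster of a normative model
#'
#' The per-square `pct` quantile (type 7) of the reference residuals; the
#' flagging boundary around the adjusted mean.
#'
#' @param norm A `normative_model`.
#' @param pct Quantile as a fraction.
#' @return Numeric matrix.
#' @export
norm_quantile_raster <- function(norm, pct = 0.05) {
  matrix(apply_quantile_cols(norm$residuals, pct), norm$n, norm$n)
}

# Column-wise type-7 quantile, NA-tolerant.
apply_quantile_cols <- function(m, p) {
  apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    stats::quantile(col, p, type = 7, names = FALSE)
  })
}

#' Relative ("pattern-deviation"-style) thickness map
#'
#' Computes each square's total deviation (observed minus age/tilt-adjusted
#' normative mean), then re-zeroes the map at the eye's own 85th percentile of
#' total deviation, so that at most 15% of valid squares are positive. This
#' mirrors how pattern deviation removes generalised depression in perimetry.
#'
#' @param map,biometry,norm As in [percentile_flag_map()].
#' @param pct Re-zeroing percentile, default 0.85.
#' @return List with `total_deviation` and `relative` matrices (um; `NA`
#'   outside valid/model squares).
#' @export
relative_thickness_map <- function(map, biometry, norm, pct = 0.85) {
  stopifnot(inherits(map, "thickness_map"), inherits(norm, "normative_model"))
  mu <- adjusted_mean_raster(norm, biometry)
  td <- map$values - mu
  td[!map$valid_mask | !norm$model_mask] <- NA
  if (all(is.na(td))) stop("no valid squares in map")
  q85 <- stats::quantile(td, pct, na.rm = TRUE, type = 7, names = FALSE)
  list(total_deviation = td, relative = td - q85)
}

#' Proportion of flagged squares per hemi-cluster
#'
#' @param flags Flag matrix from [percentile_flag_map()].
#' @param assignment A `cluster_assignment` with `grid_labels` on the same
#'   raster.
#' @return Named numeric vector of flagged/valid fractions per hemi-cluster
#'   (`NA` when a hemi-cluster has no valid squares).
#' @export
proportion_flagged <- function(flags, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  labs <- assignment$grid_labels
  stopifnot(all(dim(labs) == dim(flags)))
  ids <- sort(unique(assignment$vf_labels))
  out <- vapply(ids, function(id) {
    f <- flags[!is.na(labs) & labs == id]
    f <- f[!is.na(f)]
    if (!length(f)) NA_real_ else mean(f)
  }, numeric(1))
  names(out) <- ids
  out
}
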