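# small rasters keep the normative tests fast
small_map <- function(values) thickness_map(values)

make_reference <- function(n_eyes = 30, n = 20, age_slope = 0, tilt_slope = 0,
                           noise = 1, base = 60, seed = 1) {
  set.seed(seed)
  maps <- list(); bios <- list()
  for (i in seq_len(n_eyes)) {
    bio <- eye_biometry(24, runif(1, 30, 80), runif(1, 0, 14))
    v <- matrix(base + age_slope * (bio$age_years - 60) +
                  tilt_slope * (bio$fovea_disc_tilt_deg - 7), n, n) +
      matrix(rnorm(n * n, 0, noise), n, n)
    maps[[i]] <- small_map(v)
    bios[[i]] <- bio
  }
  list(maps = maps, bios = bios)
}

test_that("identical reference eyes give zero spread and their common map", {
  n <- 10
  v <- matrix(55, n, n)
  maps <- replicate(25, small_map(v), simplify = FALSE)
  bios <- replicate(25, eye_biometry(24, 60, 7), simplify = FALSE)
  norm <- build_normative_db(maps, bios, min_reference = 20)
  mu <- gciplvf:::adjusted_mean_raster(norm, eye_biometry(24, 60, 7))
  expect_equal(mu, matrix(55, n, n), tolerance = 1e-10)
  expect_lt(max(abs(norm$residuals), na.rm = TRUE), 1e-10)
})

test_that("injected age and tilt effects are recovered", {
  ref <- make_reference(n_eyes = 80, age_slope = -0.1, tilt_slope = 0.2,
                        noise = 0.5, seed = 3)
  norm <- build_normative_db(ref$maps, ref$bios)
  age_coefs <- norm$coef[2, ]
  tilt_coefs <- norm$coef[3, ]
  se_age <- sd(age_coefs) / sqrt(length(age_coefs))
  expect_equal(mean(age_coefs), -0.1, tolerance = 0.02)
  expect_equal(mean(tilt_coefs), 0.2, tolerance = 0.05)
})

test_that("the normative model is invariant to reference ordering", {
  ref <- make_reference(n_eyes = 25, seed = 5)
  norm1 <- build_normative_db(ref$maps, ref$bios)
  set.seed(11); o <- sample(25)
  norm2 <- build_normative_db(ref$maps[o], ref$bios[o])
  expect_equal(norm1$coef, norm2$coef, tolerance = 1e-9)
  mu1 <- gciplvf:::adjusted_mean_raster(norm1, eye_biometry(24, 45, 3))
  mu2 <- gciplvf:::adjusted_mean_raster(norm2, eye_biometry(24, 45, 3))
  expect_equal(mu1, mu2, tolerance = 1e-9)
})

test_that("percentile flags equal the brute-force quantile comparison", {
  ref <- make_reference(n_eyes = 40, noise = 3, seed = 7)
  norm <- build_normative_db(ref$maps, ref$bios)
  bio <- eye_biometry(24, 50, 9)
  set.seed(8)
  obs <- small_map(matrix(rnorm(400, 57, 5), 20, 20))
  flags <- percentile_flag_map(obs, bio, norm, pct = 0.05)
  mu <- gciplvf:::adjusted_mean_raster(norm, bio)
  for (j in sample(400, 50)) {
    q <- quantile(norm$residuals[, j], 0.05, type = 7, names = FALSE)
    expect_identical(unname(flags[j]), unname((obs$values[j] - mu[j]) < q))
  }
  # observation at the adjusted mean is never flagged at pct < 0.5
  at_mean <- small_map(mu)
  expect_false(any(percentile_flag_map(at_mean, bio, norm, 0.05), na.rm = TRUE))
  # observation below every residual is always flagged
  low <- small_map(mu + min(norm$residuals) - 1)
  expect_true(all(percentile_flag_map(low, bio, norm, 0.05), na.rm = TRUE))
})

test_that("squares with too few references are masked", {
  ref <- make_reference(n_eyes = 25, seed = 9)
  for (i in 1:10) ref$maps[[i]]$values[1, 1] <- NA
  maps <- lapply(ref$maps, function(m) thickness_map(m$values))
  norm <- build_normative_db(maps, ref$bios, min_reference = 20)
  expect_false(norm$model_mask[1, 1])
  flags <- percentile_flag_map(small_map(matrix(0, 20, 20)),
                               eye_biometry(24, 60, 7), norm)
  expect_true(is.na(flags[1, 1]))
  expect_true(all(flags[-1], na.rm = TRUE))
})

test_that("relative map re-zeroes at the eye's 85th percentile", {
  ref <- make_reference(n_eyes = 30, seed = 13)
  norm <- build_normative_db(ref$maps, ref$bios)
  bio <- eye_biometry(24, 55, 7)
  mu <- gciplvf:::adjusted_mean_raster(norm, bio)
  # uniform total deviation collapses to zero everywhere
  u <- small_map(mu + 4)
  rel <- relative_thickness_map(u, bio, norm)
  expect_equal(max(abs(rel$relative)), 0, tolerance = 1e-10)
  # adding a constant leaves the relative map unchanged
  set.seed(14)
  v <- mu + matrix(rnorm(400, 0, 6), 20, 20)
  r1 <- relative_thickness_map(small_map(v), bio, norm)
  r2 <- relative_thickness_map(small_map(v + 7), bio, norm)
  expect_equal(r1$relative, r2$relative, tolerance = 1e-9)
  # sorted-quantile oracle on the full map
  td <- v - mu
  expect_equal(r1$relative,
               td - quantile(td, 0.85, type = 7, names = FALSE),
               tolerance = 1e-12)
  # at most 15% of squares positive (up to interpolation ties)
  expect_lte(mean(r1$relative > 0), 0.15 + 1 / 400)
})

test_that("flagged proportions per hemi-cluster match exhaustive tallies", {
  n <- 20
  labs <- matrix(NA_character_, n, n)
  labs[1:10, ] <- "C3.inferior"
  labs[11:20, 1:10] <- "C3.superior"
  asg <- structure(list(vf_labels = c("C3.inferior", "C3.superior"),
                        grid_labels = labs),
                   class = "cluster_assignment")
  flags <- matrix(FALSE, n, n)
  expect_equal(unname(proportion_flagged(flags, asg)), c(0, 0))
  flags[] <- TRUE
  expect_equal(unname(proportion_flagged(flags, asg)), c(1, 1))
  set.seed(15)
  flags <- matrix(runif(n * n) < 0.3, n, n)
  flags[3, 3] <- NA
  p <- proportion_flagged(flags, asg)
  man_inf <- mean(flags[1:10, ], na.rm = TRUE)
  man_sup <- mean(flags[11:20, 1:10], na.rm = TRUE)
  expect_equal(unname(p["C3.inferior"]), man_inf)
  expect_equal(unname(p["C3.superior"]), man_sup)
})

test_that("deepening a defect never lowers flagged proportions", {
  ref <- make_reference(n_eyes = 30, noise = 2, seed = 21)
  norm <- build_normative_db(ref$maps, ref$bios)
  bio <- eye_biometry(24, 60, 7)
  labs <- matrix("C3.inferior", 20, 20)
  labs[11:20, ] <- "C3.superior"
  asg <- structure(list(vf_labels = c("C3.inferior", "C3.superior"),
                        grid_labels = labs),
                   class = "cluster_assignment")
  set.seed(22)
  base_v <- matrix(rnorm(400, 60, 2), 20, 20)
  prev <- c(0, 0)
  for (depth in c(0, 3, 6, 12)) {
    v <- base_v; v[1:10, ] <- v[1:10, ] - depth
    fl <- percentile_flag_map(small_map(v), bio, norm)
    p <- unname(proportion_flagged(fl, asg))
    expect_gte(p[1] + 1e-12, prev[1])
    prev <- p
  }
})
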