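# toy assignment on an 8x8 raster: two hemi-clusters mirroring each other
toy_assignment <- function() {
  labs <- matrix(NA_character_, 8, 8)
  labs[1:4, 3:6] <- "C3.inferior"   # superior retina -> inferior field
  labs[5:8, 3:6] <- "C3.superior"
  structure(list(vf_labels = c("C3.inferior", "C3.superior"),
                 grid_labels = labs),
            class = "cluster_assignment")
}

test_that("uniform eyes have zero spread and zero asymmetry", {
  m <- thickness_map(matrix(70, 8, 8))
  f <- compute_features(m, relative = matrix(0, 8, 8), flags = NULL,
                        assignment = toy_assignment())
  expect_equal(f$sd_um, c(0, 0))
  expect_equal(f$asymmetry_um, c(0, 0))
  expect_equal(f$mean_um, c(70, 70))
})

test_that("hemifield thinning shows as mirrored asymmetry", {
  v <- matrix(70, 8, 8)
  v[5:8, ] <- 60   # thin inferior retina (field-superior hemi-cluster)
  f <- compute_features(thickness_map(v), assignment = toy_assignment())
  sup <- f[f$hemicluster == "C3.superior", ]
  inf <- f[f$hemicluster == "C3.inferior", ]
  expect_equal(sup$asymmetry_um, -10)
  expect_equal(inf$asymmetry_um, 10)
  expect_equal(sup$asymmetry_um, -inf$asymmetry_um)
})

test_that("features match brute-force aggregation on a labelled toy grid", {
  set.seed(31)
  v <- matrix(rnorm(64, 60, 8), 8, 8)
  rel <- matrix(rnorm(64, -2, 3), 8, 8)
  fl <- matrix(runif(64) < 0.2, 8, 8)
  asg <- toy_assignment()
  f <- compute_features(thickness_map(v), rel, fl, asg)
  for (hc in c("C3.inferior", "C3.superior")) {
    sel <- !is.na(asg$grid_labels) & asg$grid_labels == hc
    row <- f[f$hemicluster == hc, ]
    expect_equal(row$mean_um, mean(v[sel]))
    expect_equal(row$sd_um, sd(v[sel]))
    expect_equal(row$mean_relative_um, mean(rel[sel]))
    expect_equal(row$flagged_proportion, mean(fl[sel]))
  }
  expect_equal(f$asymmetry_um[1], -f$asymmetry_um[2])
  expect_equal(f$asymmetry_relative_um[1], -f$asymmetry_relative_um[2])
})

make_training <- function(n = 120, seed = 41, informative = 2, noise_feats = 1,
                          beta = 2) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * (informative + noise_feats)), n)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  for (j in seq_len(informative)) X[, j] <- X[, j] + beta * y
  list(X = as.data.frame(X), y = y)
}

test_that("two perfectly correlated informative features give one dominant PC", {
  set.seed(43)
  y <- rep(c(0, 1), 60)
  a <- rnorm(120) + 1.5 * y
  d <- data.frame(f1 = a, f2 = 2 * a + 3)
  m <- fit_pca_logistic(d, y, eliminate = FALSE)
  expect_equal(m$n_pc, 1)
  expect_gt(m$eigenvalues[1] / sum(m$eigenvalues), 0.999)
})

test_that("PCA eigenvectors are orthonormal and scores decorrelated", {
  tr <- make_training(noise_feats = 2, seed = 47)
  m <- fit_pca_logistic(tr$X, tr$y, eliminate = FALSE, retention = 4)
  rot <- m$rotation
  expect_equal(unname(crossprod(rot)), diag(ncol(rot)), tolerance = 1e-10,
               ignore_attr = TRUE)
  Z <- scale(as.matrix(tr$X), m$center, m$scale)
  scores <- Z %*% rot
  cc <- cov(scores)
  expect_equal(cc[upper.tri(cc)], rep(0, sum(upper.tri(cc))), tolerance = 1e-10)
})

test_that("backward elimination removes label-independent noise features", {
  dropped <- vapply(1:60, function(i) {
    tr <- make_training(n = 150, seed = 500 + i, informative = 2,
                        noise_feats = 1, beta = 1.5)
    m <- fit_pca_logistic(tr$X, tr$y)
    !"f3" %in% m$retained_parameters
  }, logical(1))
  expect_gte(mean(dropped), 0.9)
})

test_that("the fitted model is invariant to affine feature rescaling", {
  tr <- make_training(seed = 53)
  m1 <- fit_pca_logistic(tr$X, tr$y)
  X2 <- tr$X
  X2$f1 <- 100 * X2$f1 - 7
  m2 <- fit_pca_logistic(X2, tr$y)
  p1 <- predict(m1, tr$X)
  p2 <- predict(m2, X2)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("prediction is deterministic, batch-consistent and monotone", {
  tr <- make_training(seed = 59)
  m <- fit_pca_logistic(tr$X, tr$y)
  p_batch <- predict(m, tr$X)
  p_single <- vapply(seq_len(nrow(tr$X)),
                     function(i) predict(m, tr$X[i, , drop = FALSE]),
                     numeric(1))
  expect_equal(p_batch, p_single)
  # zero PC scores -> plogis(intercept)
  center_row <- as.data.frame(as.list(m$center))
  expect_equal(unname(predict(m, center_row)), plogis(m$coefficients[1]))
  # missing retained feature is an error, not silent imputation
  expect_error(predict(m, tr$X[setdiff(names(tr$X), m$retained_parameters[1])]),
               "missing retained")
})

test_that("serialized models reproduce predictions exactly", {
  tr <- make_training(seed = 61)
  m <- fit_pca_logistic(tr$X, tr$y)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(predict(m2, tr$X), predict(m, tr$X), tolerance = 1e-12)
})

test_that("a constant central prediction reduces the cascade to plain PCA", {
  tr1 <- make_training(seed = 67)
  tr2 <- make_training(seed = 68)
  cas <- fit_cascade(
    list(central = tr1$X, peripheral = tr2$X),
    list(central = tr1$y, peripheral = tr2$y))
  expect_equal(cas$order, c("central", "peripheral"))
  # a separately trained plain model on the peripheral group
  plain <- fit_pca_logistic(tr2$X, tr2$y)
  # pass a constant central prediction: eliminated as a constant column
  tr2c <- tr2$X
  tr2c$central_prediction <- 0.5
  m_const <- fit_pca_logistic(tr2c, tr2$y)
  expect_equal(sort(m_const$retained_parameters),
               sort(plain$retained_parameters))
  expect_equal(predict(m_const, tr2c), predict(plain, tr2$X), tolerance = 1e-9)
})

test_that("cascade predictions flow central to peripheral deterministically", {
  tr1 <- make_training(seed = 71)
  tr2 <- make_training(seed = 72)
  # make the peripheral labels depend on the central ones so the cascade input helps
  tr2$y <- tr1$y
  cas <- fit_cascade(
    list(central = tr1$X, peripheral = tr2$X),
    list(central = tr1$y, peripheral = tr2$y))
  p1 <- predict(cas, list(central = tr1$X, peripheral = tr2$X))
  p2 <- predict(cas, list(central = tr1$X, peripheral = tr2$X))
  expect_identical(p1, p2)
  expect_true(all(p1$peripheral >= 0 & p1$peripheral <= 1))
  # serialization round trip
  path <- tempfile(fileext = ".json")
  write_model_json(cas, path)
  cas2 <- read_model_json(path)
  p3 <- predict(cas2, list(central = tr1$X, peripheral = tr2$X))
  expect_equal(p3$peripheral, p1$peripheral, tolerance = 1e-12)
})

test_that("spatially correlated defects let the cascade help peripherally", {
  set.seed(83)
  aucs <- replicate(30, {
    n <- 160
    latent <- rnorm(n)
    y_c <- as.numeric(latent + rnorm(n, 0, 0.4) > 0)
    y_p <- as.numeric(latent + rnorm(n, 0, 0.4) > 0)
    # central features informative; peripheral features weak
    Xc <- data.frame(f1 = rnorm(n) + 2.5 * y_c, f2 = rnorm(n) + 2.5 * y_c)
    Xp <- data.frame(f1 = rnorm(n) + 0.3 * y_p, f2 = rnorm(n))
    cas <- suppressWarnings(fit_cascade(list(cen = Xc, per = Xp),
                                        list(cen = y_c, per = y_p)))
    pl <- suppressWarnings(fit_pca_logistic(Xp, y_p))
    pred_cas <- predict(cas, list(cen = Xc, per = Xp))$per
    pred_pl <- predict(pl, Xp)
    c(cas = roc_and_auc(pred_cas, y_p)$auc,
      pca = roc_and_auc(pred_pl, y_p)$auc)
  })
  expect_gt(mean(aucs["cas", ] - aucs["pca", ]), 0)
})
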