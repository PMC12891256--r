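# brute-force pairwise concordance AUC
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("AUC handles separation, ties and the worked concordance example", {
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_and_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_and_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_and_auc(1:5, rep(1, 5)), "both classes")
})

test_that("rank-based AUC equals brute-force concordance", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_and_auc(s, y)$auc, auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(93)
  y <- rep(c(0, 1), each = 60)
  s <- rnorm(120) + y
  r <- roc_and_auc(s, y)
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$auc_se^2, pROC::var(pr, method = "delong"), tolerance = 1e-10)
})

test_that("paired DeLong test matches pROC and its invariances", {
  skip_if_not_installed("pROC")
  set.seed(95)
  y <- rep(c(0, 1), each = 50)
  a <- rnorm(100) + 0.8 * y
  b <- 0.5 * a + rnorm(100, 0, 0.5) + 0.4 * y
  cmp <- delong_compare(a, b, y)
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                       pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pr$p.value, tolerance = 1e-9)
  # self-comparison and monotone transforms are null results
  self <- delong_compare(a, a, y)
  expect_equal(self$z, 0); expect_equal(self$p_value, 1)
  mono <- delong_compare(a, qlogis(plogis(a)) * 2 + 3, y)
  expect_equal(mono$auc_a, mono$auc_b, tolerance = 1e-12)
  expect_equal(mono$p_value, 1)
  expect_error(delong_compare(a[-1], b, y), "paired")
})

test_that("Youden threshold equals the exhaustive scan", {
  set.seed(97)
  for (i in 1:10) {
    y <- runif(80) < 0.45
    if (!any(y) || all(y)) next
    s <- rnorm(80) + 1.2 * y
    roc <- roc_and_auc(s, y)
    yt <- youden_threshold(roc)
    cand <- c(sort(unique(s)), Inf)
    j <- vapply(cand, function(t) mean(s[y] >= t) + mean(s[!y] < t) - 1,
                numeric(1))
    expect_equal(yt$youden_j, max(j), tolerance = 1e-12)
    # tie-break toward higher specificity
    best <- cand[j >= max(j) - 1e-12]
    spec_at <- vapply(best, function(t) mean(s[!y] < t), numeric(1))
    expect_equal(yt$specificity, max(spec_at), tolerance = 1e-12)
  }
  # perfect classifier
  yp <- youden_threshold(roc_and_auc(c(2, 3, -2, -3), c(1, 1, 0, 0)))
  expect_equal(yp$sensitivity, 1); expect_equal(yp$specificity, 1)
})

test_that("sensitivity and specificity follow their definitions with CIs", {
  pred <- c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE)
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  ids <- paste0("p", 1:20)
  res <- sens_spec_ci(pred, truth, ids, method = "wilson")
  expect_equal(res$estimate[res$measure == "sensitivity"], 0.9)
  expect_equal(res$estimate[res$measure == "specificity"], 0.8)
  expect_true(all(res$lower <= res$estimate & res$estimate <= res$upper))
  # all-correct predictions: estimates 1, CIs bounded at 1
  perfect <- sens_spec_ci(truth, truth, ids, method = "wilson")
  expect_equal(perfect$estimate, c(1, 1))
  expect_true(all(perfect$upper <= 1))
})

test_that("cluster bootstrap approaches Wilson for independent units", {
  set.seed(99)
  truth <- runif(200) < 0.5
  pred <- ifelse(runif(200) < 0.8, truth, !truth)
  ids <- paste0("p", 1:200)
  w <- sens_spec_ci(pred, truth, ids, method = "wilson")
  b <- sens_spec_ci(pred, truth, ids, method = "cluster-bootstrap", n_boot = 500)
  expect_equal(b$estimate, w$estimate)
  expect_lt(max(abs(b$lower - w$lower)), 0.06)
  expect_lt(max(abs(b$upper - w$upper)), 0.06)
})

test_that("bootstrap sensitivity CIs achieve near-nominal coverage", {
  set.seed(103)
  true_sens <- 0.8
  cover <- replicate(120, {
    truth <- rep(TRUE, 100)
    pred <- runif(100) < true_sens
    ids <- paste0("p", 1:100)
    ci <- sens_spec_ci(pred, truth, ids, n_boot = 300)
    ci$lower[1] <= true_sens && true_sens <= ci$upper[1]
  })
  expect_gte(mean(cover), 0.86)
})

make_scores <- function(n = 120, seed = 7, lift = c(pct = 1.5, pca = 1.5, cas = 1.5)) {
  set.seed(seed)
  ids <- sprintf("p%03d", 1:n)
  out <- do.call(rbind, lapply(c("A.superior", "A.inferior"), function(hc) {
    label <- runif(n) < 0.4
    data.frame(id = ids, hemicluster = hc, label = label,
               percentile = rnorm(n) + lift[["pct"]] * label,
               pca = rnorm(n) + lift[["pca"]] * label,
               cascade = rnorm(n) + lift[["cas"]] * label,
               diagnosis = sample(c("healthy", "glaucoma"), n, TRUE))
  }))
  out
}

test_that("the percentile method is kept when alternatives do not improve", {
  sc <- make_scores(seed = 7)
  split <- list(rocc_ids = sprintf("p%03d", 1:80),
                test_ids = sprintf("p%03d", 81:120))
  rep <- select_method_and_report(sc, split, ci_method = "wilson")
  expect_true(all(rep$selection$chosen == "percentile"))
  expect_equal(rep$thresholds_from, "rocc")
})

test_that("a dominant alternative method is selected where it wins", {
  sc <- make_scores(seed = 9, lift = c(pct = 0.2, pca = 0.2, cas = 3))
  split <- list(rocc_ids = sprintf("p%03d", 1:80),
                test_ids = sprintf("p%03d", 81:120))
  rep <- select_method_and_report(sc, split, ci_method = "wilson")
  expect_true(all(rep$selection$chosen == "cascade"))
})

test_that("thresholds derive from the ROCC cohort only (no leakage)", {
  sc <- make_scores(seed = 11)
  split <- list(rocc_ids = sprintf("p%03d", 1:80),
                test_ids = sprintf("p%03d", 81:120))
  rep1 <- select_method_and_report(sc, split, ci_method = "wilson")
  # perturbing only test-cohort scores leaves selection and thresholds fixed
  sc2 <- sc
  shift <- sc2$id %in% split$test_ids
  sc2$percentile[shift] <- sc2$percentile[shift] + rnorm(sum(shift), 0, 3)
  sc2$pca[shift] <- sc2$pca[shift] + rnorm(sum(shift), 0, 3)
  sc2$cascade[shift] <- sc2$cascade[shift] + rnorm(sum(shift), 0, 3)
  rep2 <- select_method_and_report(sc2, split, ci_method = "wilson")
  expect_equal(rep2$selection$chosen, rep1$selection$chosen)
  expect_equal(rep2$selection$threshold, rep1$selection$threshold)
  expect_equal(rep2$selection$auc_percentile, rep1$selection$auc_percentile)
  # overlapping cohorts are rejected
  bad <- list(rocc_ids = sprintf("p%03d", 1:80),
              test_ids = sprintf("p%03d", 80:120))
  expect_error(select_method_and_report(sc, bad, ci_method = "wilson"),
               "disjoint")
})

test_that("reports are reproducible with a fixed seed", {
  sc <- make_scores(seed = 13)
  split <- list(rocc_ids = sprintf("p%03d", 1:80),
                test_ids = sprintf("p%03d", 81:120))
  set.seed(1); r1 <- select_method_and_report(sc, split, n_boot = 100)
  set.seed(1); r2 <- select_method_and_report(sc, split, n_boot = 100)
  expect_identical(r1, r2)
})
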