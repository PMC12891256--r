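# DeLong structural components for an AUC. labels: logical/0-1, scores numeric.
delong_components <- function(scores, labels) {
  y <- as.logical(labels)
  if (anyNA(scores) || anyNA(y)) stop("missing scores or labels")
  pos <- scores[y]; neg <- scores[!y]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n              # per-positive placement
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m      # per-negative placement
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC curve with DeLong AUC and standard error
#'
#' AUC is the Mann-Whitney concordance (ties counted 1/2); its standard error
#' comes from the DeLong structural components. Convention: higher score
#' means more likely defective; a case is called positive when
#' score >= threshold.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or 0/1 truth (TRUE = defective).
#' @return A `roc_curve`: `thresholds`, `sensitivity`, `fpr`, `auc`, `auc_se`.
#' @export
roc_and_auc <- function(scores, labels) {
  y <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  dc <- delong_components(scores, y)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  se <- sqrt(stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n)
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr,
                 auc = dc$auc, auc_se = se, m = dc$m, n = dc$n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (SE %.3f), %d positives / %d negatives\n",
              x$auc, x$auc_se, x$m, x$n))
  invisible(x)
}

#' Paired DeLong test between two AUCs
#'
#' Two-sided test for equality of the AUCs of two score sets computed on the
#' same cases, using the DeLong covariance of the paired structural
#' components.
#'
#' @param scores_a,scores_b Paired score vectors (same cases, same order).
#' @param labels Truth labels shared by both.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop("scores must be paired on identical cases")
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  a <- delong_components(scores_a[ok], labels[ok])
  b <- delong_components(scores_b[ok], labels[ok])
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / a$m + s01 / a$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
    if (abs(d) > sqrt(.Machine$double.eps)) { z <- sign(d) * Inf; p <- 0 }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, z = z, p_value = p, var_diff = var_diff)
}

#' Youden-optimal threshold from a ROC curve
#'
#' Maximises sensitivity + specificity over the curve's thresholds; ties are
#' broken toward higher specificity (the screening context favours fewer
#' false referrals).
#'
#' @param roc A `roc_curve`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + (1 - roc$fpr) - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(roc$fpr[best])]   # highest specificity among ties
  list(threshold = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = 1 - roc$fpr[pick],
       youden_j = j[pick])
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Sensitivity and specificity with clustered confidence intervals
#'
#' Point estimates are TP/(TP+FN) and TN/(TN+FP). Because hemi-clusters from
#' the same participant are correlated, the default 95% CI resamples
#' participants (nonparametric cluster bootstrap, percentile intervals);
#' `method = "wilson"` gives the independent-data fallback.
#'
#' @param predicted Logical/0-1 predicted defective status.
#' @param labels Logical/0-1 true status.
#' @param participant_ids Participant (cluster) id per observation.
#' @param method `"cluster-bootstrap"` (default) or `"wilson"`.
#' @param n_boot Bootstrap replicates, default 2000.
#' @param conf Confidence level, default 0.95.
#' @return Data frame with rows `sensitivity` and `specificity`: estimate,
#'   lower, upper, n, method.
#' @export
sens_spec_ci <- function(predicted, labels, participant_ids,
                         method = c("cluster-bootstrap", "wilson"),
                         n_boot = 2000, conf = 0.95) {
  method <- match.arg(method)
  pr <- as.logical(predicted); y <- as.logical(labels)
  ok <- !is.na(pr) & !is.na(y)
  pr <- pr[ok]; y <- y[ok]; pid <- as.character(participant_ids)[ok]
  est <- function(p, t) {
    npos <- sum(t); nneg <- sum(!t)
    c(sens = if (npos) sum(p & t) / npos else NA_real_,
      spec = if (nneg) sum(!p & !t) / nneg else NA_real_)
  }
  e <- est(pr, y)
  if (method == "wilson") {
    ci_s <- wilson_ci(sum(pr & y), sum(y), conf)
    ci_p <- wilson_ci(sum(!pr & !y), sum(!y), conf)
    lo <- c(ci_s[1], ci_p[1]); hi <- c(ci_s[2], ci_p[2])
  } else {
    ids <- unique(pid)
    by_id <- split(seq_along(pid), pid)
    reps <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      take <- unlist(by_id[sample(ids, length(ids), replace = TRUE)],
                     use.names = FALSE)
      reps[b, ] <- est(pr[take], y[take])
    }
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    lo <- apply(reps, 2, stats::quantile, qs[1], na.rm = TRUE)
    hi <- apply(reps, 2, stats::quantile, qs[2], na.rm = TRUE)
  }
  data.frame(measure = c("sensitivity", "specificity"),
             estimate = unname(e), lower = unname(lo), upper = unname(hi),
             n = c(sum(y), sum(!y)), method = method,
             stringsAsFactors = FALSE)
}

#' Choose the classification method per hemi-cluster and build the report
#'
#' On the ROCC cohort, compares the PCA and cascaded ("PCA plus central")
#' scores against the percentile-method score with paired DeLong tests. The
#' percentile method is kept unless an alternative's AUROCC is significantly
#' higher (p < alpha); when both alternatives qualify, the higher AUROCC
#' wins. The chosen score's Youden threshold is derived on the ROCC cohort
#' and applied unchanged to the test cohort and to each diagnostic stratum.
#'
#' @param scores Data frame with columns `id` (participant), `hemicluster`,
#'   `label` (logical VF-defective), `percentile`, `pca`, `cascade`
#'   (`cascade` may contain `NA` for the central group), and `diagnosis`.
#' @param split List with `rocc_ids` and `test_ids` (disjoint participant
#'   ids covering the cohort).
#' @param alpha Significance level for the DeLong comparisons, default 0.05.
#' @param ci_method Passed to [sens_spec_ci()].
#' @param n_boot Bootstrap replicates for the CIs.
#' @return An `eval_report`: `selection` (per hemi-cluster AUCs, DeLong p,
#'   chosen method, threshold) and `performance` (sens/spec + CI per
#'   hemi-cluster for ROCC cohort, test cohort and per-diagnosis strata).
#' @export
select_method_and_report <- function(scores, split, alpha = 0.05,
                                     ci_method = "cluster-bootstrap",
                                     n_boot = 2000) {
  stopifnot(all(c("id", "hemicluster", "label", "percentile", "pca") %in% names(scores)))
  if (length(intersect(split$rocc_ids, split$test_ids)))
    stop("ROCC and test cohorts must be disjoint")
  if (!setequal(c(split$rocc_ids, split$test_ids), unique(scores$id)))
    stop("split does not cover the cohort")
  if (!"cascade" %in% names(scores)) scores$cascade <- NA_real_

  sel_rows <- list(); perf_rows <- list()
  for (hc in sort(unique(scores$hemicluster))) {
    d <- scores[scores$hemicluster == hc, , drop = FALSE]
    rocc <- d[d$id %in% split$rocc_ids, , drop = FALSE]
    test <- d[d$id %in% split$test_ids, , drop = FALSE]

    auc_pct <- roc_and_auc(rocc$percentile, rocc$label)
    cmp_pca <- delong_compare(rocc$pca, rocc$percentile, rocc$label)
    has_cascade <- !all(is.na(rocc$cascade))
    cmp_cas <- if (has_cascade)
      delong_compare(rocc$cascade, rocc$percentile, rocc$label) else NULL

    better_pca <- cmp_pca$p_value < alpha && cmp_pca$auc_a > cmp_pca$auc_b
    better_cas <- has_cascade && cmp_cas$p_value < alpha && cmp_cas$auc_a > cmp_cas$auc_b
    chosen <- "percentile"
    if (better_pca && better_cas)
      chosen <- if (cmp_cas$auc_a >= cmp_pca$auc_a) "cascade" else "pca"
    else if (better_cas) chosen <- "cascade"
    else if (better_pca) chosen <- "pca"

    roc_chosen <- roc_and_auc(rocc[[chosen]], rocc$label)
    yt <- youden_threshold(roc_chosen)

    sel_rows[[hc]] <- data.frame(
      hemicluster = hc,
      auc_percentile = auc_pct$auc, se_percentile = auc_pct$auc_se,
      auc_pca = cmp_pca$auc_a, p_pca_vs_percentile = cmp_pca$p_value,
      auc_cascade = if (has_cascade) cmp_cas$auc_a else NA_real_,
      p_cascade_vs_percentile = if (has_cascade) cmp_cas$p_value else NA_real_,
      chosen = chosen, threshold = yt$threshold,
      stringsAsFactors = FALSE
    )

    eval_one <- function(dd, cohort) {
      ok <- !is.na(dd[[chosen]])
      dd <- dd[ok, , drop = FALSE]
      if (!nrow(dd) || length(unique(dd$label)) < 2) return(NULL)
      ss <- sens_spec_ci(dd[[chosen]] >= yt$threshold, dd$label, dd$id,
                         method = ci_method, n_boot = n_boot)
      ss$hemicluster <- hc; ss$cohort <- cohort; ss$chosen <- chosen
      ss
    }
    perf_rows[[length(perf_rows) + 1]] <- eval_one(rocc, "rocc")
    perf_rows[[length(perf_rows) + 1]] <- eval_one(test, "test")
    if ("diagnosis" %in% names(d)) {
      for (dg in sort(unique(d$diagnosis)))
        perf_rows[[length(perf_rows) + 1]] <-
          eval_one(d[d$diagnosis == dg, , drop = FALSE], paste0("diagnosis:", dg))
    }
  }
  structure(list(selection = do.call(rbind, sel_rows),
                 performance = do.call(rbind, perf_rows),
                 alpha = alpha,
                 thresholds_from = "rocc"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Method selection per hemi-cluster (thresholds derived on ROCC cohort):\n")
  print(x$selection, row.names = FALSE, digits = 3)
  invisible(x)
}
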