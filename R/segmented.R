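#' Fit a segmented (broken-stick) structure-function regression
#'
#' Least-squares fit of y = b0 + b1*x + b2*(x - psi)+ with the breakpoint psi
#' re-estimated by Muggeo-style iterative linearisation from an initial guess
#' (default 15.5 dB) with jittered restarts, falling back to an exhaustive
#' grid search when the iteration fails to converge. The model is continuous
#' at the breakpoint by construction; the reported right-segment slope
#' ("slope2") is b1 + b2.
#'
#' @param x Ganglion-cell count in dB (10*log10 cells) per observation.
#' @param y Visual-field threshold (dB).
#' @param init_breakpoint Initial breakpoint estimate, default 15.5 dB.
#' @param n_restarts Jittered restarts around the initial estimate, default 5.
#' @param tol Convergence tolerance on the breakpoint, default 1e-8.
#' @param max_iter Maximum iterations per start, default 100.
#' @param grid_step Step of the fallback/oracle grid search, default 0.01 dB.
#' @return A `segmented_model`: intercept, slope1, breakpoint, slope2,
#'   adj_r2, f_stat and p_value (segmented vs simple linear), mae_dB, rmse_dB,
#'   rss, n, convergence method.
#' @export
fit_segmented <- function(x, y, init_breakpoint = 15.5, n_restarts = 5,
                          tol = 1e-8, max_iter = 100, grid_step = 0.01) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  rng <- range(x)
  if (diff(rng) < sqrt(.Machine$double.eps)) stop("degenerate x range")
  lo <- rng[1] + 1e-6 * diff(rng); hi <- rng[2] - 1e-6 * diff(rng)
  clamp <- function(p) min(max(p, lo), hi)

  fit_at <- function(psi) {
    u <- pmax(x - psi, 0)
    stats::lm.fit(cbind(1, x, u), y)
  }
  rss_of <- function(f) sum(f$residuals^2)

  one_start <- function(psi0) {
    psi <- clamp(psi0)
    damp <- 1
    for (it in seq_len(max_iter)) {
      u <- pmax(x - psi, 0)
      v <- -(x > psi)
      f <- stats::lm.fit(cbind(1, x, u, v), y)
      b <- f$coefficients
      if (anyNA(b)) return(NULL)
      step <- damp * b[[4]] / b[[3]]
      if (!is.finite(step)) return(NULL)
      psi_new <- clamp(psi + step)
      if (abs(psi_new - psi) < tol) {
        return(list(psi = psi_new, fit = fit_at(psi_new), converged = TRUE))
      }
      # the working-linear update can oscillate between adjacent data gaps;
      # damp progressively so the iterate settles inside one gap
      if (it %% 20 == 0) damp <- damp / 2
      psi <- psi_new
    }
    list(psi = psi, fit = fit_at(psi), converged = FALSE)
  }

  jitter_frac <- diff(rng) * c(0, -0.15, 0.15, -0.3, 0.3, -0.45, 0.45)
  starts <- vapply(init_breakpoint + jitter_frac[seq_len(max(n_restarts, 1) + 1)],
                   clamp, numeric(1))
  cands <- list()
  for (s in starts) {
    r <- one_start(s)
    if (!is.null(r)) cands[[length(cands) + 1]] <- r
  }
  method <- "muggeo"
  if (length(cands)) {
    rs <- vapply(cands, function(r) rss_of(r$fit), numeric(1))
    best <- cands[[which.min(rs)]]
    if (!best$converged) method <- "muggeo-damped"
    # The RSS profile in psi is piecewise-smooth with kinks at the data
    # points, and near-tied local basins are common. The profile is smooth
    # between consecutive unique x values, so a within-interval search over
    # every gap locates the global profile minimum; for very large n the
    # gaps are dense and a uniform scan with local polish suffices.
    prof <- function(p) rss_of(fit_at(p))
    uu <- unique(c(lo, sort(unique(x[x > lo & x < hi])), hi))
    if (length(uu) <= 601) {
      for (i in seq_len(length(uu) - 1)) {
        opt <- stats::optimize(prof, c(uu[i], uu[i + 1]), tol = 1e-9)
        if (opt$objective < rss_of(best$fit) - 1e-12)
          best <- list(psi = opt$minimum, fit = fit_at(opt$minimum),
                       converged = best$converged)
      }
    } else {
      coarse <- seq(lo, hi, length.out = 512)
      coarse_rss <- vapply(coarse, prof, numeric(1))
      n_c <- length(coarse)
      is_locmin <- coarse_rss <= c(Inf, coarse_rss[-n_c]) &
        coarse_rss <= c(coarse_rss[-1], Inf)
      loc_idx <- which(is_locmin)[order(coarse_rss[is_locmin])]
      for (i in utils::head(loc_idx, 5)) {
        opt <- stats::optimize(prof,
                               c(if (i > 1) coarse[i - 1] else lo,
                                 if (i < n_c) coarse[i + 1] else hi),
                               tol = 1e-9)
        if (opt$objective < rss_of(best$fit) - 1e-12)
          best <- list(psi = opt$minimum, fit = fit_at(opt$minimum),
                       converged = best$converged)
      }
    }
  } else {
    best <- NULL
  }
  # grid fallback when the iteration never produced a candidate
  if (is.null(best)) {
    warning("breakpoint iteration did not converge; using grid search")
    method <- "grid"
    psis <- seq(lo, hi, by = grid_step)
    rs <- vapply(psis, function(p) rss_of(fit_at(p)), numeric(1))
    psi <- psis[which.min(rs)]
    best <- list(psi = psi, fit = fit_at(psi))
  }

  psi <- best$psi
  f <- best$fit
  b <- f$coefficients
  res <- f$residuals
  rss <- sum(res^2)
  p_seg <- 4L
  lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(lin$residuals^2)
  df2 <- n - p_seg
  fstat <- ((rss_lin - rss) / 2) / (rss / df2)
  pval <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / df2) / (tss / (n - 1))
  structure(list(
    intercept = unname(b[[1]]), slope1 = unname(b[[2]]),
    breakpoint = unname(psi), slope2 = unname(b[[2]] + b[[3]]),
    adj_r2 = adj_r2, f_stat = fstat, p_value = pval,
    mae_dB = mean(abs(res)), rmse_dB = sqrt(mean(res^2)),
    rss = rss, n = n, method = method
  ), class = "segmented_model")
}

#' Predict from a segmented model
#' @param object A `segmented_model`.
#' @param newdata Numeric vector of x values (GC count, dB).
#' @param ... Unused.
#' @return Predicted thresholds (dB).
#' @export
predict.segmented_model <- function(object, newdata, ...) {
  object$intercept + object$slope1 * newdata +
    (object$slope2 - object$slope1) * pmax(newdata - object$breakpoint, 0)
}

#' @export
print.segmented_model <- function(x, ...) {
  cat(sprintf(
    "Segmented fit (n=%d, %s): intercept %.2f, slope1 %.2f, breakpoint %.2f dB, slope2 %.2f\n  adj R2 %.2f, F %.2f (p %.3g), MAE %.2f dB, RMSE %.2f dB\n",
    x$n, x$method, x$intercept, x$slope1, x$breakpoint, x$slope2,
    x$adj_r2, x$f_stat, x$p_value, x$mae_dB, x$rmse_dB))
  invisible(x)
}

#' Davies test for a breakpoint
#'
#' Tests for the existence of a slope change against the simple linear model
#' using the maximum of Wald statistics for the added hinge term over K
#' evenly spaced candidate breakpoints, with Davies' upcrossing bound for the
#' p-value of the maximum. Two-sided.
#'
#' @param x,y Data as in [fit_segmented()].
#' @param k Number of candidate breakpoints, default 10, evenly spaced between
#'   the 10th and 90th percentiles of x.
#' @return List with `statistic` (max |t|), `p_value`, `candidates`.
#' @export
davies_test <- function(x, y, k = 10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20) stop("need at least 20 observations")
  if (k < 2) stop("need at least 2 candidate breakpoints")
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  cand <- seq(qs[1], qs[2], length.out = k)
  tstat <- vapply(cand, function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    sigma2 <- rss / (n - 3)
    xtxi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtxi[3, 3])
    f$coefficients[[3]] / se
  }, numeric(1))
  m <- max(abs(tstat))
  v <- sum(abs(diff(tstat)))
  # two-sided p: twice the one-sided Davies upcrossing bound for the maximum
  p <- 2 * (stats::pnorm(-m) + v * exp(-m^2 / 2) / sqrt(8 * pi))
  list(statistic = m, p_value = min(1, p), candidates = cand, t_stats = tstat)
}

#' Extra-sum-of-squares F test between stratified and pooled fits
#'
#' Compares per-stratum segmented fits against a single fit pooled over the
#' same observations.
#'
#' @param sub_models List of `segmented_model` fits whose data partition the
#'   pooled data.
#' @param pooled A `segmented_model` fitted to all the data.
#' @return List with `f`, `p_value`, `df1`, `df2`.
#' @export
compare_nested_f <- function(sub_models, pooled) {
  stopifnot(length(sub_models) >= 2, inherits(pooled, "segmented_model"))
  rss_sub <- sum(vapply(sub_models, `[[`, numeric(1), "rss"))
  n <- sum(vapply(sub_models, `[[`, numeric(1), "n"))
  if (n != pooled$n) stop("strata do not partition the pooled data")
  p_each <- 4L
  p_full <- p_each * length(sub_models)
  if (rss_sub > pooled$rss * (1 + 1e-8) + 1e-10)
    stop("sub-model residual SS exceeds pooled SS; numerical inconsistency")
  df1 <- p_full - p_each
  df2 <- n - p_full
  if (pooled$rss < 1e-10) {
    # both models interpolate the data (noiseless nested case)
    return(list(f = 0, p_value = 1, df1 = df1, df2 = df2))
  }
  f <- ((pooled$rss - rss_sub) / df1) / (rss_sub / df2)
  list(f = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Residual prediction errors of a fitted model
#' @param model A `segmented_model`.
#' @param x,y Evaluation data.
#' @return List with `mae_dB` and `rmse_dB`.
#' @export
prediction_errors <- function(model, x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("no finite observations")
  r <- y[ok] - predict(model, x[ok])
  list(mae_dB = mean(abs(r)), rmse_dB = sqrt(mean(r^2)))
}

#' Maximum predicted divergence between models over a range
#'
#' Largest spread (max minus min predicted threshold across models) over a
#' fine grid of GC counts.
#'
#' @param models List of `segmented_model` fits (>= 2).
#' @param x_range Length-2 numeric range of GC counts (dB).
#' @param step Grid step, default 0.001 dB.
#' @return Maximum divergence (dB).
#' @export
max_model_divergence <- function(models, x_range, step = 0.001) {
  stopifnot(length(models) >= 2, length(x_range) == 2,
            all(is.finite(x_range)), x_range[2] >= x_range[1])
  xs <- seq(x_range[1], x_range[2], by = step)
  preds <- vapply(models, function(m) predict(m, xs), numeric(length(xs)))
  max(apply(preds, 1, max) - apply(preds, 1, min))
}

#' Breakpoint by exhaustive grid search (oracle)
#'
#' Profiles the residual sum of squares of the hinge model over a fixed grid
#' of breakpoints. Used as an independent check on [fit_segmented()].
#'
#' @param x,y Data.
#' @param step Grid step (dB), default 0.01.
#' @return List with `breakpoint` and `rss`.
#' @export
grid_search_breakpoint <- function(x, y, step = 0.01) {
  rng <- range(x)
  psis <- seq(rng[1] + 1e-6, rng[2] - 1e-6, by = step)
  rs <- vapply(psis, function(p) {
    sum(stats::lm.fit(cbind(1, x, pmax(x - p, 0)), y)$residuals^2)
  }, numeric(1))
  i <- which.min(rs)
  list(breakpoint = psis[i], rss = rs[i])
}
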