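#' Hemi-cluster GCIPL features for one eye
#'
#' Computes, per hemi-cluster, the five GCIPL parameters used for
#' classification: mean and standard deviation of thickness across the
#' hemi-cluster, asymmetry (this hemi-cluster's mean minus the mean of the
#' mirror hemi-cluster in the opposite hemifield), mean relative thickness,
#' and asymmetry in relative thickness; plus the percentile-method flagged
#' proportion when a flag map is supplied.
#'
#' @param map A [thickness_map()].
#' @param relative Relative-thickness matrix from [relative_thickness_map()]
#'   (`NULL` to skip relative features).
#' @param flags Flag matrix from [percentile_flag_map()] (`NULL` to skip).
#' @param assignment A `cluster_assignment`.
#' @param mode `"hemicluster"` (default) aggregates over all labelled raster
#'   squares; `"stimulus"` restricts aggregation to squares inside the
#'   projected stimulus regions of the hemi-cluster's VF locations;
#'   `"pointwise"` uses only the single square containing each projected
#'   location centre.
#' @param biometry Needed for the stimulus/pointwise modes to project
#'   locations; defaults to AL 24 mm.
#' @return Data frame, one row per hemi-cluster: `hemicluster`, `group`,
#'   `hemifield`, `mean_um`, `sd_um`, `asymmetry_um`, `mean_relative_um`,
#'   `asymmetry_relative_um`, `flagged_proportion`.
#' @export
compute_features <- function(map, relative = NULL, flags = NULL, assignment,
                             mode = c("hemicluster", "stimulus", "pointwise"),
                             biometry = eye_biometry(24, 60)) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "thickness_map"), inherits(assignment, "cluster_assignment"))
  labs <- assignment$grid_labels
  if (mode != "hemicluster") {
    # keep only squares within stimulus footprints (or their centre square)
    keep <- matrix(FALSE, map$n, map$n)
    ax <- raster_axes(map)
    grid <- vf_grid_analyzable()
    for (i in seq_len(nrow(grid))) {
      reg <- apply_henle_displacement(
        project_stimulus(grid$x_deg[i], grid$y_deg[i], biometry))
      cx <- reg$center_mm[["x"]]; cy <- reg$center_mm[["y"]]
      if (mode == "pointwise") {
        j <- which.min(abs(ax$x - cx)); ii <- which.min(abs(ax$y - cy))
        keep[ii, j] <- TRUE
      } else {
        jx <- which(abs(ax$x - cx) <= reg$radii_mm[["rx"]])
        iy <- which(abs(ax$y - cy) <= reg$radii_mm[["ry"]])
        if (length(jx) && length(iy)) {
          ell <- outer(((ax$y[iy] - cy) / reg$radii_mm[["ry"]])^2,
                       ((ax$x[jx] - cx) / reg$radii_mm[["rx"]])^2, "+") <= 1
          keep[iy, jx][ell] <- TRUE
        }
      }
    }
    labs[!keep] <- NA
  }
  ids <- sort(unique(assignment$vf_labels))
  vals <- map$values
  vals[!map$valid_mask] <- NA
  agg <- function(m, id, fn) {
    v <- m[!is.na(labs) & labs == id]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fn(v)
  }
  mean_um <- vapply(ids, agg, numeric(1), m = vals, fn = mean)
  sd_um <- vapply(ids, agg, numeric(1), m = vals,
                  fn = function(v) if (length(v) > 1) stats::sd(v) else 0)
  mir <- mirror_hemicluster(ids)
  asym <- mean_um - mean_um[match(mir, ids)]
  out <- data.frame(
    hemicluster = ids,
    group = sub("\\..*$", "", ids),
    hemifield = sub("^.*\\.", "", ids),
    mean_um = unname(mean_um), sd_um = unname(sd_um),
    asymmetry_um = unname(asym),
    stringsAsFactors = FALSE
  )
  if (!is.null(relative)) {
    mr <- vapply(ids, agg, numeric(1), m = relative, fn = mean)
    out$mean_relative_um <- unname(mr)
    out$asymmetry_relative_um <- unname(mr - mr[match(mir, ids)])
  }
  if (!is.null(flags)) {
    fl <- vapply(ids, agg, numeric(1), m = flags + 0, fn = mean)
    out$flagged_proportion <- unname(fl)
  }
  out
}

# Logistic regression with a small ridge penalty, used as a fallback under
# complete separation. Returns glm-like coefficients.
penalized_logistic <- function(X, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta) + lambda * sum(b[-1]^2) / 2
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    g <- drop(crossprod(X, p - y))
    g[-1] <- g[-1] + lambda * b[-1]
    g
  }
  o <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                    control = list(maxit = 500))
  o$par
}

#' Fit a PCA-plus-logistic hemi-cluster classifier
#'
#' Standardises the candidate parameters, performs backward elimination on
#' the standardised parameters via Wald p-values in a multiple logistic
#' regression (dropping the least significant while any p >= alpha), then
#' runs PCA on the survivors, retains principal components by the Kaiser rule
#' (eigenvalue > 1, always at least one), and fits a logistic regression of
#' the class labels on the retained PC scores.
#'
#' @param features Data frame / matrix of candidate parameters (rows =
#'   training units).
#' @param labels Logical or 0/1 vector of VF-defective status.
#' @param alpha Elimination significance level, default 0.05.
#' @param retention `"kaiser"` (default) or an integer number of PCs.
#' @param eliminate Set `FALSE` to skip backward elimination.
#' @return A `pca_logistic_model`: retained parameter names, standardisation,
#'   eigenvectors/eigenvalues, logistic coefficients, training metadata.
#' @export
fit_pca_logistic <- function(features, labels, alpha = 0.05,
                             retention = "kaiser", eliminate = TRUE) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y))
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(X) < 20) stop("need at least 20 complete rows")
  if (length(unique(y)) < 2) stop("need both classes present")

  drop_constant <- apply(X, 2, stats::sd) <= 0
  X <- X[, !drop_constant, drop = FALSE]
  if (!ncol(X)) stop("all candidate parameters are constant")

  params <- colnames(X)
  if (eliminate) {
    repeat {
      Z <- scale(X[, params, drop = FALSE])
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Z), y,
                                             family = stats::binomial()))
      # Wald p-values from the final IRLS weights
      W <- fit$weights
      XtWX <- crossprod(cbind(1, Z) * sqrt(W))
      se <- sqrt(diag(solve(XtWX)))
      z <- fit$coefficients / se
      p <- 2 * stats::pnorm(-abs(z))[-1]
      if (all(is.finite(p)) && any(p >= alpha) && length(params) > 1) {
        params <- params[-which.max(p)]
      } else break
    }
    if (!length(params)) stop("all parameters eliminated")
  }

  Xr <- X[, params, drop = FALSE]
  ctr <- colMeans(Xr); scl <- apply(Xr, 2, stats::sd)
  Z <- scale(Xr, ctr, scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  n_pc <- if (identical(retention, "kaiser")) max(1L, sum(ev > 1)) else
    max(1L, min(as.integer(retention), length(ev)))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]

  Xd <- cbind(1, scores)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (separated) {
    warning("possible complete separation; using penalised logistic fit")
    beta <- penalized_logistic(Xd, y)
  } else {
    beta <- fit$coefficients
  }
  structure(list(
    retained_parameters = params,
    center = ctr, scale = scl,
    rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
    eigenvalues = ev,
    n_pc = n_pc,
    coefficients = unname(beta),
    penalized = separated,
    n_train = nrow(X)
  ), class = "pca_logistic_model")
}

#' Predict defect probability from a PCA-logistic model
#' @param object A `pca_logistic_model`.
#' @param newdata Data frame / matrix containing the retained parameters.
#' @param ... Unused.
#' @return Probability per row; `NA` where a retained parameter is missing.
#' @export
predict.pca_logistic_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$retained_parameters, names(nd))
  if (length(miss)) stop("missing retained parameters: ", paste(miss, collapse = ", "))
  X <- as.matrix(nd[object$retained_parameters])
  storage.mode(X) <- "double"
  Z <- scale(X, object$center, object$scale)
  scores <- Z %*% object$rotation
  eta <- object$coefficients[1] + drop(scores %*% object$coefficients[-1])
  out <- stats::plogis(eta)
  out[!stats::complete.cases(X)] <- NA
  out
}

#' Fit the cascaded "PCA plus central" classifier
#'
#' Trains one PCA-logistic model per cluster group in central-to-peripheral
#' order; every model after the first receives the predicted defect
#' probability of the immediately more central group as an additional
#' candidate parameter (subject to the same backward elimination).
#'
#' @param features_by_group Named list (central to peripheral order) of
#'   training feature data frames; rows must be aligned across groups (same
#'   eyes/hemifields in the same order).
#' @param labels_by_group Named list of label vectors aligned to the feature
#'   rows of each group.
#' @param ... Passed to [fit_pca_logistic()].
#' @return A `cascade_model`: list of models in training order plus metadata.
#' @export
fit_cascade <- function(features_by_group, labels_by_group, ...) {
  groups <- names(features_by_group)
  stopifnot(!is.null(groups), identical(groups, names(labels_by_group)),
            !anyDuplicated(groups))
  models <- vector("list", length(groups))
  names(models) <- groups
  central_pred <- NULL
  for (g in groups) {
    feats <- as.data.frame(features_by_group[[g]])
    if (!is.null(central_pred)) {
      stopifnot(nrow(feats) == length(central_pred))
      feats$central_prediction <- central_pred
    }
    models[[g]] <- fit_pca_logistic(feats, labels_by_group[[g]], ...)
    central_pred <- predict(models[[g]], feats)
  }
  structure(list(models = models, order = groups), class = "cascade_model")
}

#' Predict from a cascade model
#' @param object A `cascade_model`.
#' @param features_by_group Named list of feature data frames matching the
#'   training order, rows aligned across groups.
#' @param ... Unused.
#' @return Named list of probability vectors per cluster group.
#' @export
predict.cascade_model <- function(object, features_by_group, ...) {
  out <- vector("list", length(object$order))
  names(out) <- object$order
  central_pred <- NULL
  for (g in object$order) {
    feats <- as.data.frame(features_by_group[[g]])
    if (!is.null(central_pred)) feats$central_prediction <- central_pred
    out[[g]] <- predict(object$models[[g]], feats)
    central_pred <- out[[g]]
  }
  out
}
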