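#' Project all 24-2 locations and estimate GC counts for one eye
#'
#' Runs the per-location structural pipeline: project each analyzable 24-2
#' location onto the thickness raster, apply Henle-fibre displacement to the
#' central 16 locations, average GCIPL over the stimulus region, convert to
#' GCL thickness and multiply by co-localised density to estimate the
#' ganglion-cell count.
#'
#' @param map A [thickness_map()].
#' @param biometry The eye's [eye_biometry()].
#' @param field A `density_field`; default [synthetic_density_field()].
#' @param displacement_fn Henle displacement curve; default
#'   [henle_displacement()].
#' @param min_coverage Locations with raster coverage below this fraction are
#'   flagged `excluded`; default 0.5.
#' @param conv_slope,conv_offset GCIPL-to-GCL conversion coefficients.
#' @return Data frame, one row per analyzable location: `loc`, `x_deg`,
#'   `y_deg`, `gcipl_um`, `coverage`, `gcl_um`, `area_mm2`, `density`,
#'   `count`, `count_dB`, `floored`, `excluded`.
#' @export
project_and_estimate <- function(map, biometry, field = synthetic_density_field(),
                                 displacement_fn = henle_displacement,
                                 min_coverage = 0.5,
                                 conv_slope = 0.5651, conv_offset = 0.9026) {
  grid <- vf_grid_analyzable()
  out <- lapply(seq_len(nrow(grid)), function(i) {
    reg <- project_stimulus(grid$x_deg[i], grid$y_deg[i], biometry)
    reg <- apply_henle_displacement(reg, displacement_fn)
    s <- sample_mean_thickness(map, reg)
    if (is.na(s$mean_um)) {
      return(data.frame(gcipl_um = NA_real_, coverage = s$coverage,
                        gcl_um = NA_real_, area_mm2 = NA_real_,
                        density = NA_real_, count = NA_real_,
                        count_dB = NA_real_, floored = NA))
    }
    gcl <- gcipl_to_gcl(s$mean_um, conv_slope, conv_offset)
    est <- estimate_gc_count(gcl, reg, field)
    data.frame(gcipl_um = s$mean_um, coverage = s$coverage, gcl_um = gcl,
               area_mm2 = est$area_mm2, density = est$density,
               count = est$count, count_dB = est$count_dB,
               floored = est$floored)
  })
  res <- cbind(grid[c("loc", "x_deg", "y_deg")], do.call(rbind, out))
  res$excluded <- is.na(res$coverage) | res$coverage < min_coverage
  res
}

#' Run the full hemi-cluster classification analysis on a synthetic cohort
#'
#' Orchestrates every stage on a generated cohort: builds the normative model
#' from held-out healthy reference eyes, derives percentile flag maps,
#' relative maps and hemi-cluster features per eye, labels hemi-clusters from
#' the eyes' visual fields (HPA rule + 25% criterion), trains the PCA and
#' cascaded classifiers on the ROCC cohort, and evaluates all three methods.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param reference List of reference eyes (maps + biometries) for the
#'   normative model; by default generated internally from the cohort's
#'   config with a shifted seed.
#' @param n_reference Reference eyes when generating internally, default 120.
#' @param pct Flagging percentile, default 0.05.
#' @param criterion Hemi-cluster VF criterion, default 0.25.
#' @param use_repeatable When the cohort carries two VFs per eye, require the
#'   defect to be repeatable across both attempts (intersection of HPA maps);
#'   default `FALSE`.
#' @param ci_method,n_boot Passed to [select_method_and_report()].
#' @return List: `features` (long per eye x hemi-cluster data frame with
#'   scores and labels), `models` (cascade + per-group PCA fits),
#'   `report` (an `eval_report`), `assignment`, `norm`.
#' @export
run_cohort_analysis <- function(cohort, reference = NULL, n_reference = 120,
                                pct = 0.05, criterion = 0.25,
                                use_repeatable = FALSE,
                                ci_method = "cluster-bootstrap", n_boot = 500) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  if (is.null(reference)) {
    reference <- generate_reference_eyes(cfg, n_reference)
  }
  norm <- build_normative_db(lapply(reference, `[[`, "map"),
                             lapply(reference, `[[`, "biometry"))
  assignment <- build_cluster_assignment(cohort$eyes[[1]]$map)
  q_raster <- norm_quantile_raster(norm, pct)

  rows <- lapply(cohort$eyes, function(eye) {
    flags <- percentile_flag_map(eye$map, eye$biometry, norm, pct, q_raster)
    rel <- relative_thickness_map(eye$map, eye$biometry, norm)
    feats <- compute_features(eye$map, rel$relative, flags, assignment)
    defects <- if (use_repeatable && !is.null(eye$vf2))
      require_repeatable_defect(eye$vf, eye$vf2)
    else classify_defect_locations(eye$vf)
    lab <- label_hemiclusters(defects, assignment$vf_labels, criterion)
    feats$vf_defective <- unname(lab[feats$hemicluster])
    feats$id <- eye$id
    feats$diagnosis <- eye$diagnosis
    feats$perimetric <- any(defects)
    feats
  })
  features <- do.call(rbind, rows)

  split <- cohort$split
  rocc <- features[features$id %in% split$rocc_ids, , drop = FALSE]
  feature_names <- c("mean_um", "sd_um", "asymmetry_um",
                     "mean_relative_um", "asymmetry_relative_um")
  groups <- cluster_group_levels()

  models <- list()
  scores <- features[c("id", "hemicluster", "group", "hemifield", "diagnosis")]
  scores$label <- features$vf_defective
  scores$percentile <- features$flagged_proportion
  scores$pca <- NA_real_
  scores$cascade <- NA_real_
  for (h in c("superior", "inferior")) {
    tr_by_group <- lapply(groups, function(g) {
      d <- rocc[rocc$group == g & rocc$hemifield == h, , drop = FALSE]
      d[order(d$id), , drop = FALSE]
    })
    names(tr_by_group) <- groups
    feats_by_group <- lapply(tr_by_group, function(d) d[feature_names])
    labels_by_group <- lapply(tr_by_group, function(d) d$vf_defective)
    cas <- fit_cascade(feats_by_group, labels_by_group)
    models[[h]] <- cas
    all_by_group <- lapply(groups, function(g) {
      d <- features[features$group == g & features$hemifield == h, , drop = FALSE]
      d[order(d$id), , drop = FALSE]
    })
    names(all_by_group) <- groups
    cas_pred <- predict(cas, lapply(all_by_group, function(d) d[feature_names]))
    for (g in groups) {
      d <- all_by_group[[g]]
      idx <- match(paste(d$id, d$hemicluster), paste(scores$id, scores$hemicluster))
      scores$cascade[idx] <- cas_pred[[g]]
    }
  }
  # independent (non-cascaded) PCA models for the comparison
  for (h in c("superior", "inferior")) for (g in groups) {
    d <- rocc[rocc$group == g & rocc$hemifield == h, , drop = FALSE]
    m <- fit_pca_logistic(d[feature_names], d$vf_defective)
    models[[paste("pca", h, g, sep = ".")]] <- m
    all_d <- features[features$group == g & features$hemifield == h, , drop = FALSE]
    idx <- match(paste(all_d$id, all_d$hemicluster),
                 paste(scores$id, scores$hemicluster))
    scores$pca[idx] <- predict(m, all_d[feature_names])
  }
  # central group has no more-central input; its cascade score is the PCA score
  central <- scores$group == groups[1]
  scores$cascade[central] <- NA_real_

  report <- select_method_and_report(scores, split, ci_method = ci_method,
                                     n_boot = n_boot)
  list(features = features, scores = scores, models = models,
       report = report, assignment = assignment, norm = norm)
}
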