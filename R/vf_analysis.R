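#' Visual-field reliability check
#'
#' An eye's 24-2 result is considered reliable when its false-positive rate is
#' strictly below the cutoff (default 15%).
#'
#' @param vf A [vf_result()].
#' @param fp_cutoff Fraction; default 0.15.
#' @return Logical.
#' @export
check_reliability <- function(vf, fp_cutoff = 0.15) {
  stopifnot(inherits(vf, "vf_result"))
  vf$false_positive_rate < fp_cutoff
}

# Adjacency between analyzable 24-2 locations on the 6-degree lattice.
# `neighbourhood` 8 includes diagonals; hemifield_restricted forbids edges
# crossing the horizontal midline (glaucomatous defects respect it).
vf_adjacency <- function(grid, neighbourhood = 8, hemifield_restricted = TRUE) {
  stopifnot(neighbourhood %in% c(4, 8))
  n <- nrow(grid)
  dx <- outer(grid$x_deg, grid$x_deg, "-") / 6
  dy <- outer(grid$y_deg, grid$y_deg, "-") / 6
  adj <- if (neighbourhood == 8) {
    abs(dx) <= 1 & abs(dy) <= 1
  } else {
    (abs(dx) + abs(dy)) <= 1
  }
  diag(adj) <- FALSE
  if (hemifield_restricted) {
    same_hemi <- outer(grid$y_deg > 0, grid$y_deg > 0, "==")
    adj <- adj & same_hemi
  }
  adj
}

# Connected components of a logical membership vector under an adjacency matrix.
connected_components <- function(member, adj) {
  idx <- which(member)
  comp <- integer(length(member))
  cur <- 0L
  for (s in idx) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & member & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Classify 24-2 locations as defective (Hodapp-Parrish-Anderson rule)
#'
#' A location is defective when it belongs to a contiguous group of at least
#' three locations each flagged at p < 5% or worse on the pattern-deviation
#' probability map, with at least one group member at p < 1% or worse. When no
#' pattern-deviation map is available (severely depressed hill of vision),
#' every analyzable location is classified defective.
#'
#' @param vf A [vf_result()].
#' @param neighbourhood 8 (default, includes diagonals) or 4.
#' @param hemifield_restricted Logical; restrict contiguity to within one
#'   hemifield (default `TRUE`).
#' @return Logical vector over the 52 analyzable locations (class `defect_map`).
#' @export
classify_defect_locations <- function(vf, neighbourhood = 8,
                                      hemifield_restricted = TRUE) {
  stopifnot(inherits(vf, "vf_result"))
  grid <- vf$grid
  if (!vf$pd_map_available) {
    return(structure(rep(TRUE, nrow(grid)), class = "defect_map"))
  }
  rank5 <- prob_rank("p<5")
  rank1 <- prob_rank("p<1")
  r <- prob_rank(vf$pd_prob)
  member <- r <= rank5
  adj <- vf_adjacency(grid, neighbourhood, hemifield_restricted)
  comp <- connected_components(member, adj)
  defective <- rep(FALSE, nrow(grid))
  for (k in seq_len(max(comp, 0L))) {
    in_k <- comp == k
    if (sum(in_k) >= 3 && any(r[in_k] <= rank1)) defective[in_k] <- TRUE
  }
  structure(defective, class = "defect_map")
}

#' Label hemi-clusters as visual-field defective
#'
#' A hemi-cluster is defective when the fraction of its assigned analyzable
#' locations that are defective meets the criterion (default 25%, inclusive,
#' so the two-point central hemi-cluster with one defective point qualifies).
#'
#' @param defects Logical defect map over the 52 analyzable locations.
#' @param vf_labels Hemi-cluster id per analyzable location (character/factor).
#' @param criterion Fraction, default 0.25.
#' @return Named logical vector, one entry per hemi-cluster.
#' @export
label_hemiclusters <- function(defects, vf_labels, criterion = 0.25) {
  stopifnot(length(defects) == length(vf_labels))
  if (anyNA(vf_labels)) stop("every analyzable location must be assigned to a hemi-cluster")
  tab <- tapply(as.logical(defects), as.character(vf_labels),
                function(d) mean(d) >= criterion)
  if (any(is.na(tab))) stop("empty hemi-cluster in assignment")
  tab
}

#' Stage glaucoma severity from visual-field results
#'
#' Pre-perimetric when no significant defect is present; otherwise staged by
#' mean-deviation bands: early MD > -6 dB, moderate -12 < MD <= -6 dB,
#' advanced MD <= -12 dB.
#'
#' @param vf A [vf_result()].
#' @param defects Defect map from [classify_defect_locations()].
#' @param md_bands Two descending negative cutoffs, default `c(-6, -12)`.
#' @return One of `"pre-perimetric"`, `"early"`, `"moderate"`, `"advanced"`.
#' @export
stage_glaucoma <- function(vf, defects, md_bands = c(-6, -12)) {
  stopifnot(inherits(vf, "vf_result"), length(md_bands) == 2, md_bands[1] > md_bands[2])
  if (!any(defects)) return("pre-perimetric")
  md <- vf$md_dB
  if (md > md_bands[1]) "early"
  else if (md > md_bands[2]) "moderate"
  else "advanced"
}

#' Repeatable defect across two visual-field attempts
#'
#' A location counts as defective only when flagged by the defect rule in both
#' same-visit attempts (intersection of the two defect maps).
#'
#' @param vf1,vf2 Two [vf_result()] objects from the same eye.
#' @param ... Passed to [classify_defect_locations()].
#' @return A `defect_map`.
#' @export
require_repeatable_defect <- function(vf1, vf2, ...) {
  stopifnot(inherits(vf1, "vf_result"), inherits(vf2, "vf_result"))
  if (!identical(vf1$grid[c("x_deg", "y_deg")], vf2$grid[c("x_deg", "y_deg")]))
    stop("mismatched grids between attempts")
  d1 <- classify_defect_locations(vf1, ...)
  d2 <- classify_defect_locations(vf2, ...)
  structure(as.logical(d1) & as.logical(d2), class = "defect_map")
}
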