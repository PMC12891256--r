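#' The 24-2 perimetric test grid
#'
#' Returns the 54 locations of the standard 24-2 test pattern in visual-field
#' coordinates normalised to a right eye: x positive temporal (blind spot at
#' x = +15), y positive superior, 6 degree spacing. Two locations fall on the
#' physiological blind spot and are excluded from analysis, leaving 52
#' analyzable points.
#'
#' @return A data frame with one row per location and columns `loc` (stable
#'   integer id, row-major from superior-nasal), `x_deg`, `y_deg` and
#'   `is_blind_spot`.
#' @export
vf_grid_242 <- function() {
  rows <- list(
    c(y = 21, xmin = -9,  xmax = 9),
    c(y = 15, xmin = -15, xmax = 15),
    c(y = 9,  xmin = -21, xmax = 21),
    c(y = 3,  xmin = -27, xmax = 21),
    c(y = -3, xmin = -27, xmax = 21),
    c(y = -9, xmin = -21, xmax = 21),
    c(y = -15, xmin = -15, xmax = 15),
    c(y = -21, xmin = -9,  xmax = 9)
  )
  pts <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[["xmin"]], r[["xmax"]], by = 6)
    cbind(x_deg = x, y_deg = rep(r[["y"]], length(x)))
  }))
  grid <- data.frame(loc = seq_len(nrow(pts)), pts)
  grid$is_blind_spot <- grid$x_deg == 15 & abs(grid$y_deg) == 3
  stopifnot(nrow(grid) == 54L, sum(grid$is_blind_spot) == 2L)
  grid
}

#' Analyzable (non-blind-spot) 24-2 locations
#' @return `vf_grid_242()` restricted to the 52 analyzable locations.
#' @export
vf_grid_analyzable <- function() {
  g <- vf_grid_242()
  g[!g$is_blind_spot, , drop = FALSE]
}

# Hemifield of a VF location in field space: "superior" for y > 0.
vf_hemifield <- function(y_deg) ifelse(y_deg > 0, "superior", "inferior")

#' Ordered pattern-deviation probability categories
#'
#' Perimetric probability maps grade each location on an ordinal scale; lower
#' levels are more abnormal. Category `"p<0.5"` means flagged at p < 0.5%,
#' and `"ns"` means not significant.
#' @return Character vector of the five categories from most to least abnormal.
#' @export
vf_prob_levels <- function() c("p<0.5", "p<1", "p<2", "p<5", "ns")

# Ordinal rank: 1 = most abnormal. Accepts factor or character.
prob_rank <- function(p) {
  lv <- vf_prob_levels()
  r <- match(as.character(p), lv)
  if (anyNA(r)) stop("unknown probability category: ",
                     paste(setdiff(unique(as.character(p)), lv), collapse = ", "))
  r
}

#' Construct a visual-field result
#'
#' Bundles the pointwise 24-2 data for one eye: thresholds, total and pattern
#' deviation with their probability categories, and the global indices. All
#' pointwise vectors are ordered as `vf_grid_analyzable()` (52 locations).
#'
#' @param thresholds_dB,total_deviation_dB,pattern_deviation_dB Numeric length-52.
#' @param td_prob,pd_prob Probability categories per location (see
#'   [vf_prob_levels()]). `pd_prob` may be `NULL` when `pd_map_available` is
#'   `FALSE` (severely depressed hill of vision).
#' @param md_dB,psd_dB Mean deviation and pattern standard deviation.
#' @param false_positive_rate Fraction in \[0, 1\].
#' @param pd_map_available Logical; if `FALSE` the pattern-deviation map could
#'   not be produced and every location is treated as defective downstream.
#' @return An object of class `vf_result`.
#' @export
vf_result <- function(thresholds_dB, total_deviation_dB, pattern_deviation_dB,
                      td_prob, pd_prob, md_dB, psd_dB, false_positive_rate,
                      pd_map_available = TRUE) {
  n <- 52L
  stopifnot(length(thresholds_dB) == n, length(total_deviation_dB) == n,
            length(pattern_deviation_dB) == n || !pd_map_available,
            length(td_prob) == n)
  if (is.null(false_positive_rate) || is.na(false_positive_rate))
    stop("false_positive_rate is required")
  stopifnot(false_positive_rate >= 0, false_positive_rate <= 1)
  if (pd_map_available) {
    stopifnot(length(pd_prob) == n)
    prob_rank(pd_prob)  # validate categories
  }
  prob_rank(td_prob)
  structure(list(
    grid = vf_grid_analyzable(),
    thresholds_dB = as.numeric(thresholds_dB),
    total_deviation_dB = as.numeric(total_deviation_dB),
    pattern_deviation_dB = if (pd_map_available) as.numeric(pattern_deviation_dB) else rep(NA_real_, n),
    td_prob = as.character(td_prob),
    pd_prob = if (pd_map_available) as.character(pd_prob) else rep(NA_character_, n),
    md_dB = md_dB, psd_dB = psd_dB,
    false_positive_rate = false_positive_rate,
    pd_map_available = isTRUE(pd_map_available)
  ), class = "vf_result")
}

#' @export
print.vf_result <- function(x, ...) {
  cat(sprintf("24-2 visual field: MD %.2f dB, PSD %.2f dB, FP %.1f%%%s\n",
              x$md_dB, x$psd_dB, 100 * x$false_positive_rate,
              if (!x$pd_map_available) " (no PD map)" else ""))
  invisible(x)
}
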