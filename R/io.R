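#' Write a thickness (or density) raster to CSV
#'
#' Plain numeric CSV, one row per raster row, `NA` for invalid squares.
#' @param values Numeric matrix.
#' @param path Output file.
#' @export
write_raster_csv <- function(values, path) {
  utils::write.table(values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a raster from CSV (or single-channel float TIFF)
#'
#' CSV rasters are plain numeric grids with `NA` (or `NaN`) marking invalid
#' squares; `.tif`/`.tiff` files are read as 32-bit float via the `tiff`
#' package when available, with `NaN` as invalid.
#'
#' @param path Input file.
#' @return Numeric matrix.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF rasters requires the 'tiff' package")
    m <- tiff::readTIFF(path)  # float samples are returned unscaled
    m[is.nan(m)] <- NA
    return(m)
  }
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = c("NA", "NaN")))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("raster file is not numeric: ", path)
  m
}

#' Write a visual-field result as CSV plus JSON sidecar
#'
#' CSV has one row per analyzable location (`x_deg`, `y_deg`, `threshold`,
#' `td`, `pd`, `td_prob`, `pd_prob`); the JSON sidecar (same path with
#' `.json`) carries `md`, `psd`, `fp_rate`, `pd_map_available`, `laterality`.
#'
#' @param vf A [vf_result()] (internally right-eye normalised).
#' @param path CSV path; sidecar written next to it.
#' @param laterality `"OD"` or `"OS"`; left-eye records are written in their
#'   native (mirrored) field coordinates, as a perimeter export would be.
#' @export
write_vf <- function(vf, path, laterality = "OD") {
  stopifnot(inherits(vf, "vf_result"))
  xs <- if (identical(laterality, "OS")) -vf$grid$x_deg else vf$grid$x_deg
  df <- data.frame(x_deg = xs, y_deg = vf$grid$y_deg,
                   threshold = vf$thresholds_dB,
                   td = vf$total_deviation_dB, pd = vf$pattern_deviation_dB,
                   td_prob = vf$td_prob, pd_prob = vf$pd_prob)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  side <- list(md = vf$md_dB, psd = vf$psd_dB,
               fp_rate = vf$false_positive_rate,
               pd_map_available = vf$pd_map_available,
               laterality = laterality)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a visual-field result written by [write_vf()]
#'
#' Left-eye records are mirrored to right-eye field coordinates on read
#' (x -> -x). Missing required fields raise errors naming the field.
#'
#' @param path CSV path (JSON sidecar expected next to it).
#' @return A [vf_result()].
#' @export
read_vf <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_deg", "y_deg", "threshold", "td", "td_prob")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("VF file ", path, " missing field(s): ",
                         paste(miss, collapse = ", "))
  side_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(side_path)) stop("missing VF sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (f in c("md", "psd", "fp_rate")) {
    if (is.null(side[[f]])) stop("VF sidecar ", side_path, " missing field: ", f)
  }
  pd_available <- !isFALSE(side$pd_map_available)
  if (pd_available && !"pd_prob" %in% names(df))
    stop("VF file ", path, " missing field: pd_prob")
  if (identical(side$laterality, "OS")) df$x_deg <- -df$x_deg
  grid <- vf_grid_analyzable()
  o <- match(paste(grid$x_deg, grid$y_deg), paste(df$x_deg, df$y_deg))
  if (anyNA(o)) stop("VF file ", path, " does not cover the 24-2 grid")
  df <- df[o, , drop = FALSE]
  vf_result(df$threshold, df$td,
            if ("pd" %in% names(df)) df$pd else rep(NA_real_, 52),
            df$td_prob,
            if (pd_available) df$pd_prob else NULL,
            side$md, side$psd, side$fp_rate, pd_available)
}

#' Serialize a PCA-logistic model (or cascade) to JSON
#' @param model A `pca_logistic_model` or `cascade_model`.
#' @param path Output JSON path.
#' @export
write_model_json <- function(model, path) {
  ser_one <- function(m) list(
    retained_parameters = m$retained_parameters,
    center = as.list(m$center), scale = as.list(m$scale),
    rotation = lapply(seq_len(ncol(m$rotation)), function(j) unname(m$rotation[, j])),
    rotation_rows = rownames(m$rotation),
    eigenvalues = m$eigenvalues, n_pc = m$n_pc,
    coefficients = m$coefficients, penalized = m$penalized,
    n_train = m$n_train)
  obj <- if (inherits(model, "cascade_model")) {
    list(type = "cascade", order = model$order,
         models = lapply(model$models, ser_one))
  } else list(type = "pca_logistic", model = ser_one(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_model_json()]
#' @param path JSON path.
#' @return A `pca_logistic_model` or `cascade_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_one <- function(m) {
    # jsonlite simplifies the list of PC columns to a matrix (one row per
    # column) or, for a single PC, a plain vector
    rot <- m$rotation
    rot <- if (is.list(rot)) do.call(cbind, lapply(rot, unlist))
    else if (is.matrix(rot)) t(rot)
    else matrix(rot, ncol = 1)
    rownames(rot) <- unlist(m$rotation_rows)
    structure(list(
      retained_parameters = unlist(m$retained_parameters),
      center = unlist(m$center), scale = unlist(m$scale),
      rotation = rot, eigenvalues = unlist(m$eigenvalues),
      n_pc = m$n_pc, coefficients = unlist(m$coefficients),
      penalized = isTRUE(m$penalized), n_train = m$n_train
    ), class = "pca_logistic_model")
  }
  if (identical(obj$type, "cascade")) {
    structure(list(models = lapply(obj$models, de_one), order = unlist(obj$order)),
              class = "cascade_model")
  } else de_one(obj$model)
}
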