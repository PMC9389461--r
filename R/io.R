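#' Read nucleus centroid tables
#'
#' Parses a CSV with header columns `sample_id`, `x_um`, `y_um` into one
#' [nucleus_set()] per sample. Coordinates are micrometres.
#'
#' @param path Path to a CSV file.
#' @return Named list of `nucleus_set` objects (one per `sample_id`, in
#'   order of first appearance).
#' @export
read_points <- function(path) {
  if (!file.exists(path))
    stop("points file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE, colClasses = "character")
  need <- c("sample_id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- suppressWarnings(as.numeric(df$x_um))
  y <- suppressWarnings(as.numeric(df$y_um))
  bad <- which(nrow(df) > 0 & (is.na(x) | is.na(y)))
  if (length(bad))
    stop(sprintf("non-numeric coordinate in points CSV at data row %d",
                 bad[1L]), call. = FALSE)
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    sel <- df$sample_id == id
    nucleus_set(id, x[sel], y[sel])
  })
  names(out) <- ids
  out
}

#' Read the source geometry
#'
#' Parses a CSV with columns `role` (`outline` or `interface`),
#' `vertex_index`, `x_um`, `y_um` into a [source_geometry()].
#'
#' @param path Path to a CSV file.
#' @param contact_length Optional spheroid-material contact length in um.
#' @return A `source_geometry`.
#' @export
read_geometry <- function(path, contact_length = NA_real_) {
  if (!file.exists(path))
    stop("geometry file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("role", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("geometry CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(df$role), c("outline", "interface"))
  if (length(bad_role))
    stop("geometry CSV has unknown role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  pick <- function(role) {
    sub <- df[df$role == role, , drop = FALSE]
    sub <- sub[order(sub$vertex_index), , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    cbind(x = as.numeric(sub$x_um), y = as.numeric(sub$y_um))
  }
  interface <- pick("interface")
  if (is.null(interface))
    stop("geometry CSV contains no interface vertices", call. = FALSE)
  source_geometry(outline = pick("outline"), interface = interface,
                  contact_length = contact_length)
}

#' Read a JSON analysis configuration
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a JSON file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, vals)
}

#' Write pipeline products to disk
#'
#' Tables (per-nucleus distances, ROI grids, profiles) are written as CSV;
#' scalar summaries (fitted ellipses, anisotropy summaries) as JSON.
#' Numeric round-trips are lossless to better than 1e-9 relative.
#'
#' @param x A pipeline product (`nucleus_set`, `density_grid`,
#'   `isodensity_profile`, `distance_result`, `anisotropy_summary`,
#'   `fitted_ellipse`, or a plain data.frame).
#' @param path Output file path; the format follows the object type.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num],
                    function(v) trimws(formatC(v, digits = 15, format = "g")))
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

.write_json <- function(obj, path) {
  tryCatch(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @export
write_results.nucleus_set <- function(x, path) {
  .write_csv(data.frame(sample_id = x$sample_id,
                        x_um = x$points$x, y_um = x$points$y), path)
}

#' @export
write_results.density_grid <- function(x, path) {
  .write_csv(data.frame(col_index = x$rois$col_index,
                        row_index = x$rois$row_index,
                        x_um = x$rois$x, y_um = x$rois$y,
                        count = x$rois$count,
                        density_cells_per_mm2 = x$rois$density), path)
}

#' @export
write_results.isodensity_profile <- function(x, path) {
  .write_csv(data.frame(threshold_label = x$threshold_label,
                        threshold_value = x$threshold_value,
                        x_um = x$points$x, y_um = x$points$y), path)
}

#' @export
write_results.distance_result <- function(x, path) {
  .write_csv(data.frame(sample_id = x$sample_id, assay_mode = x$assay_mode,
                        distance_um = x$distances), path)
}

#' @export
write_results.fitted_ellipse <- function(x, path) {
  .write_json(list(a_um = x$a, b_um = x$b,
                   center_x_um = x$center[1], center_y_um = x$center[2],
                   tilt_deg = x$tilt), path)
}

#' @export
write_results.anisotropy_summary <- function(x, path) {
  per_thr <- lapply(x$per_threshold, function(row) {
    list(a_um = row$a, sd_a_um = row$sd_a, b_um = row$b, sd_b_um = row$sd_b,
         a_prime_um = row$a_prime,
         R_star = if (is.na(row$R_star)) NULL else row$R_star)
  })
  .write_json(list(P_um = x$P, reference_R = x$reference_R,
                   thresholds = per_thr), path)
}

#' @export
write_results.data.frame <- function(x, path) .write_csv(x, path)

#' Read a TIFF stack as projection images
#'
#' Reads a single- or multi-page grayscale TIFF into a list of
#' `projection_image` objects (one per page).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size Pixel edge length in um/pixel.
#' @return List of `projection_image` objects.
#' @export
read_tiff_stack <- function(path, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB export
    projection_image(p, pixel_size)
  })
}
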