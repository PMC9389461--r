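#' Construct a nucleus set
#'
#' A `nucleus_set` holds the centroids of all detected nuclei of one sample,
#' in physical micrometre coordinates. Coordinates live in the sample frame
#' until [register_frame()] maps them into the interface-anchored frame
#' (interface at y = 0, material at y > 0).
#'
#' @param sample_id Character label for the sample.
#' @param x,y Numeric vectors of equal length, centroid coordinates in um.
#' @param pixel_size Optional um/pixel used during image-based detection;
#'   `NA` for point-table input.
#' @return An object of class `nucleus_set` with elements `sample_id`,
#'   `points` (data.frame with columns `x`, `y`, in um) and `pixel_size`.
#' @examples
#' ns <- nucleus_set("s1", x = c(0, 10), y = c(5, 50))
#' nrow(ns$points)
#' @export
nucleus_set <- function(sample_id, x = numeric(), y = numeric(),
                        pixel_size = NA_real_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  .check_finite_coords(x, y)
  structure(list(sample_id = sample_id,
                 points = data.frame(x = x, y = y),
                 pixel_size = pixel_size),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> sample '%s': %d nuclei", x$sample_id,
              nrow(x$points)))
  if (nrow(x$points) > 0)
    cat(sprintf(", x in [%.1f, %.1f] um, y in [%.1f, %.1f] um",
                min(x$points$x), max(x$points$x),
                min(x$points$y), max(x$points$y)))
  cat("\n")
  invisible(x)
}

.check_finite_coords <- function(x, y) {
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("coordinates must be finite (no NA/NaN/Inf)", call. = FALSE)
  invisible(TRUE)
}

#' Construct the cell-source geometry
#'
#' Bundles the manually outlined cell-source (spheroid) region, which is
#' excluded from all density and distance analyses, with the biomaterial
#' interface polyline and, optionally, the measured spheroid-material
#' contact length (2 P).
#'
#' @param outline Two-column matrix/data.frame of polygon vertices (um)
#'   delimiting the excluded source region. Closed automatically when the
#'   first and last vertex differ. Must be simple (non-self-intersecting).
#' @param interface Two-column matrix/data.frame (>= 2 vertices, um) tracing
#'   the biomaterial surface.
#' @param contact_length Optional positive scalar, spheroid-material contact
#'   length in um.
#' @return An object of class `source_geometry`.
#' @export
source_geometry <- function(outline = NULL, interface, contact_length = NA_real_) {
  interface <- .as_xy(interface, "interface")
  if (nrow(interface) < 2L)
    stop("interface polyline needs at least 2 vertices", call. = FALSE)
  if (!is.null(outline)) {
    outline <- .as_xy(outline, "outline")
    if (nrow(outline) < 3L)
      stop("outline polygon needs at least 3 vertices", call. = FALSE)
    if (!isTRUE(all.equal(outline[1L, ], outline[nrow(outline), ],
                          check.attributes = FALSE)))
      outline <- rbind(outline, outline[1L, ])
    if (.polygon_self_intersects(outline))
      stop("outline polygon is self-intersecting", call. = FALSE)
  }
  if (!is.na(contact_length) && contact_length <= 0)
    stop("contact_length must be > 0", call. = FALSE)
  structure(list(outline = outline, interface = interface,
                 contact_length = contact_length),
            class = "source_geometry")
}

.as_xy <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop(what, " must have two columns (x, y)", call. = FALSE)
  storage.mode(m) <- "double"
  if (nrow(m) && !all(is.finite(m)))
    stop(what, " vertices must be finite", call. = FALSE)
  colnames(m) <- c("x", "y")
  m
}

# Proper-crossing test between non-adjacent edges of a closed polygon.
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly) - 1L                      # closed: last vertex == first
  if (n < 4L) return(FALSE)                 # a triangle cannot self-intersect
  seg <- cbind(poly[seq_len(n), , drop = FALSE],
               poly[seq_len(n) + 1L, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]          # skip edges sharing a vertex
    for (j in js) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Analysis configuration
#'
#' All tunable parameters of the density/isodensity pipeline with the
#' defaults used throughout: 200-um circular ROIs overlapping by 50% of
#' their diameter, density thresholds of 50, 95, 150 and 475 cells/mm2
#' (5/10/15/50% of a 950 cells/mm2 reference density), a 200-um interface
#' band, and a spheroid-radius correction of P = 745 um. The 50% threshold
#' is computed and exported but excluded from the anisotropy ratio R* by
#' default (`anisotropy_thresholds`).
#'
#' @param roi_diameter ROI diameter in um.
#' @param roi_overlap_fraction Fraction of the diameter by which adjacent
#'   ROIs overlap; grid spacing is `roi_diameter * (1 - roi_overlap_fraction)`.
#' @param reference_density Reference cell density in cells/mm2.
#' @param density_thresholds Strictly increasing vector of cells/mm2.
#' @param threshold_labels Labels parallel to `density_thresholds`.
#' @param min_area,max_area Nucleus area filter in um2.
#' @param min_circularity Minimum circularity (4 pi A / P^2) of a particle.
#' @param binarization_threshold Numeric intensity or `"auto"` (Otsu).
#' @param band_height Interface band height in um.
#' @param p_reference Spheroid radius P in um subtracted from semi-major axes.
#' @param anisotropy_thresholds Labels of thresholds entering R*.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(roi_diameter = 200,
                            roi_overlap_fraction = 0.5,
                            reference_density = 950,
                            density_thresholds = c(50, 95, 150, 475),
                            threshold_labels = c("5%", "10%", "15%", "50%"),
                            min_area = 20,
                            max_area = 500,
                            min_circularity = 0.3,
                            binarization_threshold = "auto",
                            band_height = 200,
                            p_reference = 745,
                            anisotropy_thresholds = c("5%", "10%", "15%")) {
  if (roi_diameter <= 0) stop("roi_diameter must be > 0", call. = FALSE)
  if (roi_overlap_fraction < 0 || roi_overlap_fraction >= 1)
    stop("roi_overlap_fraction must be in [0, 1)", call. = FALSE)
  if (length(density_thresholds) != length(threshold_labels))
    stop("density_thresholds and threshold_labels differ in length",
         call. = FALSE)
  if (is.unsorted(density_thresholds, strictly = TRUE))
    stop("density_thresholds must be strictly increasing", call. = FALSE)
  if (band_height <= 0) stop("band_height must be > 0", call. = FALSE)
  if (min_area >= max_area) stop("min_area must be < max_area", call. = FALSE)
  structure(list(roi_diameter = roi_diameter,
                 roi_overlap_fraction = roi_overlap_fraction,
                 reference_density = reference_density,
                 density_thresholds = density_thresholds,
                 threshold_labels = threshold_labels,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 binarization_threshold = binarization_threshold,
                 band_height = band_height,
                 p_reference = p_reference,
                 anisotropy_thresholds = anisotropy_thresholds),
            class = "analysis_config")
}
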