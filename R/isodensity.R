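#' Register a sample into the interface-anchored frame
#'
#' Fits a least-squares line through the interface polyline vertices and
#' applies the rigid transform that maps this line onto y = 0 with the
#' biomaterial side at y > 0 (the cell-source outline, when present, ends up
#' at y < 0). All downstream geometry (density grid, profiles, bands) lives
#' in this frame: x is lateral (interface-parallel), y is depth into the
#' material.
#'
#' @param nuclei A [nucleus_set()].
#' @param geom A [source_geometry()].
#' @param roi_diameter ROI diameter in um; interfaces shorter than this are
#'   rejected and deviations from straightness beyond it trigger a warning.
#' @return List with `nuclei` (transformed `nucleus_set`), `geometry`
#'   (transformed `source_geometry`), and `transform` (list `R` 2x2 rotation,
#'   `t` translation applied as `p %*% t(R) + t`).
#' @export
register_frame <- function(nuclei, geom, roi_diameter = 200) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(geom, "source_geometry"))
  v <- geom$interface
  span <- sqrt(sum((v[nrow(v), ] - v[1L, ])^2))
  if (span < roi_diameter)
    stop("interface shorter than one ROI diameter (", roi_diameter, " um)",
         call. = FALSE)
  ctr <- colMeans(v)
  pc <- stats::prcomp(v, center = TRUE)     # 1st PC = least-squares direction
  dir <- pc$rotation[, 1L]
  nrm <- c(-dir[2L], dir[1L])
  dev <- abs((v[, 1L] - ctr[1L]) * nrm[1L] + (v[, 2L] - ctr[2L]) * nrm[2L])
  if (max(dev) >= roi_diameter)
    warning(sprintf(paste0("interface deviates from its least-squares line ",
                           "by up to %.0f um (>= ROI diameter); the flat-",
                           "interface registration is approximate"), max(dev)),
            call. = FALSE)
  R <- rbind(dir, nrm)                      # rotates dir -> x axis, nrm -> y
  trans <- function(p) sweep(p %*% t(R), 2L, as.vector(R %*% ctr))
  # orient the material side to y > 0: the source outline sits above the
  # interface, so its centroid must map to y < 0; without an outline, the
  # majority of nuclei decide.
  flip <- FALSE
  if (!is.null(geom$outline)) {
    oc <- trans(matrix(colMeans(geom$outline[-nrow(geom$outline), , drop = FALSE]),
                       ncol = 2L))
    if (oc[2L] > 0) flip <- TRUE
  } else if (nrow(nuclei$points) > 0L) {
    yy <- trans(as.matrix(nuclei$points))[, 2L]
    if (mean(yy > 0) < 0.5) flip <- TRUE
  }
  if (flip) {
    R <- rbind(dir, -nrm)
    trans <- function(p) sweep(p %*% t(R), 2L, as.vector(R %*% ctr))
  }
  np <- trans(as.matrix(nuclei$points))
  new_nuc <- nucleus_set(nuclei$sample_id, np[, 1L], np[, 2L],
                         pixel_size = nuclei$pixel_size)
  new_geom <- source_geometry(
    outline = if (is.null(geom$outline)) NULL else trans(geom$outline),
    interface = trans(geom$interface),
    contact_length = geom$contact_length)
  list(nuclei = new_nuc, geometry = new_geom,
       transform = list(R = R, t = -as.vector(R %*% ctr)))
}

#' Build the overlapping circular-ROI density grid
#'
#' Circular ROIs (diameter `config$roi_diameter`) are laid out on a regular
#' lattice with spacing `diameter * (1 - overlap)` (100 um at defaults, i.e.
#' 50% overlap). ROI centers sit at x = x_min + j * spacing and
#' y = spacing * (i + 1), so the first row lies fully inside the material.
#' A nucleus contributes to every ROI whose center is within one ROI radius
#' (boundary inclusive). Nuclei inside the excluded source-region polygon
#' are not counted. Density = count / ROI area, in cells/mm2.
#'
#' @param nuclei Registered `nucleus_set` (interface at y = 0, material y > 0).
#' @param config An [analysis_config()].
#' @param extent Optional list with `x_min`, `x_max`, `y_max` (um) bounding
#'   the grid; defaults to the bounding box of the nuclei at y >= 0.
#' @param exclude Optional polygon (um) of the excluded source region, e.g.
#'   `geometry$outline` after registration.
#' @return An object of class `density_grid`: `rois` data.frame
#'   (`col_index`, `row_index`, `x`, `y`, `count`, `density`),
#'   `roi_diameter`, `spacing`, `x_cols`, `y_rows`, and `density_matrix`
#'   (rows = depth index, cols = lateral index).
#' @export
build_density_grid <- function(nuclei, config = analysis_config(),
                               extent = NULL, exclude = NULL) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  spacing <- config$roi_diameter * (1 - config$roi_overlap_fraction)
  radius <- config$roi_diameter / 2
  pts <- as.matrix(nuclei$points)
  pts <- pts[pts[, 2L] >= 0, , drop = FALSE]
  if (nrow(pts) == 0L) {
    warning("no nuclei at y >= 0; empty density grid", call. = FALSE)
    return(structure(list(rois = data.frame(col_index = integer(),
                                            row_index = integer(),
                                            x = numeric(), y = numeric(),
                                            count = integer(),
                                            density = numeric()),
                          roi_diameter = config$roi_diameter,
                          spacing = spacing, x_cols = numeric(),
                          y_rows = numeric(),
                          density_matrix = matrix(0, 0, 0)),
                     class = "density_grid"))
  }
  if (!is.null(exclude)) {
    pts <- pts[!.points_in_polygon(pts, exclude), , drop = FALSE]
  }
  if (is.null(extent))
    extent <- list(x_min = min(pts[, 1L]), x_max = max(pts[, 1L]),
                   y_max = max(pts[, 2L]))
  x_cols <- seq(extent$x_min, extent$x_max + spacing, by = spacing)
  y_rows <- seq(spacing, max(extent$y_max + spacing, spacing), by = spacing)
  centers <- cbind(rep(x_cols, each = length(y_rows)),
                   rep(y_rows, times = length(x_cols)))
  # counts by vectorised distance filtering, column-blocked to bound memory
  cnt <- integer(nrow(centers))
  if (nrow(pts) > 0L) {
    for (jb in seq_along(x_cols)) {
      rows <- (jb - 1L) * length(y_rows) + seq_along(y_rows)
      near <- abs(pts[, 1L] - x_cols[jb]) <= radius
      sub <- pts[near, , drop = FALSE]
      if (nrow(sub) == 0L) next
      d2 <- outer(sub[, 1L], centers[rows, 1L], "-")^2 +
            outer(sub[, 2L], centers[rows, 2L], "-")^2
      cnt[rows] <- colSums(d2 <= radius^2 + 1e-9)
    }
  }
  area_mm2 <- pi * radius^2 * 1e-6
  dens <- cnt / area_mm2
  rois <- data.frame(col_index = rep(seq_along(x_cols), each = length(y_rows)),
                     row_index = rep(seq_along(y_rows), times = length(x_cols)),
                     x = centers[, 1L], y = centers[, 2L],
                     count = cnt, density = dens)
  dm <- matrix(dens[order(rois$col_index, rois$row_index)],
               nrow = length(y_rows), ncol = length(x_cols))
  structure(list(rois = rois, roi_diameter = config$roi_diameter,
                 spacing = spacing, x_cols = x_cols, y_rows = y_rows,
                 density_matrix = dm),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d ROIs (d = %g um, spacing %g um), max density %.1f cells/mm2\n",
              length(x$y_rows), length(x$x_cols), x$roi_diameter, x$spacing,
              if (nrow(x$rois)) max(x$rois$density) else 0))
  invisible(x)
}

#' Select the threshold ROI of a single grid column
#'
#' Given the densities of one column ordered shallow to deep, returns the
#' index of the deepest ROI with density >= threshold whose next two deeper
#' ROIs (virtual ROIs beyond the grid count as density 0) both lie below the
#' threshold, or `NA` when no ROI qualifies. The two-deeper-ROI condition
#' suppresses scattering from local density fluctuations.
#'
#' @param column Numeric vector of densities, shallow to deep.
#' @param threshold Density threshold in cells/mm2.
#' @return Integer index into `column`, or `NA_integer_`.
#' @export
select_threshold_roi_column <- function(column, threshold) {
  k <- length(column)
  if (k == 0L) return(NA_integer_)
  padded <- c(column, 0, 0)
  ok <- which(column >= threshold &
              padded[seq_len(k) + 1L] < threshold &
              padded[seq_len(k) + 2L] < threshold)
  if (length(ok) == 0L) NA_integer_ else max(ok)
}

#' Select threshold ROIs for every grid column
#'
#' @param grid A [build_density_grid()] result.
#' @param threshold Density threshold in cells/mm2.
#' @return Integer vector, one (possibly `NA`) row index per grid column.
#' @export
select_threshold_rois <- function(grid, threshold) {
  stopifnot(inherits(grid, "density_grid"))
  vapply(seq_along(grid$x_cols), function(j)
    select_threshold_roi_column(grid$density_matrix[, j], threshold),
    integer(1))
}

#' Extract an isodensity profile
#'
#' For each column with a threshold ROI, the profile point is the point of
#' the ROI perimeter most distant from the (flat, registered) interface:
#' (center x, center y + radius). Points are joined left to right into a
#' polygonal profile.
#'
#' @param grid A `density_grid`.
#' @param selected Integer vector from [select_threshold_rois()].
#' @param threshold_value Density threshold in cells/mm2.
#' @param threshold_label Label such as `"5%"`.
#' @return An object of class `isodensity_profile` with `points`
#'   (data.frame `x`, `y`, strictly increasing x), `threshold_label`,
#'   `threshold_value`, `selected` (per-column row indices).
#' @export
extract_profile <- function(grid, selected, threshold_value,
                            threshold_label = "") {
  stopifnot(inherits(grid, "density_grid"),
            length(selected) == length(grid$x_cols))
  has <- which(!is.na(selected))
  if (length(has) < 2L)
    stop("profile too sparse: fewer than 2 contributing columns",
         call. = FALSE)
  radius <- grid$roi_diameter / 2
  pts <- data.frame(x = grid$x_cols[has],
                    y = grid$y_rows[selected[has]] + radius)
  structure(list(points = pts, threshold_label = threshold_label,
                 threshold_value = threshold_value,
                 selected = selected),
            class = "isodensity_profile")
}

#' Extract all configured isodensity profiles
#'
#' @param grid A `density_grid`.
#' @param config An [analysis_config()]; one profile per entry of
#'   `config$density_thresholds`. Thresholds whose profile would have fewer
#'   than 2 contributing columns are dropped with a warning.
#' @return Named list of `isodensity_profile` objects (names = labels).
#' @export
extract_profiles <- function(grid, config = analysis_config()) {
  out <- list()
  for (i in seq_along(config$density_thresholds)) {
    thr <- config$density_thresholds[i]
    lab <- config$threshold_labels[i]
    sel <- select_threshold_rois(grid, thr)
    p <- tryCatch(extract_profile(grid, sel, thr, lab),
                  error = function(e) {
                    warning("threshold ", lab, ": ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(p)) out[[lab]] <- p
  }
  out
}

# x-coordinate splitting the area under a polyline profile (vs y = 0) in
# half, solved exactly on the piecewise-quadratic cumulative trapezoid area.
.half_area_x <- function(x, y) {
  seg <- diff(x) * (y[-length(y)] + y[-1L]) / 2
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("profile has zero underlying area", call. = FALSE)
  target <- total / 2
  k <- max(which(cum <= target + 1e-12))
  if (k == length(x)) return(x[length(x)])
  rem <- target - cum[k]
  dx <- x[k + 1L] - x[k]
  s <- (y[k + 1L] - y[k]) / dx
  if (abs(s) < 1e-14) {
    u <- rem / max(y[k], .Machine$double.eps)
  } else {
    # solve y_k u + s u^2 / 2 = rem for u in [0, dx]
    disc <- y[k]^2 + 2 * s * rem
    u <- (-y[k] + sqrt(max(disc, 0))) / s
    if (u < 0 || u > dx + 1e-9) u <- rem / max(y[k], .Machine$double.eps)
  }
  x[k] + min(max(u, 0), dx)
}

#' Center the lateral origin of the isodensity profiles
#'
#' The lateral zero is the mean, over the 5%, 10% and 15% profiles, of the
#' x-coordinate that splits the area between the profile polyline and the
#' interface (y = 0) into equal halves. All supplied profiles are shifted by
#' the resulting offset.
#'
#' @param profiles Named list of `isodensity_profile` objects.
#' @param labels Labels entering the origin average (default 5/10/15%).
#' @return List with `x0` (the lateral offset, um) and `profiles` (all input
#'   profiles shifted by `-x0`).
#' @export
center_origin <- function(profiles, labels = c("5%", "10%", "15%")) {
  use <- profiles[intersect(labels, names(profiles))]
  if (length(use) == 0L)
    stop("none of the origin-defining profiles are present", call. = FALSE)
  splits <- vapply(use, function(p) .half_area_x(p$points$x, p$points$y),
                   numeric(1))
  x0 <- mean(splits)
  shifted <- lapply(profiles, function(p) {
    p$points$x <- p$points$x - x0
    p
  })
  list(x0 = x0, profiles = shifted)
}
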