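#' Minimum distance from points to a polyline or polygon
#'
#' Exact Euclidean minimum over all point-to-segment distances. This is the
#' migration distance of a nucleus from the cell-source outline (3D spheroid
#' assay) or from the contacted material surface (2D layer assays).
#'
#' @param points Two-column matrix/data.frame of query points (um).
#' @param outline Two-column matrix/data.frame of curve vertices (um),
#'   >= 2 vertices; consecutive vertices form segments.
#' @return Numeric vector of minimum distances, one per point.
#' @export
min_distance_to_outline <- function(points, outline) {
  p <- .as_xy(points, "points")
  v <- .as_xy(outline, "outline")
  if (nrow(v) < 2L)
    stop("outline needs at least 2 vertices", call. = FALSE)
  ax <- v[-nrow(v), 1L]; ay <- v[-nrow(v), 2L]
  bx <- v[-1L, 1L];      by <- v[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  if (all(len2 == 0))
    stop("degenerate outline: all segments have zero length", call. = FALSE)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    t <- ((p[i, 1L] - ax) * dx + (p[i, 2L] - ay) * dy) / pmax(len2, .Machine$double.eps)
    t <- pmin(1, pmax(0, t))
    out[i] <- sqrt(min((p[i, 1L] - (ax + t * dx))^2 +
                       (p[i, 2L] - (ay + t * dy))^2))
  }
  out
}

#' Per-sample migration distances
#'
#' Computes the minimum distance of every nucleus from the reference curve
#' of the selected assay mode: the source outline for the 3D spheroid assay
#' (`"spheroid"`, d3D) or the interface for the 2D layer assays
#' (`"layer_vertical"` d2DV / `"layer_horizontal"` d2DH). Nuclei strictly
#' inside the excluded source region are omitted. The median uses linear
#' interpolation between order statistics (type-7 quantile).
#'
#' @param nuclei A [nucleus_set()].
#' @param geom A [source_geometry()].
#' @param mode One of `"spheroid"`, `"layer_vertical"`, `"layer_horizontal"`.
#' @return An object of class `distance_result` with elements `sample_id`,
#'   `distances` (um), `median` (um), `assay_mode`, `n_excluded`.
#' @export
sample_distances <- function(nuclei, geom,
                             mode = c("spheroid", "layer_vertical",
                                      "layer_horizontal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(geom, "source_geometry"))
  curve <- if (mode == "spheroid") {
    if (is.null(geom$outline))
      stop("spheroid mode requires a source outline", call. = FALSE)
    geom$outline
  } else geom$interface
  pts <- as.matrix(nuclei$points)
  inside <- .points_in_polygon(pts, geom$outline)
  kept <- pts[!inside, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no nuclei outside the excluded source region", call. = FALSE)
    res <- list(sample_id = nuclei$sample_id, distances = numeric(),
                median = NA_real_, assay_mode = mode,
                n_excluded = sum(inside))
    return(structure(res, class = "distance_result"))
  }
  d <- min_distance_to_outline(kept, curve)
  structure(list(sample_id = nuclei$sample_id, distances = d,
                 median = stats::median(d), assay_mode = mode,
                 n_excluded = sum(inside)),
            class = "distance_result")
}

# Which points fall strictly inside the (closed) polygon; NULL polygon ->
# none excluded.
.points_in_polygon <- function(pts, poly) {
  if (is.null(poly) || nrow(pts) == 0L)
    return(rep(FALSE, nrow(pts)))
  mgcv::in.out(poly, pts)
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> sample '%s' (%s): n = %d, median = %.1f um\n",
              x$sample_id, x$assay_mode, length(x$distances), x$median))
  invisible(x)
}

#' Cross-sample summary of median migration distances
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-sample
#' median migration distances within one biomaterial group.
#'
#' @param results List of `distance_result` objects (>= 1).
#' @param group Group (biomaterial) label.
#' @return An object of class `assay_summary` with `mean_of_medians`,
#'   `sd_of_medians` (0 for a single sample) and `n_samples`.
#' @export
summarize_group <- function(results, group = "") {
  if (inherits(results, "distance_result")) results <- list(results)
  if (length(results) < 1L) stop("need at least one result", call. = FALSE)
  med <- vapply(results, function(r) r$median, numeric(1))
  structure(list(group = group,
                 mean_of_medians = mean(med),
                 sd_of_medians = if (length(med) > 1L) stats::sd(med) else 0,
                 n_samples = length(med)),
            class = "assay_summary")
}

#' Anisotropy ratio R from paired 2D layer assays
#'
#' R = d2DV / d2DH, the ratio of the median migration distances measured in
#' the vertical and horizontal 2D layer assays. R > 1 indicates preferential
#' migration along the material's vertical (depth) direction.
#'
#' @param d2DV_median Median vertical migration distance, um.
#' @param d2DH_median Median horizontal migration distance, um (> 0).
#' @return The dimensionless ratio; `NA` when the denominator is zero.
#' @examples
#' compute_R(480, 196)  # ~2.4, strongly vertical
#' @export
compute_R <- function(d2DV_median, d2DH_median) {
  if (d2DH_median == 0) return(NA_real_)
  d2DV_median / d2DH_median
}
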