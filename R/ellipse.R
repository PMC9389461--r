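#' Direct least-squares ellipse fit of an isodensity profile
#'
#' Fits the algebraic conic k1 x^2 + k2 x y + k3 y^2 + k4 x + k5 y + k6 = 0
#' to the profile vertices by the direct least-squares method with the
#' ellipse constraint (numerically stable block formulation). Because an
#' isodensity profile is a half-arc above the interface, the points are
#' first mirrored across y = 0 (each (x, y) also contributes (x, -y)); this
#' conditions the fit and encodes the interface-symmetric, axis-aligned
#' geometry of the assay.
#'
#' @param points Two-column matrix/data.frame of profile vertices (um), or
#'   an `isodensity_profile`.
#' @param mirror Mirror across y = 0 before fitting (default TRUE).
#' @return An object of class `conic_coefficients`: numeric `k` of length 6
#'   with unit Euclidean norm, satisfying the ellipse discriminant
#'   k2^2 - 4 k1 k3 < 0.
#' @export
fit_conic <- function(points, mirror = TRUE) {
  if (inherits(points, "isodensity_profile")) points <- points$points
  p <- .as_xy(points, "points")
  if (mirror) p <- rbind(p, cbind(p[, 1L], -p[, 2L]))
  if (nrow(p) < 6L)
    stop("need at least 6 points (after mirroring) for a conic fit",
         call. = FALSE)
  x <- p[, 1L]; y <- p[, 2L]
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2L] <= 1e-10 * max(sv[1L], 1))
    stop("points are collinear; conic fit is degenerate", call. = FALSE)
  # center/scale for conditioning, fit, then map coefficients back
  mx <- mean(x); my <- mean(y)
  s <- max(stats::sd(x), stats::sd(y), .Machine$double.eps)
  u <- (x - mx) / s; v <- (y - my) / s
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("degenerate point configuration",
                                          call. = FALSE))
  M <- S1 + S2 %*% T3
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  cand <- Re(ev$vectors)
  cond <- 4 * cand[1L, ] * cand[3L, ] - cand[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    stop("no elliptical solution (hyperbola-only fit)", call. = FALSE)
  a1 <- cand[, ok[1L]]
  k_sc <- c(a1, as.vector(T3 %*% a1))
  # undo scaling: substitute u = (x - mx)/s, v = (y - my)/s
  k <- numeric(6)
  k[1] <- k_sc[1] / s^2
  k[2] <- k_sc[2] / s^2
  k[3] <- k_sc[3] / s^2
  k[4] <- -2 * k_sc[1] * mx / s^2 - k_sc[2] * my / s^2 + k_sc[4] / s
  k[5] <- -2 * k_sc[3] * my / s^2 - k_sc[2] * mx / s^2 + k_sc[5] / s
  k[6] <- k_sc[1] * mx^2 / s^2 + k_sc[2] * mx * my / s^2 +
    k_sc[3] * my^2 / s^2 - k_sc[4] * mx / s - k_sc[5] * my / s + k_sc[6]
  k <- k / sqrt(sum(k^2))
  structure(list(k = k), class = "conic_coefficients")
}

#' Semi-axes and center of a fitted conic
#'
#' Recovers the ellipse geometry from the algebraic coefficients via the
#' eigendecomposition of the quadratic form \[\[k1, k2/2\], \[k2/2, k3\]\]
#' (convention-independent, unlike closed-form transcriptions that assume
#' half-coefficients). The semi-axis whose direction lies closer to the
#' x-axis is labeled `a` (horizontal/lateral), the other `b`
#' (vertical/depth), matching the assay's direction conventions; `a` is not
#' forced to exceed `b`.
#'
#' @param conic A `conic_coefficients` object (or numeric k of length 6).
#' @return An object of class `fitted_ellipse`: `a`, `b` (um), `center`
#'   (um), `tilt` (degrees of the a-axis from horizontal, |tilt| <= 90).
#' @export
semi_axes <- function(conic) {
  k <- if (inherits(conic, "conic_coefficients")) conic$k else as.numeric(conic)
  stopifnot(length(k) == 6L)
  if (k[2]^2 - 4 * k[1] * k[3] >= 0)
    stop("coefficients do not describe an ellipse", call. = FALSE)
  M <- matrix(c(k[1], k[2] / 2, k[2] / 2, k[3]), 2L, 2L)
  center <- solve(2 * M, -c(k[4], k[5]))
  c0 <- drop(center %*% M %*% center) + sum(c(k[4], k[5]) * center) + k[6]
  ev <- eigen(M, symmetric = TRUE)
  len2 <- -c0 / ev$values
  if (any(len2 <= 0))
    stop("coefficients do not describe a real ellipse", call. = FALSE)
  axes <- sqrt(len2)
  dirs <- ev$vectors
  # axis closer to horizontal is 'a'
  horiz <- which.max(abs(dirs[1L, ]))
  vert <- 3L - horiz
  a_dir <- dirs[, horiz]
  tilt <- atan2(a_dir[2L], a_dir[1L]) * 180 / pi
  if (tilt > 90) tilt <- tilt - 180
  if (tilt < -90) tilt <- tilt + 180
  structure(list(a = axes[horiz], b = axes[vert], center = center,
                 tilt = tilt),
            class = "fitted_ellipse")
}

#' @export
print.fitted_ellipse <- function(x, ...) {
  cat(sprintf("<fitted_ellipse> a = %.1f um, b = %.1f um, center (%.1f, %.1f), tilt %.2f deg\n",
              x$a, x$b, x$center[1L], x$center[2L], x$tilt))
  invisible(x)
}

# Closed-form semi-axes under the half-coefficient conic convention
# A x^2 + 2 B x y + C y^2 + 2 D x + 2 F y + G = 0; cross-check for
# semi_axes() in the test suite.
.semi_axes_closed_form <- function(k) {
  A <- k[1]; B <- k[2] / 2; C <- k[3]; D <- k[4] / 2; F <- k[5] / 2; G <- k[6]
  num <- 2 * (A * F^2 + C * D^2 + G * B^2 - 2 * B * D * F - A * C * G)
  den1 <- (B^2 - A * C) * ( sqrt((A - C)^2 + 4 * B^2) - (A + C))
  den2 <- (B^2 - A * C) * (-sqrt((A - C)^2 + 4 * B^2) - (A + C))
  sort(c(sqrt(num / den1), sqrt(num / den2)), decreasing = TRUE)
}

#' Fit an ellipse to a profile in one step
#'
#' Convenience composition of [fit_conic()] and [semi_axes()].
#'
#' @inheritParams fit_conic
#' @return A `fitted_ellipse`.
#' @export
fit_ellipse <- function(points, mirror = TRUE) semi_axes(fit_conic(points, mirror))

#' Average fitted ellipses across samples
#'
#' Arithmetic mean and sample SD of the semi-axes a and b over per-sample
#' fits of one threshold; the mean ellipse is axis-aligned at the origin.
#'
#' @param fits List of `fitted_ellipse` objects (>= 1).
#' @return List with `a`, `sd_a`, `b`, `sd_b`, `n`.
#' @export
average_ellipses <- function(fits) {
  if (inherits(fits, "fitted_ellipse")) fits <- list(fits)
  if (length(fits) < 1L) stop("need at least one fit", call. = FALSE)
  a <- vapply(fits, function(f) f$a, numeric(1))
  b <- vapply(fits, function(f) f$b, numeric(1))
  list(a = mean(a), sd_a = if (length(a) > 1) stats::sd(a) else 0,
       b = mean(b), sd_b = if (length(b) > 1) stats::sd(b) else 0,
       n = length(fits))
}

#' Calibrate the spheroid radius P on a reference material
#'
#' For each reference threshold i, P_i = a_i - b_i / R_ref is the lateral
#' offset that makes the corrected ratio b_i / (a_i - P_i) equal the
#' reference anisotropy R_ref measured in the 2D layer assays. P is the mean
#' of the per-threshold P_i.
#'
#' @param a,b Numeric vectors of reference semi-axes (um), one entry per
#'   threshold (typically 5/10/15%).
#' @param reference_R Reference anisotropy ratio (> 0) from [compute_R()].
#' @return List with `P` (mean, um) and `P_i` (per threshold).
#' @examples
#' calibrate_P(a = 1167, b = 939, reference_R = 2.4)  # single threshold
#' @export
calibrate_P <- function(a, b, reference_R) {
  stopifnot(length(a) == length(b), reference_R > 0, all(a > 0), all(b > 0))
  P_i <- a - b / reference_R
  if (any(P_i <= 0))
    warning("non-positive per-threshold P_i; calibration is unreliable",
            call. = FALSE)
  list(P = mean(P_i), P_i = P_i)
}

#' Corrected anisotropy ratio R*
#'
#' R* = b / (a - P): the depth semi-axis over the spheroid-radius-corrected
#' lateral semi-axis, comparable to the 2D layer ratio R for a point-like
#' source. Undefined (NA) when a' = a - P <= 0, i.e. when the profile's
#' lateral extent does not exceed the cell-source radius.
#'
#' @param a Lateral (horizontal) semi-axis, um.
#' @param b Depth (vertical) semi-axis, um.
#' @param P Spheroid radius, um (default 745).
#' @return Dimensionless ratio, or `NA_real_` when undefined.
#' @examples
#' compute_R_star(1134, 701, 745)  # ~1.8
#' @export
compute_R_star <- function(a, b, P = 745) {
  stopifnot(a > 0, b > 0, P >= 0)
  a_prime <- a - P
  if (a_prime <= 0) return(NA_real_)
  b / a_prime
}

#' Anisotropy summary across thresholds
#'
#' Combines per-sample ellipse fits of each threshold into the mean/SD
#' semi-axes and the corrected ratio R* (for the thresholds listed in
#' `config$anisotropy_thresholds`; the 50% profile is excluded by default).
#'
#' @param fits_by_threshold Named list (threshold label ->) of lists of
#'   `fitted_ellipse` objects.
#' @param P Spheroid radius in um.
#' @param config An [analysis_config()].
#' @param reference_R Optional reference R recorded alongside.
#' @return An object of class `anisotropy_summary`.
#' @export
anisotropy_summary <- function(fits_by_threshold, P = 745,
                               config = analysis_config(),
                               reference_R = NA_real_) {
  per <- lapply(names(fits_by_threshold), function(lab) {
    avg <- average_ellipses(fits_by_threshold[[lab]])
    in_rstar <- lab %in% config$anisotropy_thresholds
    a_prime <- avg$a - P
    list(label = lab, a = avg$a, sd_a = avg$sd_a, b = avg$b, sd_b = avg$sd_b,
         n = avg$n, a_prime = a_prime,
         R_star = if (in_rstar) compute_R_star(avg$a, avg$b, P) else NA_real_)
  })
  names(per) <- names(fits_by_threshold)
  structure(list(per_threshold = per, P = P, reference_R = reference_R),
            class = "anisotropy_summary")
}

#' @export
print.anisotropy_summary <- function(x, ...) {
  cat(sprintf("<anisotropy_summary> P = %.0f um\n", x$P))
  for (row in x$per_threshold)
    cat(sprintf("  %-4s a = %7.1f +/- %5.1f um  b = %7.1f +/- %5.1f um  R* = %s\n",
                row$label, row$a, row$sd_a, row$b, row$sd_b,
                if (is.na(row$R_star)) "--" else sprintf("%.1f", row$R_star)))
  invisible(x)
}
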