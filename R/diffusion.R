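#' Migration speed from distance and time
#'
#' Converts an average migration distance over an observation time into a
#' constant speed in mm/s. This speed is used numerically as the higher
#' diffusion coefficient of the reference simulation (a modeling
#' convention: the mm/s value is reused as mm2/s).
#'
#' @param distance_um Migration distance in um.
#' @param duration_s Observation time in s (> 0).
#' @return Speed in mm/s.
#' @examples
#' derive_speed(500, 432000)  # 5 days -> ~1.16e-6 mm/s
#' @export
derive_speed <- function(distance_um, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0", call. = FALSE)
  (distance_um * 1e-3) / duration_s
}

#' Configuration of the anisotropic-diffusion reference simulation
#'
#' Defaults reproduce the reference setup: a 5 x 5 mm square discretized
#' into 50 x 50 cells (2,601 nodes), a centered line source spanning the
#' surface nodes of 18 edge elements held at 100% concentration, zero-flux
#' boundaries elsewhere, and a single diffusion step of 432,000 s (5 days).
#' The higher coefficient HD = 1.16e-6 mm2/s is the derived migration speed
#' (see [derive_speed()]); the lower is HD / 2. Regimes: `"2:1"` (vertical
#' HD, horizontal LD), `"1:1"` (LD, LD), `"1:2"` (LD vertical, HD
#' horizontal).
#'
#' @param domain_mm Side length of the square domain, mm.
#' @param n_cells Grid cells per side (nodes per side = n_cells + 1).
#' @param source_elements Number of edge elements forming the line source.
#' @param source_concentration Source concentration, %.
#' @param D_vertical,D_horizontal Diffusion coefficients, mm2/s.
#' @param duration_s Simulated time, s.
#' @param time_step Optional explicit time step, s; solver-chosen (and
#'   stability-bounded) when `NULL`.
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(domain_mm = 5, n_cells = 50L,
                             source_elements = 18L,
                             source_concentration = 100,
                             D_vertical = 1.16e-6,
                             D_horizontal = 1.16e-6 / 2,
                             duration_s = 432000,
                             time_step = NULL) {
  stopifnot(domain_mm > 0, n_cells >= 2L, source_elements >= 1L,
            source_elements <= n_cells, D_vertical > 0, D_horizontal > 0,
            duration_s > 0)
  structure(list(domain_mm = domain_mm, n_cells = as.integer(n_cells),
                 source_elements = as.integer(source_elements),
                 source_concentration = source_concentration,
                 D_vertical = D_vertical, D_horizontal = D_horizontal,
                 duration_s = duration_s, time_step = time_step),
            class = "diffusion_config")
}

#' Preset diffusion regimes
#'
#' @param regime One of `"2:1"`, `"1:1"`, `"1:2"` (vertical:horizontal
#'   coefficient ratio).
#' @param HD Higher diffusion coefficient, mm2/s.
#' @param ... Passed to [diffusion_config()].
#' @return A `diffusion_config`.
#' @export
diffusion_regime <- function(regime = c("2:1", "1:1", "1:2"),
                             HD = 1.16e-6, ...) {
  regime <- match.arg(regime)
  LD <- HD / 2
  D <- switch(regime,
              "2:1" = c(HD, LD),
              "1:1" = c(LD, LD),
              "1:2" = c(LD, HD))
  diffusion_config(D_vertical = D[1L], D_horizontal = D[2L], ...)
}

#' Solve the anisotropic diffusion problem
#'
#' Integrates dc/dt = D_h d2c/dx2 + D_v d2c/dy2 on the square domain by
#' explicit finite differences (FTCS). The line source (Dirichlet,
#' `source_concentration`) occupies the centered nodes of the y = 0 edge;
#' all other boundaries are zero-flux. The initial concentration is zero off
#' the source. x is lateral, y is depth away from the source edge.
#'
#' @param config A [diffusion_config()].
#' @return An object of class `diffusion_field`: `conc` matrix (rows = x
#'   index, cols = y index, %), `x_mm`, `y_mm` node coordinates,
#'   `source_center_x`, `source_half_length_mm`, `config`.
#' @export
solve_diffusion <- function(config = diffusion_config()) {
  stopifnot(inherits(config, "diffusion_config"))
  n <- config$n_cells
  h <- config$domain_mm / n
  nn <- n + 1L
  Dv <- config$D_vertical; Dh <- config$D_horizontal
  dt_max <- h^2 / (2 * (Dv + Dh))
  if (is.null(config$time_step)) {
    nsteps <- ceiling(config$duration_s / (0.9 * dt_max))
    dt <- config$duration_s / nsteps
  } else {
    dt <- config$time_step
    if (dt > dt_max)
      stop(sprintf("explicit time step %.3g s exceeds the stability bound %.3g s",
                   dt, dt_max), call. = FALSE)
    nsteps <- ceiling(config$duration_s / dt)
    dt <- config$duration_s / nsteps
  }
  # source: surface nodes of `source_elements` centered edge elements
  first_el <- floor((n - config$source_elements) / 2)
  src <- (first_el + 1L):(first_el + config$source_elements + 1L)
  c0 <- matrix(0, nn, nn)            # conc[x index, y index]
  c0[src, 1L] <- config$source_concentration
  rx <- Dh * dt / h^2
  ry <- Dv * dt / h^2
  cc <- c0
  for (s in seq_len(nsteps)) {
    # reflecting (zero-flux) ghost values via edge duplication
    cW <- cc[c(1L, seq_len(nn - 1L)), ]
    cE <- cc[c(seq_len(nn - 1L) + 1L, nn), ]
    cS <- cc[, c(1L, seq_len(nn - 1L))]
    cN <- cc[, c(seq_len(nn - 1L) + 1L, nn)]
    cc <- cc + rx * (cE - 2 * cc + cW) + ry * (cN - 2 * cc + cS)
    cc[src, 1L] <- config$source_concentration
  }
  x_mm <- seq(0, config$domain_mm, length.out = nn)
  structure(list(conc = cc, x_mm = x_mm, y_mm = x_mm,
                 source_center_x = mean(x_mm[range(src)]),
                 source_half_length_mm = (config$source_elements / 2) * h,
                 config = config),
            class = "diffusion_field")
}

#' Extract iso-concentration contours
#'
#' Marching-squares contours (linear interpolation) of the final
#' concentration field; for each level, the longest connected contour is
#' returned.
#'
#' @param field A [solve_diffusion()] result.
#' @param levels Concentration levels in % (each within (0, 100)).
#' @return Named list (one element per level) of data.frames `x_mm`, `y_mm`;
#'   an empty data.frame (with a warning) for levels outside the field
#'   range.
#' @export
extract_contours <- function(field, levels = c(5, 10, 15, 50)) {
  stopifnot(inherits(field, "diffusion_field"), all(levels > 0 & levels < 100))
  out <- lapply(levels, function(lev) {
    if (lev >= max(field$conc) || lev <= min(field$conc)) {
      warning("level ", lev, "% outside the field range; empty contour",
              call. = FALSE)
      return(data.frame(x_mm = numeric(), y_mm = numeric()))
    }
    cl <- grDevices::contourLines(field$x_mm, field$y_mm, field$conc,
                                  levels = lev)
    if (length(cl) == 0L)
      return(data.frame(x_mm = numeric(), y_mm = numeric()))
    len <- vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)),
                  numeric(1))
    best <- cl[[which.max(len)]]
    data.frame(x_mm = best$x, y_mm = best$y)
  })
  names(out) <- paste0(levels, "%")
  out
}

#' Depth and lateral extents of a contour
#'
#' Returns the depth extent (max y) and lateral half-extent (max |x -
#' source_center_x|) of an iso-concentration contour, in mm. Feeding these
#' into [calibrate_P()] with `reference_R = 1` on the isotropic regime
#' yields the effective source half-length that makes [contour_anisotropy()]
#' of the isotropic field equal 1 -- the simulation-side analogue of
#' calibrating the spheroid radius P on a reference biomaterial.
#'
#' @param contour Data.frame `x_mm`, `y_mm` from [extract_contours()].
#' @param source_center_x Lateral source center in mm.
#' @return Named numeric: `depth`, `lateral` (mm).
#' @export
contour_extents <- function(contour, source_center_x = 2.5) {
  if (nrow(contour) == 0L) stop("empty contour", call. = FALSE)
  c(depth = max(contour$y_mm),
    lateral = max(abs(contour$x_mm - source_center_x)))
}

#' Anisotropy ratio of an iso-concentration contour
#'
#' Depth extent of the contour divided by its lateral half-extent minus the
#' source half-length -- the simulation-side analogue of the corrected
#' ratio R*, so simulated and experimental profiles are directly
#' comparable.
#'
#' @param contour Data.frame `x_mm`, `y_mm` from [extract_contours()].
#' @param source_half_length Source half-length in mm.
#' @param source_center_x Lateral source center in mm.
#' @return Dimensionless ratio; `NA` when the lateral half-extent does not
#'   exceed the source half-length.
#' @export
contour_anisotropy <- function(contour, source_half_length,
                               source_center_x = 2.5) {
  if (nrow(contour) == 0L) stop("empty contour", call. = FALSE)
  depth <- max(contour$y_mm)
  lateral <- max(abs(contour$x_mm - source_center_x))
  a_prime <- lateral - source_half_length
  if (a_prime <= 0) return(NA_real_)
  depth / a_prime
}
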