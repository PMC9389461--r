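#' Analyze one sample end to end
#'
#' Chains the per-sample stages of the spheroid-assay analysis: frame
#' registration, density grid, isodensity profiles, lateral origin
#' centering, and ellipse fits, returning everything downstream summaries
#' need.
#'
#' @param nuclei A [nucleus_set()].
#' @param geom A [source_geometry()].
#' @param config An [analysis_config()].
#' @return List with `registered` (from [register_frame()]), `grid`,
#'   `profiles` (origin-centered), `x0` (lateral offset, um), `fits` (named
#'   list of `fitted_ellipse` per threshold label), and `distances`
#'   (spheroid-mode `distance_result` when an outline is present).
#' @export
analyze_sample <- function(nuclei, geom, config = analysis_config()) {
  reg <- register_frame(nuclei, geom, config$roi_diameter)
  grid <- build_density_grid(reg$nuclei, config,
                             exclude = reg$geometry$outline)
  profiles <- extract_profiles(grid, config)
  centered <- center_origin(profiles,
                            labels = intersect(config$anisotropy_thresholds,
                                               names(profiles)))
  fits <- lapply(centered$profiles, function(p)
    tryCatch(fit_ellipse(p$points), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  dist <- if (!is.null(geom$outline))
    sample_distances(nuclei, geom, "spheroid") else NULL
  list(registered = reg, grid = grid, profiles = centered$profiles,
       x0 = centered$x0, fits = fits, distances = dist)
}

#' Corrected anisotropy ratio of one sample
#'
#' Convenience wrapper: runs [analyze_sample()] and returns R* of the
#' requested threshold.
#'
#' @inheritParams analyze_sample
#' @param threshold_label Profile used (default `"5%"`).
#' @param P Spheroid radius in um; defaults to `config$p_reference`.
#' @return R* (dimensionless), or `NA` when undefined or the profile is
#'   missing.
#' @export
sample_R_star <- function(nuclei, geom, config = analysis_config(),
                          threshold_label = "5%", P = config$p_reference) {
  res <- analyze_sample(nuclei, geom, config)
  fit <- res$fits[[threshold_label]]
  if (is.null(fit)) return(NA_real_)
  compute_R_star(fit$a, fit$b, P)
}

#' Run the full pipeline on files
#'
#' Reads inputs, runs every stage (distances, density grid, profiles,
#' ellipse anisotropy, interface band density) per sample, writes all
#' products plus a run manifest into `out_dir`, and returns the manifest.
#' Stage failures abort with the stage name; outputs of completed stages are
#' retained.
#'
#' @param points_path CSV of nucleus centroids (see [read_points()]).
#' @param geometry_path CSV of the source geometry (see [read_geometry()]).
#' @param out_dir Output directory (created if missing).
#' @param config_path Optional JSON config (see [read_config()]).
#' @param P Spheroid radius for R*; defaults to the config value.
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(points_path, geometry_path, out_dir,
                         config_path = NULL, P = NULL) {
  config <- if (is.null(config_path)) analysis_config() else
    read_config(config_path)
  if (is.null(P)) P <- config$p_reference
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- function(p) unname(tools::md5sum(p))
  manifest <- list(tool = "spheromigrate",
                   version = as.character(utils::packageVersion("spheromigrate")),
                   inputs = list(points = list(path = points_path,
                                               md5 = digest(points_path)),
                                 geometry = list(path = geometry_path,
                                                 md5 = digest(geometry_path))),
                   config = unclass(config), P_um = P, stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- "completed"
    res
  }
  samples <- stage("read", function() read_points(points_path))
  geom <- stage("geometry", function() read_geometry(geometry_path))
  dist_results <- stage("distances", function() {
    lapply(samples, function(ns) {
      r <- sample_distances(ns, geom,
                            if (is.null(geom$outline)) "layer_vertical"
                            else "spheroid")
      write_results(r, file.path(out_dir,
                                 sprintf("distances_%s.csv", ns$sample_id)))
      r
    })
  })
  analyses <- stage("profiles", function() {
    lapply(samples, function(ns) {
      a <- analyze_sample(ns, geom, config)
      write_results(a$grid, file.path(out_dir,
                                      sprintf("grid_%s.csv", ns$sample_id)))
      for (p in a$profiles)
        write_results(p, file.path(out_dir,
                                   sprintf("profile_%s_%s.csv", ns$sample_id,
                                           gsub("%", "pct", p$threshold_label))))
      a
    })
  })
  summary <- stage("anisotropy", function() {
    labs <- unique(unlist(lapply(analyses, function(a) names(a$fits))))
    fits_by_thr <- lapply(labs, function(lab)
      Filter(Negate(is.null), lapply(analyses, function(a) a$fits[[lab]])))
    names(fits_by_thr) <- labs
    fits_by_thr <- Filter(function(f) length(f) > 0, fits_by_thr)
    s <- anisotropy_summary(fits_by_thr, P = P, config = config)
    write_results(s, file.path(out_dir, "anisotropy.json"))
    s
  })
  stage("band_density", function() {
    for (a in analyses) {
      ns <- a$registered$nuclei
      xr <- if (!is.na(geom$contact_length))
        c(-geom$contact_length / 2, geom$contact_length / 2)
      else range(ns$points$x)
      b <- band_density(ns, config$band_height, xr)
      .write_json(list(sample_id = b$sample_id, band_height_um = b$band_height,
                       band_length_um = b$band_length, count = b$count,
                       density_cells_per_mm2 = b$density),
                  file.path(out_dir, sprintf("band_%s.json", ns$sample_id)))
    }
    invisible(NULL)
  })
  manifest$summary <- list(
    median_distances_um = vapply(dist_results, function(r) r$median, numeric(1)),
    R_star = vapply(summary$per_threshold, function(r) r$R_star, numeric(1)))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
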