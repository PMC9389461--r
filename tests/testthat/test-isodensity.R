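test_that("register_frame is the identity for an interface already on y = 0", {
  ns <- nucleus_set("s", x = c(10, 50), y = c(100, 300))
  reg <- register_frame(ns, std_geometry())
  expect_equal(reg$nuclei$points, ns$points, tolerance = 1e-12)
  expect_equal(max(abs(reg$geometry$interface[, 2])), 0, tolerance = 1e-12)
})

test_that("registration of a rotated interface yields signed point-line depth", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  iface0 <- cbind(seq(-1000, 1000, length.out = 9), 0)
  set.seed(4)
  pts0 <- cbind(runif(50, -800, 800), runif(50, 0, 900))
  out0 <- semicircle_outline(200)
  ns <- {
    p <- pts0 %*% t(R)
    nucleus_set("s", p[, 1] + 55, p[, 2] - 77)
  }
  geom <- source_geometry(outline = sweep(out0 %*% t(R), 2, c(-55, 77)),
                          interface = sweep(iface0 %*% t(R), 2, c(-55, 77)))
  reg <- register_frame(ns, geom)
  # oracle: analytic signed distance to the rotated-translated line
  n_vec <- R %*% c(0, 1)
  depth <- as.vector((as.matrix(ns$points) -
                       matrix(c(55, -77), 50, 2, byrow = TRUE)) %*% n_vec)
  expect_equal(sort(reg$nuclei$points$y), sort(depth), tolerance = 1e-9)
  expect_equal(max(abs(reg$geometry$interface[, 2])), 0, tolerance = 1e-9)
  # material side is positive, outline side negative
  expect_lt(mean(reg$geometry$outline[, 2]), 0)
})

test_that("curved interfaces warn but still register; short interfaces error", {
  xs <- seq(-500, 500, length.out = 21)
  curved <- cbind(xs, 500 * (1 - (xs / 500)^2))   # sagitta 500 um
  ns <- nucleus_set("s", x = 0, y = 500)
  expect_warning(register_frame(ns, source_geometry(interface = curved)),
                 "approximate")
  short <- source_geometry(interface = cbind(c(0, 50), c(0, 0)))
  expect_error(register_frame(ns, short), "shorter")
})

test_that("ROI densities follow count / area and overlap duplicates nuclei", {
  cfg <- analysis_config()
  # 10 nuclei packed near one ROI center (first row center x=0, y=100)
  ns <- nucleus_set("s", x = rnorm(10, 0, 5), y = rnorm(10, 100, 5))
  set.seed(1)
  grid <- build_density_grid(ns, cfg,
                             extent = list(x_min = 0, x_max = 0, y_max = 100))
  roi1 <- grid$rois[grid$rois$col_index == 1 & grid$rois$row_index == 1, ]
  expect_equal(roi1$count, 10)
  expect_equal(roi1$density, 10 / (pi * 100^2 * 1e-6), tolerance = 1e-12)
  expect_equal(roi1$density, 318.3099, tolerance = 1e-4)

  # a nucleus equidistant from two adjacent centers counts in both
  ns2 <- nucleus_set("s", x = 50, y = 100)
  g2 <- build_density_grid(ns2, cfg,
                           extent = list(x_min = 0, x_max = 100, y_max = 100))
  counts <- g2$rois$count[g2$rois$row_index == 1 & g2$rois$col_index %in% c(1, 2)]
  expect_equal(counts, c(1, 1))
})

test_that("per-ROI counts equal brute-force distance filtering", {
  set.seed(17)
  ns <- nucleus_set("s", x = runif(500, -1000, 1000), y = runif(500, 0, 800))
  cfg <- analysis_config()
  grid <- build_density_grid(ns, cfg)
  pts <- as.matrix(ns$points)
  for (k in sample(nrow(grid$rois), 40)) {
    cx <- grid$rois$x[k]; cy <- grid$rois$y[k]
    oracle <- sum((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= 100^2 + 1e-9)
    expect_equal(grid$rois$count[k], oracle)
  }
})

test_that("doubling every nucleus doubles every ROI density exactly", {
  set.seed(23)
  x <- runif(200, -500, 500); y <- runif(200, 0, 500)
  cfg <- analysis_config()
  ext <- list(x_min = -500, x_max = 500, y_max = 500)
  g1 <- build_density_grid(nucleus_set("s", x, y), cfg, extent = ext)
  g2 <- build_density_grid(nucleus_set("s", c(x, x), c(y, y)), cfg,
                           extent = ext)
  expect_equal(g2$rois$density, 2 * g1$rois$density)
})

test_that("threshold-ROI rule matches the worked columns and exhaustive enumeration", {
  expect_equal(select_threshold_roi_column(c(600, 300, 120, 80, 40, 20), 95), 3)
  expect_equal(select_threshold_roi_column(c(600, 80, 120, 40, 20), 95), 3)
  expect_equal(select_threshold_roi_column(c(600, 120, 100, 98, 40, 20), 95), 4)
  expect_true(is.na(select_threshold_roi_column(c(10, 20, 30), 95)))
  # deepest ROI selectable when the grid ends (virtual ROIs count as 0)
  expect_equal(select_threshold_roi_column(c(600, 300, 120), 95), 3)

  set.seed(31)
  for (i in 1:300) {
    col <- round(runif(sample(1:12, 1), 0, 700))
    thr <- runif(1, 10, 500)
    expect_equal(select_threshold_roi_column(col, thr),
                 enumerate_threshold_roi(col, thr),
                 info = paste("column", paste(col, collapse = ","), "thr", thr))
  }
})

test_that("profile points sit on the deepest point of the threshold ROI perimeter", {
  set.seed(12)
  ns <- nucleus_set("s", x = runif(3000, -800, 800),
                    y = abs(rnorm(3000, 0, 300)))
  cfg <- analysis_config()
  grid <- build_density_grid(ns, cfg)
  sel <- select_threshold_rois(grid, 95)
  prof <- extract_profile(grid, sel, 95, "10%")
  expect_true(all(diff(prof$points$x) > 0))
  expect_true(all(prof$points$y >= 0))
  has <- which(!is.na(sel))
  # angular-sampling oracle: deepest of 360 sampled perimeter points
  th <- seq(0, 2 * pi, length.out = 360)
  for (j in sample(has, min(10, length(has)))) {
    cx <- grid$x_cols[j]; cy <- grid$y_rows[sel[j]]
    oracle_y <- max(cy + 100 * sin(th))
    row <- which(prof$points$x == cx)
    expect_equal(prof$points$y[row], oracle_y, tolerance = 1e-3)
  }
  expect_error(extract_profile(grid, rep(NA_integer_, length(grid$x_cols)),
                               95, "10%"), "sparse")
})

test_that("center_origin halves the underlying area", {
  mkprof <- function(x, y, lab = "5%") {
    structure(list(points = data.frame(x = x, y = y), threshold_label = lab,
                   threshold_value = 50, selected = NULL),
              class = "isodensity_profile")
  }
  # symmetric triangle on [-a, a]: split at 0
  tri <- mkprof(c(-300, 0, 300), c(0, 400, 0))
  res <- center_origin(list("5%" = tri, "10%" = tri, "15%" = tri))
  expect_equal(res$x0, 0, tolerance = 1e-9)

  # rectangle on [0, 10]: split at 5
  rect <- mkprof(c(0, 10), c(1, 1))
  res2 <- center_origin(list("5%" = rect, "10%" = rect, "15%" = rect))
  expect_equal(res2$x0, 5, tolerance = 1e-9)
  expect_equal(res2$profiles[["5%"]]$points$x, c(-5, 5))

  # random piecewise profile vs fine-grid numeric integration
  set.seed(19)
  x <- sort(runif(12, -500, 500)); y <- runif(12, 50, 400)
  p <- mkprof(x, y)
  res3 <- center_origin(list("5%" = p, "10%" = p, "15%" = p))
  xs <- seq(min(x), max(x), length.out = 2e5)
  ys <- approx(x, y, xs)$y
  cum <- cumsum(ys) * diff(xs[1:2])
  oracle <- xs[which.min(abs(cum - cum[length(cum)] / 2))]
  expect_equal(res3$x0, oracle, tolerance = 1e-2)

  flatzero <- mkprof(c(0, 10), c(0, 0))
  expect_error(center_origin(list("5%" = flatzero, "10%" = flatzero,
                                  "15%" = flatzero)), "zero")
})

test_that("profile areas shrink with increasing threshold on decaying fields", {
  set.seed(41)
  g <- generate_points(synth_spec(n_cells = 4000, anisotropy_true = 1,
                                  seed = 41))
  cfg <- analysis_config()
  grid <- build_density_grid(g$nuclei, cfg, exclude = g$geometry$outline)
  profs <- extract_profiles(grid, cfg)
  area <- function(p) {
    x <- p$points$x; y <- p$points$y
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  a <- vapply(profs[c("5%", "10%", "15%")], area, numeric(1))
  expect_true(all(diff(a) < 0))   # 5% largest, 15% smallest
})

test_that("profiles shift with a whole-sample translation by the grid spacing", {
  set.seed(43)
  x <- runif(2000, -600, 600); y <- abs(rnorm(2000, 0, 250))
  cfg <- analysis_config()
  g1 <- build_density_grid(nucleus_set("s", x, y), cfg)
  g2 <- build_density_grid(nucleus_set("s", x + 300, y), cfg)
  p1 <- extract_profile(g1, select_threshold_rois(g1, 95), 95)
  p2 <- extract_profile(g2, select_threshold_rois(g2, 95), 95)
  expect_equal(p2$points$x - 300, p1$points$x, tolerance = 1e-9)
  expect_equal(p2$points$y, p1$points$y, tolerance = 1e-9)
})
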