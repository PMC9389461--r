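test_that("read_points parses per-sample centroid tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,x_um,y_um",
               "s1,10.0,20.0", "s1,11.5,21.5", "s1,12.0,100.0",
               "s2,0,0"), f)
  sets <- read_points(f)
  expect_named(sets, c("s1", "s2"))
  expect_equal(nrow(sets$s1$points), 3)
  expect_equal(sets$s1$points$x, c(10, 11.5, 12))
  expect_equal(nrow(sets$s2$points), 1)
})

test_that("read_points handles empty tables and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,x_um,y_um", f)
  sets <- read_points(f)
  expect_length(sets, 0)

  writeLines(c("sample_id,x_um,y_um", "s1,1.0,2.0", "s1,10.0,abc"), f)
  expect_error(read_points(f), "row 2")

  writeLines(c("sample_id,x_um", "s1,1.0"), f)
  expect_error(read_points(f), "y_um")
})

test_that("read_geometry validates roles and polygon geometry", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("role,vertex_index,x_um,y_um",
               "outline,1,-100,0", "outline,2,100,0",
               "outline,3,100,-200", "outline,4,-100,-200",
               "interface,1,-500,0", "interface,2,500,0"), f)
  g <- read_geometry(f)
  expect_s3_class(g, "source_geometry")
  expect_equal(nrow(g$outline), 5)   # closed automatically
  expect_equal(g$outline[1, ], g$outline[5, ], ignore_attr = TRUE)
  expect_equal(nrow(g$interface), 2)

  writeLines(c("role,vertex_index,x_um,y_um",
               "outline,1,0,0", "outline,2,10,0",
               "interface,1,-500,0", "interface,2,500,0"), f)
  expect_error(read_geometry(f), "3 vertices")
})

test_that("self-intersecting outlines are rejected, agreeing with a segment oracle", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(source_geometry(outline = bowtie,
                               interface = flat_interface()),
               "self-intersecting")
  # oracle: solve each pair of segments parametrically
  seg_cross <- function(p1, p2, q1, q2) {
    A <- cbind(p2 - p1, q1 - q2)
    if (abs(det(A)) < 1e-12) return(FALSE)
    st <- solve(A, q1 - p1)
    all(st > 1e-9 & st < 1 - 1e-9)
  }
  set.seed(42)
  for (trial in 1:50) {
    quad <- matrix(runif(8, -10, 10), 4, 2)
    closed <- rbind(quad, quad[1, ])
    oracle <- FALSE
    for (i in 1:3) for (j in (i + 1):4) {
      if (j - i == 1 || (i == 1 && j == 4)) next
      if (seg_cross(closed[i, ], closed[i + 1, ], closed[j, ], closed[j + 1, ]))
        oracle <- TRUE
    }
    got <- tryCatch({source_geometry(outline = quad,
                                     interface = flat_interface()); FALSE},
                    error = function(e) TRUE)
    expect_equal(got, oracle, info = sprintf("trial %d", trial))
  }
})

test_that("non-finite coordinates are rejected everywhere", {
  expect_error(nucleus_set("s", c(1, NaN), c(1, 2)), "finite")
  expect_error(nucleus_set("s", c(1, Inf), c(1, 2)), "finite")
  expect_error(source_geometry(interface = cbind(c(0, NA), c(0, 0))), "finite")
  expect_error(projection_image(matrix(c(1, NA), 1), 1), "finite")
})

test_that("write/read round-trips are lossless", {
  d <- withr::local_tempdir()
  ns <- nucleus_set("s1", x = c(0.123456789012, 1e3 / 3), y = c(pi, 745.0001))
  p <- file.path(d, "pts.csv")
  write_results(ns, p)
  back <- read_points(p)$s1
  expect_equal(back$points$x, ns$points$x, tolerance = 1e-9)
  expect_equal(back$points$y, ns$points$y, tolerance = 1e-9)

  fit <- structure(list(a = 1134.5678, b = 701.1234, center = c(0.1, 0.2),
                        tilt = 0), class = "fitted_ellipse")
  j <- file.path(d, "fit.json")
  write_results(fit, j)
  vals <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(vals$a_um, fit$a, tolerance = 1e-9)
  expect_equal(vals$b_um, fit$b, tolerance = 1e-9)
})

test_that("anisotropy summaries serialize semi-axes and R* per threshold", {
  d <- withr::local_tempdir()
  fits <- list("5%" = list(structure(list(a = 1134, b = 701, center = c(0, 0),
                                          tilt = 0), class = "fitted_ellipse")))
  s <- anisotropy_summary(fits, P = 745)
  j <- file.path(d, "aniso.json")
  write_results(s, j)
  vals <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(vals$thresholds[["5%"]]$a_um, 1134)
  expect_equal(vals$thresholds[["5%"]]$b_um, 701)
  expect_equal(round(vals$thresholds[["5%"]]$R_star, 1), 1.8)
})

test_that("config validation enforces invariants", {
  expect_error(analysis_config(roi_diameter = 0), "roi_diameter")
  expect_error(analysis_config(roi_overlap_fraction = 1), "overlap")
  expect_error(analysis_config(density_thresholds = c(95, 50),
                               threshold_labels = c("a", "b")), "increasing")
  expect_error(analysis_config(band_height = -1), "band_height")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"roi_diameter": 100, "p_reference": 600}', f)
  cfg <- read_config(f)
  expect_equal(cfg$roi_diameter, 100)
  expect_equal(cfg$p_reference, 600)
  expect_equal(cfg$reference_density, 950)
  writeLines('{"not_a_key": 1}', f)
  expect_error(read_config(f), "unknown config key")
})
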