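test_that("fit_conic recovers closed-form conics", {
  # x^2/4 + y^2 = 1  <->  (1, 0, 4, 0, 0, -4)
  pts <- half_ellipse_points(2, 1, m = 8)
  k <- fit_conic(pts)$k
  expect_equal(abs(sum(k^2)), 1, tolerance = 1e-12)
  want <- c(1, 0, 4, 0, 0, -4); want <- want / sqrt(sum(want^2))
  expect_equal(abs(sum(k * want)), 1, tolerance = 1e-9)

  # unit circle: k1 = k3, k2 = 0
  circ <- half_ellipse_points(1, 1, m = 6)
  kc <- fit_conic(circ)$k
  expect_equal(kc[1], kc[3], tolerance = 1e-9)
  expect_equal(kc[2], 0, tolerance = 1e-9)

  # 200 noiseless points on a random centered-on-y=0 ellipse
  set.seed(7)
  cx <- runif(1, -2, 2)
  pts2 <- half_ellipse_points(3, 1.5, cx = cx, m = 200)
  fit <- fit_ellipse(pts2)
  expect_equal(fit$a, 3, tolerance = 1e-6)
  expect_equal(fit$b, 1.5, tolerance = 1e-6)
  expect_equal(fit$center[1], cx, tolerance = 1e-6)
  expect_equal(fit$center[2], 0, tolerance = 1e-6)

  expect_error(fit_conic(cbind(1:10, 0 * (1:10))), "collinear")
})

test_that("semi_axes recovers axes from the quadratic form", {
  expect_equal(semi_axes(c(1, 0, 1, 0, 0, -1))$a, 1)
  e <- semi_axes(c(1, 0, 4, 0, 0, -4))
  expect_equal(e$a, 2)
  expect_equal(e$b, 1)
  expect_equal(e$center, c(0, 0))
  expect_error(semi_axes(c(1, 0, -1, 0, 0, -1)), "ellipse")

  set.seed(77)
  for (i in 1:100) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.5, 5)
    cx <- runif(1, -3, 3); cy <- runif(1, -3, 3)
    # conic of ((x-cx)/a)^2 + ((y-cy)/b)^2 = 1
    k <- c(b^2, 0, a^2, -2 * b^2 * cx, -2 * a^2 * cy,
           b^2 * cx^2 + a^2 * cy^2 - a^2 * b^2)
    f <- semi_axes(k)
    expect_equal(f$a, a, tolerance = 1e-9)
    expect_equal(f$b, b, tolerance = 1e-9)
    expect_equal(f$center, c(cx, cy), tolerance = 1e-9)
  }
})

test_that("eigendecomposition axes agree with the closed-form semi-axis formula", {
  set.seed(13)
  for (i in 1:25) {
    pts <- half_ellipse_points(runif(1, 1, 4), runif(1, 0.5, 3),
                               cx = runif(1, -1, 1), m = 60)
    k <- fit_conic(pts)$k
    f <- semi_axes(k)
    cf <- spheromigrate:::.semi_axes_closed_form(k)
    expect_equal(sort(c(f$a, f$b), decreasing = TRUE), cf, tolerance = 1e-7)
  }
})

test_that("round-trip fit tolerates small coordinate noise", {
  set.seed(29)
  for (i in 1:10) {
    a <- runif(1, 800, 1500); b <- runif(1, 300, 1000)
    pts <- half_ellipse_points(a, b, cx = runif(1, -100, 100), m = 80)
    noisy <- pts * (1 + matrix(rnorm(length(pts), 0, 0.01), nrow(pts)))
    f <- fit_ellipse(noisy)
    expect_equal(f$a, a, tolerance = 0.02)
    expect_equal(f$b, b, tolerance = 0.02)
  }
})

test_that("swapping coordinate axes swaps the a/b labels", {
  pts <- half_ellipse_points(3, 1.5, m = 50)
  f1 <- fit_ellipse(pts)
  f2 <- fit_ellipse(pts[, 2:1])
  expect_equal(f1$a, f2$b, tolerance = 1e-9)
  expect_equal(f1$b, f2$a, tolerance = 1e-9)
})

test_that("average_ellipses averages semi-axes with sample SD", {
  mk <- function(a, b) structure(list(a = a, b = b, center = c(0, 0),
                                      tilt = 0), class = "fitted_ellipse")
  avg <- average_ellipses(list(mk(1000, 600), mk(1200, 800)))
  expect_equal(avg$a, 1100); expect_equal(avg$b, 700)
  expect_equal(avg$sd_a, sd(c(1000, 1200)))
  one <- average_ellipses(mk(500, 300))
  expect_equal(one$sd_a, 0)
  set.seed(3)
  as <- runif(8, 900, 1400); bs <- runif(8, 400, 900)
  m8 <- average_ellipses(mapply(mk, as, bs, SIMPLIFY = FALSE))
  expect_equal(m8$a, mean(as)); expect_equal(m8$sd_b, sd(bs))
})

test_that("P calibration follows a - b / R and averages per-threshold values", {
  cal <- calibrate_P(1167, 939, 2.4)
  expect_equal(cal$P, 1167 - 939 / 2.4)
  expect_equal(cal$P, 775.75)
  expect_equal(calibrate_P(10, 4, 1)$P, 6)
  expect_equal(calibrate_P(rep(900, 3), rep(200, 3), 1)$P, 700)
  expect_warning(calibrate_P(100, 500, 1), "non-positive")
})

test_that("R* arithmetic, undefined marker, and scale invariance", {
  expect_equal(round(compute_R_star(1134, 701, 745), 1), 1.8)
  expect_equal(compute_R_star(1134, 389, 745), 1)
  expect_true(is.na(compute_R_star(700, 500, 745)))
  set.seed(15)
  for (i in 1:20) {
    a <- runif(1, 800, 1500); b <- runif(1, 200, 900); P <- runif(1, 0, 700)
    s <- runif(1, 0.1, 10)
    expect_equal(compute_R_star(s * a, s * b, s * P),
                 compute_R_star(a, b, P), tolerance = 1e-12)
  }
})

test_that("calibration closure: R* built from calibrated P returns the reference R", {
  a <- c(1100, 1150, 1200); b <- c(700, 730, 760); R_ref <- 1.9
  P <- calibrate_P(a, b, R_ref)$P
  rs <- mapply(compute_R_star, a, b, MoreArgs = list(P = P))
  expect_equal(mean(b / (a - calibrate_P(a, b, R_ref)$P_i)), R_ref,
               tolerance = 1e-9)
  # with equal P_i the closure is exact for each threshold
  a2 <- c(1000, 1100, 1200); b2 <- (a2 - 700) * R_ref
  P2 <- calibrate_P(a2, b2, R_ref)$P
  expect_equal(P2, 700, tolerance = 1e-9)
  rs2 <- mapply(compute_R_star, a2, b2, MoreArgs = list(P = P2))
  expect_equal(unname(rs2), rep(R_ref, 3), tolerance = 1e-9)
  # otherwise the per-threshold spread brackets the reference
  expect_true(min(rs) <= R_ref + 0.1 && max(rs) >= R_ref - 0.1)
})

test_that("anisotropy_summary excludes the 50% threshold from R* by default", {
  mk <- function(a, b) structure(list(a = a, b = b, center = c(0, 0),
                                      tilt = 0), class = "fitted_ellipse")
  fits <- list("5%" = list(mk(1134, 701)), "50%" = list(mk(900, 500)))
  s <- anisotropy_summary(fits, P = 745)
  expect_equal(round(s$per_threshold[["5%"]]$R_star, 1), 1.8)
  expect_true(is.na(s$per_threshold[["50%"]]$R_star))
})
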