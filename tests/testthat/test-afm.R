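test_that("helical undulation is sinusoidal, bounded and mean-zero", {
  ch <- straight_chain(2000)
  und <- undulate_centerline(ch, amplitude = 1, period = 3.5, phase = 0)
  off <- und$y_nm - ch$y_nm
  expect_equal(max(abs(off)), 1, tolerance = 1e-3)
  expect_equal(mean(off), 0, tolerance = 1e-2)
  expect_true(all(abs(off) <= 1 + 1e-9))
  expect_equal(und$y_nm[1], 0) # phase 0 starts on the axis
  ident <- undulate_centerline(ch, 0)
  expect_equal(ident$y_nm, ch$y_nm)
  expect_error(undulate_centerline(ch, 1, period = 0), "positive")
  expect_error(undulate_centerline(ch, 1.5), "amplitude")
})

test_that("rendered heights equal the Gaussian of polyline distance", {
  sr <- straight_ridge(y0 = 39.0, params = noiseless_params())
  img <- sr$image
  px <- sr$px
  H <- img$heights
  pr <- noiseless_params()
  # compare a band of pixels against the closed form (within the rendering
  # reach of 3.5 sigma around the crest row 21)
  for (i in 18:24) {
    y <- (i - 1) * px
    j <- 30:60
    x <- (j - 1) * px
    d <- abs(y - sr$y0) # inside the ridge span, distance is vertical
    expect_equal(H[i, j], rep(pr$ridge_height * exp(-d^2 / (2 * pr$ridge_sigma^2)),
                              length(j)), tolerance = 1e-12)
  }
  # apparent full width at half maximum ~ 2.355 sigma
  prof <- function(y) interpolate_height(img, 100, y)
  half <- pr$ridge_height / 2
  up <- uniroot(function(y) prof(y) - half, c(sr$y0 - 6, sr$y0))$root
  dn <- uniroot(function(y) prof(y) - half, c(sr$y0, sr$y0 + 6))$root
  expect_equal(dn - up, 2.355 * pr$ridge_sigma, tolerance = 0.05)
})

test_that("rendering is equivariant under integer-pixel translation", {
  px <- 1.95
  co <- manual_contour(c(20, 120), c(40.3, 47.1))
  img1 <- render_image(co, noiseless_params(), px, n_row = 60, n_col = 90)
  co2 <- co
  co2$x_nm <- co2$x_nm + 3 * px
  co2$y_nm <- co2$y_nm + 5 * px
  img2 <- render_image(co2, noiseless_params(), px, n_row = 60, n_col = 90)
  expect_equal(img2$heights[6:60, 4:90], img1$heights[1:55, 1:87],
               tolerance = 1e-12)
})

test_that("ridge volume grows linearly with contour length", {
  px <- 1.95
  v <- vapply(c(200, 400), function(len) {
    co <- manual_contour(c(20, 20 + len), c(30, 30))
    img <- render_image(co, noiseless_params(), px)
    sum(img$heights) * px^2
  }, numeric(1))
  expect_equal(v[2] / v[1], 2, tolerance = 0.02)
})

test_that("contours outside the canvas margin are rejected", {
  co <- manual_contour(c(2, 50), c(30, 30))
  expect_error(render_image(co, noiseless_params(), 1.95), "translate")
  co2 <- manual_contour(c(20, 300), c(30, 30))
  expect_error(render_image(co2, noiseless_params(), 1.95, n_row = 40,
                            n_col = 40), "fit")
})

test_that("fixture sets are reproducible and carry exact ground truth", {
  set.seed(77)
  f1 <- make_fixture_set(2, energy_model("harmonic", lb = 56), 300)
  set.seed(77)
  f2 <- make_fixture_set(2, energy_model("harmonic", lb = 56), 300)
  expect_identical(f1$images[[1]]$heights, f2$images[[1]]$heights)
  expect_identical(f1$chains, f2$chains)
  # ground-truth chains keep exact bead geometry in image coordinates
  for (id in 1:2) {
    p <- f1$chains[f1$chains$molecule_id == id, ]
    links <- sqrt(diff(p$x_nm)^2 + diff(p$y_nm)^2)
    expect_equal(max(abs(links - 0.34)), 0, tolerance = 1e-9)
    expect_equal(sum(links), 299 * 0.34, tolerance = 1e-9)
  }
})

test_that("TIFF plus sidecar round trips preserve heights and metadata", {
  set.seed(78)
  img <- afm_image(matrix(rnorm(30 * 40, 0.5, 0.4), 30, 40), 1.95)
  f <- withr::local_tempfile(fileext = ".tif")
  write_afm_image(img, f, meta = list(seed = 78))
  back <- read_afm_image(f)
  expect_equal(back$heights, img$heights, tolerance = 1e-6)
  expect_equal(back$pixel_size, 1.95)
  expect_equal(attr(back, "meta")$seed, 78)
})
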