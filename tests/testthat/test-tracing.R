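test_that("bilinear interpolation is exact at centers, block centers and affine ramps", {
  set.seed(21)
  H <- matrix(rnorm(20 * 25), 20, 25)
  img <- afm_image(H, 2)
  # pixel centers
  expect_equal(interpolate_height(img, 2 * (7 - 1), 2 * (5 - 1)), H[5, 7])
  # center of a 2x2 block is the mean of the four values
  expect_equal(interpolate_height(img, 2 * 6.5, 2 * 4.5),
               mean(H[5:6, 7:8]))
  # affine fields are reproduced everywhere
  ramp <- outer(seq_len(20), seq_len(25),
                function(i, j) 0.3 * (j - 1) * 2 - 0.7 * (i - 1) * 2 + 1.1)
  rimg <- afm_image(ramp, 2)
  xs <- runif(50, 0, 48); ys <- runif(50, 0, 38)
  expect_equal(interpolate_height(rimg, xs, ys),
               0.3 * xs - 0.7 * ys + 1.1, tolerance = 1e-12)
  expect_error(interpolate_height(img, -1, 5), "outside")
  expect_true(is.na(interpolate_height(img, -1, 5, outside = "na")))
})

test_that("the correction integral is symmetric on-ridge and matches fine quadrature", {
  sr <- straight_ridge()
  X <- correction_direction(sr$image, c(96.5, sr$y0), c(100, sr$y0))
  expect_lt(abs(atan2(X[2], X[1])), 0.3 * pi / 180)
  expect_false(isTRUE(attr(X, "truncated")))
  # composite midpoint at px/4 vs a 10x finer rule
  fine <- function(img, origin, predicted, mul) {
    u <- (predicted - origin) / sqrt(sum((predicted - origin)^2))
    nr <- c(-u[2], u[1])
    ds <- img$pixel_size / 4 / mul
    nq <- ceiling(10 / ds); ds <- 10 / nq
    s <- -5 + (seq_len(nq) - 0.5) * ds
    qx <- predicted[1] + s * nr[1]; qy <- predicted[2] + s * nr[2]
    z <- interpolate_height(img, qx, qy)
    c(sum(z * (qx - origin[1])) * ds, sum(z * (qy - origin[2])) * ds)
  }
  X1 <- fine(sr$image, c(96.5, sr$y0 + 0.7), c(100, sr$y0 + 0.7), 1)
  X10 <- fine(sr$image, c(96.5, sr$y0 + 0.7), c(100, sr$y0 + 0.7), 10)
  expect_lt(sqrt(sum((X1 - X10)^2)) / sqrt(sum(X10^2)), 1e-3)
})

test_that("three correction iterations land on a laterally offset ridge", {
  sr <- straight_ridge()
  px <- sr$px
  v <- c(96.5, sr$y0 - px) # start one pixel off the crest
  d <- c(1, 0)
  for (it in 1:3) {
    p <- v + 3.5 * d
    X <- correction_direction(sr$image, v, p)
    d <- X / sqrt(sum(X^2))
  }
  land <- v + 3.5 * d
  expect_lt(abs(land[2] - sr$y0) / px, 0.2)
})

test_that("straight ridges are traced straight with exact chord lengths", {
  sr <- straight_ridge()
  tr <- trace_molecule(sr$image, rbind(c(12, sr$y0), c(15.5, sr$y0)),
                       l0 = 3.5)
  P <- cbind(tr$x_nm, tr$y_nm)
  chords <- sqrt(rowSums(diff(P)^2))
  expect_lt(max(abs(chords - 3.5)), 1e-6 * 3.5)
  ang <- tangent_angles(tr, 1)
  expect_lt(max(abs(ang$theta)) * 180 / pi, 0.5)
  expect_lt(max(abs(P[, 2] - sr$y0)) / sr$px, 0.1)
  # termination near the ridge end: within two links of the available span
  expect_lt(abs((nrow(tr) - 1) * 3.5 - (sr$x_range[2] - 12)), 7)
})

test_that("circular arcs are traced with the right per-link turning", {
  ar <- arc_ridge(R = 50)
  s2 <- rbind(c(ar$center[1] + ar$R * cos(0.01),
                ar$center[2] + ar$R * sin(0.01)),
              c(ar$center[1] + ar$R * cos(0.08),
                ar$center[2] + ar$R * sin(0.08)))
  tr <- trace_molecule(ar$image, s2, l0 = 3.5)
  expect_gt(nrow(tr), 40)
  ang <- tangent_angles(tr, 1)
  expected <- 2 * asin(3.5 / (2 * ar$R))
  expect_equal(mean(abs(ang$theta)), expected, tolerance = 0.1)
  # refinement pins vertices onto the arc
  rf <- refine_trace(ar$image, tr)
  radial <- abs(sqrt((rf$x_nm - ar$center[1])^2 +
                       (rf$y_nm - ar$center[2])^2) - ar$R)
  expect_lt(max(radial) / ar$px, 0.1)
  arf <- tangent_angles(rf, 1)
  expect_equal(mean(abs(arf$theta)), expected, tolerance = 0.02)
})

test_that("opposite seeding retraces the same centerline", {
  ar <- arc_ridge(R = 50, span = pi)
  fwd_seed <- rbind(c(ar$center[1] + ar$R * cos(0.02),
                      ar$center[2] + ar$R * sin(0.02)),
                    c(ar$center[1] + ar$R * cos(0.09),
                      ar$center[2] + ar$R * sin(0.09)))
  rev_seed <- rbind(c(ar$center[1] + ar$R * cos(pi - 0.02),
                      ar$center[2] + ar$R * sin(pi - 0.02)),
                    c(ar$center[1] + ar$R * cos(pi - 0.09),
                      ar$center[2] + ar$R * sin(pi - 0.09)))
  t1 <- trace_molecule(ar$image, fwd_seed, 3.5)
  t2 <- trace_molecule(ar$image, rev_seed, 3.5)
  # compare over the overlapping arc (traces overshoot the ends by ~a link)
  mid <- cbind(t2$x_nm, t2$y_nm)[3:(nrow(t2) - 2), ]
  d <- wormtrace:::dist_to_polyline(mid, cbind(t1$x_nm, t1$y_nm))$dist
  expect_lt(max(d), ar$px)
})

test_that("tracing is equivariant under a quarter-turn of the image", {
  sr <- straight_ridge()
  H <- sr$image$heights
  px <- sr$px
  nr <- nrow(H); nc <- ncol(H)
  # quarter turn: old pixel (i, j) moves to Hrot[j, nr - i + 1], i.e. the
  # point map is (x, y) -> (xmax - y, x) with xmax = (nr - 1) px
  Hrot <- matrix(0, nc, nr)
  for (i in seq_len(nr)) Hrot[, nr - i + 1] <- H[i, ]
  img_rot <- afm_image(Hrot, px)
  xmax <- (nr - 1) * px
  rot <- function(p) c(xmax - p[2], p[1])
  tr <- trace_molecule(sr$image, rbind(c(12, sr$y0), c(15.5, sr$y0)), 3.5)
  tr_rot <- trace_molecule(img_rot, rbind(rot(c(12, sr$y0)),
                                          rot(c(15.5, sr$y0))), 3.5)
  n <- min(nrow(tr), nrow(tr_rot))
  mapped <- t(apply(cbind(tr$x_nm, tr$y_nm)[seq_len(n), ], 1, rot))
  expect_equal(mapped, cbind(tr_rot$x_nm, tr_rot$y_nm)[seq_len(n), ],
               tolerance = 1e-6)
})

test_that("acute vertices are pruned and refinement is near-idempotent", {
  # a 120-degree turn (60-degree interior angle) must be removed
  P <- rbind(c(0, 0), c(3.5, 0), c(1.75, 1.0), c(7, 0.5))
  pruned <- wormtrace:::prune_acute(P)
  expect_equal(nrow(pruned), 3)
  expect_false(any(pruned[, 1] == 1.75 & pruned[, 2] == 1.0))
  # refinement barely moves a trace already on the centerline
  sr <- straight_ridge()
  tr <- trace_molecule(sr$image, rbind(c(12, sr$y0), c(15.5, sr$y0)), 3.5)
  rf <- refine_trace(sr$image, tr)
  d <- wormtrace:::dist_to_polyline(cbind(rf$x_nm, rf$y_nm),
                                    cbind(tr$x_nm, tr$y_nm))$dist
  expect_lt(max(d) / sr$px, 0.05)
  # a deliberate spike on a straight ridge is flattened out
  spiked <- tr
  spiked$y_nm[5] <- spiked$y_nm[5] + 4
  rf2 <- refine_trace(sr$image, spiked)
  expect_lt(max(abs(rf2$y_nm - sr$y0)) / sr$px, 0.1)
})

test_that("bundle spread is zero for identical traces and exact for offsets", {
  tr <- manual_contour(seq(0, 70, by = 3.5), rep(0, 21), l0 = 3.5,
                       source = "traced")
  b <- dplyr::bind_rows(dplyr::mutate(tr, trace_id = 1),
                        dplyr::mutate(tr, trace_id = 2))
  sp <- bundle_spread(b, n_stations = 40)
  expect_true(all(sp$max_pairwise_nm < 1e-9))
  off <- dplyr::mutate(tr, y_nm = y_nm + 1, trace_id = 2)
  b2 <- dplyr::bind_rows(dplyr::mutate(tr, trace_id = 1), off)
  sp2 <- bundle_spread(b2, n_stations = 40)
  expect_equal(unique(round(sp2$max_pairwise_nm, 9)), 1)
  expect_error(bundle_spread(dplyr::mutate(tr, trace_id = 1)), "two traces")
})
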