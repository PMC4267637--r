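test_that("tangent angles partition bends without overlap", {
  # straight contour: all angles zero
  st <- manual_contour(seq(0, 35, by = 3.5), rep(0, 11), l0 = 3.5)
  a <- tangent_angles(st, 1)
  expect_true(all(a$theta == 0))
  # right-angle corner at separation 1
  corner <- manual_contour(c(0, 3.5, 3.5), c(0, 0, 3.5), l0 = 3.5)
  expect_equal(tangent_angles(corner, 1)$theta, pi / 2)
  # non-overlapping partition counts: floor((n_links - 1) / s)
  cases <- list(c(10, 1, 9), c(10, 2, 4), c(10, 3, 3), c(9, 3, 2),
                c(5, 4, 1))
  for (cs in cases) {
    co <- manual_contour(seq(0, by = 3.5, length.out = cs[1] + 1),
                         rep(0, cs[1] + 1), l0 = 3.5)
    expect_equal(nrow(tangent_angles(co, cs[2])), cs[3])
  }
  # too-short contour: empty sample, not an error
  short <- manual_contour(c(0, 3.5), c(0, 0), l0 = 3.5)
  expect_equal(nrow(tangent_angles(short, 2)), 0)
})

test_that("distribution tables are normalized and Gaussian samples linearize", {
  set.seed(31)
  sigma2 <- 0.05
  a <- manual_angles(rnorm(2e5, 0, sqrt(sigma2)), L_nm = 7)
  tab <- neg_log_distribution(a, 0.05)
  expect_equal(sum(tab$p), 1, tolerance = 1e-12)
  expect_true(all(tab$count > 0))
  fit <- linear_fit(tab)
  expect_equal(fit$slope, 1 / (2 * sigma2), tolerance = 0.05)
  expect_gt(fit$r_squared, 0.99)
  # uniform angles give a flat profile
  u <- manual_angles(runif(2e5, -pi, pi), L_nm = 7)
  tabu <- neg_log_distribution(u, 0.1)
  full <- tabu[tabu$theta_rad < 3.1, ] # last bin only partially covers pi
  expect_lt(max(full$neg_log_p) - min(full$neg_log_p), 0.2)
  expect_error(neg_log_distribution(a, 0), "positive")
})

test_that("the analytic WLC curve is a normalized quadratic in theta", {
  f <- function(t) exp(-analytic_wlc_neglogp(t, L = 7, lb = 56))
  expect_equal(stats::integrate(f, -pi, pi, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # curvature lb / L everywhere
  th <- seq(-0.5, 0.5, by = 0.01)
  y <- analytic_wlc_neglogp(th, 7, 56)
  expect_equal(diff(diff(y)) / 0.01^2, rep(56 / 7, length(th) - 2),
               tolerance = 1e-8)
  expect_equal(which.min(y), which(th == 0))
  # linearize maps the zero bin to the origin
  lin <- linearize(neg_log_distribution(manual_angles(rnorm(1000, 0, 0.1),
                                                      7), 0.5))
  expect_equal(lin$x[1], 0.25^2)
})

test_that("variance and slope estimators recover lb and agree", {
  set.seed(32)
  lb <- 56; L <- 7
  a <- manual_angles(rnorm(3e4, 0, sqrt(L / lb)), L_nm = L,
                     molecule_id = rep(1:100, each = 300))
  ev <- estimate_lb(a, "variance", n_boot = 200)
  es <- estimate_lb(a, "slope", n_boot = 200)
  expect_lt(abs(ev$lb_nm - lb), 3 * ev$stderr_nm)
  expect_lt(abs(es$lb_nm - lb), 3 * es$stderr_nm)
  expect_lt(abs(ev$lb_nm - es$lb_nm),
            3 * sqrt(ev$stderr_nm^2 + es$stderr_nm^2))
  expect_equal(ev$L_eff_nm, L) # tangent samples need no chord correction
  td <- tidy(ev)
  expect_equal(td$estimate, ev$lb_nm)
  expect_error(estimate_lb(manual_angles(rep(0, 100), 7)), "undefined")
})

test_that("chord-corrected estimates are independent of tangent separation", {
  set.seed(33)
  ch <- sample_chains(energy_model("harmonic", lb = 56), 150, 4363)
  co <- resample_with_stride(ch, 3.5)
  ests <- lapply(c(2, 3, 4), function(s) {
    estimate_lb(tangent_angles(co, s), n_boot = 100)
  })
  for (e in ests) expect_equal(e$lb_nm, 56, tolerance = 0.05)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_lt(abs(ests[[i]]$lb_nm - ests[[j]]$lb_nm),
                3 * sqrt(ests[[i]]$stderr_nm^2 + ests[[j]]$stderr_nm^2))
    }
  }
})

test_that("kinkable chains still yield a finite stiffness at one helical turn", {
  set.seed(34)
  ch <- sample_chains(energy_model("lsec"), 100, 500)
  co <- resample_with_stride(ch, 3.4)
  e <- estimate_lb(tangent_angles(co, 1), n_boot = 0)
  expect_true(is.finite(e$lb_nm) && e$lb_nm > 0)
})

test_that("bisector noise inflates short-separation variance more than long", {
  set.seed(35)
  ch <- sample_chains(energy_model("harmonic", lb = 56), 120, 4363)
  infl <- vapply(c(3.5, 7), function(l0) {
    co <- resample_with_stride(ch, l0)
    v0 <- mean(tangent_angles(co, 1)$theta^2)
    v1 <- mean(tangent_angles(apply_bisector_noise(co, 1.5), 1)$theta^2)
    v1 / v0
  }, numeric(1))
  expect_gt(infl[1], infl[2])
  expect_gt(infl[2], 1)
})
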