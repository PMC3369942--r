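test_that("structure factor has the expected limits and bounds", {
  # single cluster: perfect phase coherence at every mode
  sf <- structure_factor(7.3, 5, 20)
  expect_true(all(abs(sf$S - 1) < 1e-12))
  # perfect lattice of M equal clusters: Bragg peak at 2*pi/d
  M <- 8; d <- 20 / M
  sf <- structure_factor(d * (0:(M - 1)) + 0.7, rep(3, M), 20)
  expect_equal(sf$S[sf$m == M], 1, tolerance = 1e-12)
  # two equal clusters half a ring apart interfere destructively at m = 1
  sf <- structure_factor(c(2, 12), c(1, 1), 20)
  expect_lt(sf$S[sf$m == 1], 1e-24)
  # bounds
  set.seed(30)
  sf <- structure_factor(stats::runif(40, 0, 20), stats::runif(40, 0.5, 4), 20)
  expect_true(all(sf$S >= 0 & sf$S <= 1))
  expect_error(structure_factor(numeric(0), numeric(0), 20), "empty")
  expect_error(structure_factor(c(1, 2), c(0, 0), 20), "sum > 0")
})

test_that("structure factor is translation invariant", {
  set.seed(31)
  x <- stats::runif(20, 0, 20); w <- stats::runif(20, 1, 5)
  s0 <- structure_factor(x, w, 20)$S
  for (sh in c(0.37, 5, -3.2)) {
    s1 <- structure_factor(wrap_ring(x + sh, 20), w, 20)$S
    expect_lt(max(abs(s1 - s0)), 1e-12)
  }
})

test_that("the windowed Bragg peak defines the order parameter", {
  M <- 8; d <- 20 / M
  sf <- structure_factor(d * (0:(M - 1)), rep(1, M), 20)
  op <- order_parameter(sf, c(1, 4))
  expect_equal(op$S_star, 1, tolerance = 1e-12)
  expect_equal(op$lambda_star, d)
  expect_error(order_parameter(sf, c(0.01, 0.02)), "window")
  # a fully random cluster arrangement scores low on average
  set.seed(32)
  null_S <- replicate(300, {
    sf <- structure_factor(stats::runif(50, 0, 20), rep(1, 50), 20)
    order_parameter(sf, c(1, 4))$S_star
  })
  expect_lt(mean(null_S), 0.2)
})

test_that("myosin order parameter mirrors the cluster definition with unit weights", {
  p <- bundle_params(N_actin = 2, N_myosin = 8, k0 = 0)
  fil <- data.frame(id = 1:2, sigma = c(1L, -1L), length = 1, plus_pos = 5,
                    cluster_id = 1L)
  d <- 20 / 8
  myo <- data.frame(id = 1:8, center = d * (0:7) + 1,
                    f1 = NA_integer_, off1 = NA_real_,
                    f2 = NA_integer_, off2 = NA_real_)
  st <- make_test_state(p, fil, data.frame(id = 1L, z_pos = 5), myo)
  op <- myosin_order_parameter(st)
  expect_equal(op$S_star, 1, tolerance = 1e-12)
  expect_equal(op$lambda_star, d)
  st$myo <- st$myo[0, ]
  expect_error(myosin_order_parameter(st), "no myosin")
})

test_that("cluster counting includes singletons and drops after merging", {
  p <- bundle_params(N_actin = 12, N_myosin = 0)
  set.seed(33)
  st <- init_bundle(p)
  expect_identical(cluster_count(st), 12L)
  st2 <- apply_crosslinks(st, data.frame(f1 = st$fil$id[1], f2 = st$fil$id[2]))
  expect_identical(cluster_count(st2), 11L)
})

test_that("spacing reports the Bragg wavelength and the exact mean ring gap", {
  M <- 8; d <- 20 / M
  p <- bundle_params(N_actin = M, N_myosin = 0)
  fil <- data.frame(id = 1:M, sigma = 1L, length = 1,
                    plus_pos = d * (0:(M - 1)), cluster_id = 1:M)
  st <- make_test_state(p, fil, data.frame(id = 1:M, z_pos = d * (0:(M - 1))))
  sp <- sarcomere_spacing(st)
  expect_equal(sp$lambda_star, d)
  expect_equal(sp$nn_mean, d)
  # nn_mean telescopes to L/M for ANY arrangement (why lambda* is the
  # informative spacing)
  set.seed(34)
  st$clusters$z_pos <- sort(stats::runif(M, 0, 20))
  st$fil$plus_pos <- st$clusters$z_pos
  expect_equal(sarcomere_spacing(st)$nn_mean, 20 / M, tolerance = 1e-12)
  # scale covariance: doubling lengths and the domain doubles both estimates
  p2 <- bundle_params(N_actin = M, N_myosin = 0, L_sys = 40, ell_mean = 2)
  fil2 <- data.frame(id = 1:M, sigma = 1L, length = 2,
                     plus_pos = 2 * d * (0:(M - 1)), cluster_id = 1:M)
  st2 <- make_test_state(p2, fil2,
                         data.frame(id = 1:M, z_pos = 2 * d * (0:(M - 1))))
  sp2 <- sarcomere_spacing(st2)
  expect_equal(sp2$lambda_star, 2 * d)
  expect_equal(sp2$nn_mean, 2 * d)
})

test_that("saturation fits recover known time scales deterministically", {
  t <- seq(0, 40, by = 0.25)
  S <- 0.8 * (1 - exp(-t / 5))
  fit <- fit_saturation(t, S)
  expect_lt(abs(fit$S_sat - 0.8), 1e-6)
  expect_lt(abs(fit$tau - 5), 1e-5)
  expect_false(fit$degenerate)
  # repeated noisy fits stay within 5% on tau
  set.seed(35)
  for (i in 1:5) {
    Sn <- S + stats::rnorm(length(t), 0, 0.02)
    fit <- fit_saturation(t, Sn)
    expect_lt(abs(fit$tau - 5) / 5, 0.05)
  }
  # identical data give identical fits
  f1 <- fit_saturation(t, S + 0.01)
  f2 <- fit_saturation(t, S + 0.01)
  expect_identical(f1, f2)
  # degenerate inputs are flagged
  expect_true(fit_saturation(t, rep(0, length(t)))$S_sat == 0)
  expect_true(is.na(fit_saturation(t, rep(0, length(t)))$tau))
  expect_true(fit_saturation(t, rep(0.6, length(t)))$degenerate)
  expect_error(fit_saturation(1:3, 1:3), "at least 5")
})

test_that("myosin localization measures the relative offset from plus ends", {
  p <- bundle_params(N_actin = 2, N_myosin = 2, k0 = 0)
  fil <- data.frame(id = 1:2, sigma = c(1L, -1L), length = c(1, 2),
                    plus_pos = c(5, 5), cluster_id = 1L)
  mk <- function(o1, o2) {
    myo <- data.frame(id = 1:2,
                      center = c(wrap_ring(5 + o1 + 0.25, 20),
                                 wrap_ring(5 - o2 - 0.25, 20)),
                      f1 = c(2L, NA), off1 = c(o1, NA),
                      f2 = c(NA, 1L), off2 = c(NA, o2))
    make_test_state(p, fil, data.frame(id = 1L, z_pos = 5), myo)
  }
  expect_equal(myosin_localization(mk(2, 1)), 1)      # both at minus ends
  expect_equal(myosin_localization(mk(0, 0)), 0)      # both at plus ends
  expect_equal(myosin_localization(mk(1, 0.5)), 0.5)
  st <- mk(1, 0.5); st$myo$f1 <- NA; st$myo$f2 <- NA
  expect_error(myosin_localization(st), "no bound")
})

test_that("the stationary severing distribution solves the balance equation", {
  sol <- severing_steady_pdf(1, 1)
  # boundary identity p'(0) = r/v from the stationary equation at l = 0
  expect_equal((sol$pdf[2] - sol$pdf[1]) / (sol$l[2] - sol$l[1]), 1,
               tolerance = 1e-2)
  # closed form of the stationary law: Rayleigh p(l) = (r/v) l exp(-r l^2 / 2v)
  ray <- sol$l * exp(-sol$l^2 / 2)
  expect_lt(max(abs(sol$pdf - ray)), 1e-5)
  # unimodality: exactly one sign change of p'
  dp <- diff(sol$pdf)
  sign_changes <- sum(diff(sign(dp[abs(dp) > 1e-12])) != 0)
  expect_identical(sign_changes, 1L)
  expect_error(severing_steady_pdf(0, 1), "> 0")
})

test_that("the severing density collapses under the sqrt(v/r) rescaling", {
  lam <- sqrt(4 / 1)  # v = 4, r = 1
  base <- severing_steady_pdf(1, 1, l_grid = seq(0, 8, length.out = 1601))
  fast <- severing_steady_pdf(4, 1, l_grid = seq(0, 8, length.out = 1601) * lam)
  collapsed <- fast$pdf * lam
  expect_lt(max(abs(collapsed - base$pdf)), 1e-6)
})

test_that("the event-driven severing sampler matches the stationary solution", {
  set.seed(36)
  x <- sample_severing_lengths(5000, 1, 1)
  sol <- severing_steady_pdf(1, 1)
  cdf <- stats::approxfun(sol$l, sol$cdf, yleft = 0, yright = 1)
  D <- suppressWarnings(stats::ks.test(x, cdf))$statistic
  expect_lt(D, 0.05)
  # mean length scales as sqrt(v/r)
  y <- sample_severing_lengths(5000, 1, 4)
  expect_lt(abs(mean(x) / mean(y) - 2) / 2, 0.1)
})
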