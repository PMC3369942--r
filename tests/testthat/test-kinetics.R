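test_that("crosslink rate is a Gaussian kernel in plus-end separation", {
  expect_equal(crosslink_rate(0, 10, 0.1), 10)
  expect_equal(crosslink_rate(0.1, 10, 0.1), 10 * exp(-1))
  expect_lt(crosslink_rate(10, 10, 0.1), 1e-300)
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(crosslink_rate(d, 10, 0.1)) <= 0))
  expect_error(crosslink_rate(0.1, 10, 0), "delta")
  expect_error(crosslink_rate(-0.1, 10, 0.1), ">= 0")
})

test_that("crosslink sampling matches the per-pair Bernoulli probability", {
  p <- bundle_params(N_actin = 2, N_myosin = 0, k0 = 5, delta = 0.1, dt = 1e-2)
  fil <- data.frame(id = 1:2, sigma = c(1L, -1L), length = 1,
                    plus_pos = c(5, 5), cluster_id = 1:2)
  st <- make_test_state(p, fil, data.frame(id = 1:2, z_pos = c(5, 5)))
  expect_equal(nrow(sample_crosslink_events(
    make_test_state(bundle_params(N_actin = 2, N_myosin = 0, k0 = 0),
                    fil, st$clusters), 1e-2)), 0)
  set.seed(20)
  n_trials <- 2000
  hits <- sum(vapply(seq_len(n_trials), function(i) {
    nrow(sample_crosslink_events(st, 1e-2)) }, numeric(1)))
  pr <- 1 - exp(-5 * 1e-2)
  se <- sqrt(pr * (1 - pr) / n_trials)
  expect_lt(abs(hits / n_trials - pr), 3 * se)
})

test_that("cluster merging takes the weighted circular average", {
  m <- merge_clusters(list(id = 1, z_pos = 0, members = 1),
                      list(id = 2, z_pos = 0.1, members = 2:4), 20)
  expect_equal(m$z_pos, 0.075)
  expect_setequal(m$members, 1:4)
  # across the periodic boundary
  m <- merge_clusters(list(id = 1, z_pos = 19.9, members = 1),
                      list(id = 2, z_pos = 0.1, members = 2), 20)
  expect_equal(m$z_pos, 0)
  expect_error(merge_clusters(list(id = 1, z_pos = 0, members = 1),
                              list(id = 1, z_pos = 1, members = 2), 20),
               "itself")
})

test_that("multi-way merges are order independent", {
  cl <- list(a = list(id = 1, z_pos = 5.00, members = 1),
             b = list(id = 2, z_pos = 5.10, members = 2:3),
             c = list(id = 3, z_pos = 5.25, members = 4:7))
  perms <- list(c("a", "b", "c"), c("a", "c", "b"), c("b", "c", "a"),
                c("c", "a", "b"), c("b", "a", "c"), c("c", "b", "a"))
  res <- lapply(perms, function(ord) {
    m <- merge_clusters(cl[[ord[1]]], cl[[ord[2]]], 20)
    merge_clusters(m, cl[[ord[3]]], 20)
  })
  for (r in res[-1]) {
    expect_setequal(r$members, 1:7)
    expect_lt(abs(r$z_pos - res[[1]]$z_pos), 1e-12)
  }
})

test_that("in-state merging snaps members and preserves myosin lab positions", {
  p <- bundle_params(N_actin = 3, N_myosin = 1, k0 = 10, k_on = 0, k_off = 0,
                     F_stall = 0, mu_my = NA, v_my0 = 0.5)
  fil <- data.frame(id = 1:3, sigma = c(1L, -1L, 1L), length = 1,
                    plus_pos = c(5, 5.2, 12), cluster_id = c(1L, 2L, 3L))
  myo <- data.frame(id = 1L, center = 5.55, f1 = 2L, off1 = 0.1,
                    f2 = NA_integer_, off2 = NA_real_)
  st <- make_test_state(p, fil, data.frame(id = 1:3, z_pos = c(5, 5.2, 12)), myo)
  st2 <- apply_crosslinks(st, data.frame(f1 = 1L, f2 = 2L))
  expect_equal(cluster_count(st2), 2)
  z <- st2$clusters$z_pos[st2$clusters$id == 1]
  expect_equal(z, 5.1)
  expect_equal(st2$fil$plus_pos[1:2], c(5.1, 5.1))
  # site lab position unchanged: offset recomputed against the snapped filament
  expect_equal(st2$myo$off1, 5.3 - 5.1)
  validate_state(st2)
})

test_that("myosin sites bind with the polarity convention and Poisson kinetics", {
  # right site (center + L_my/2) binds only sigma = +1 filaments
  p <- bundle_params(N_actin = 2, N_myosin = 1, k0 = 0, k_on = 1000, k_off = 0,
                     dt = 0.05, F_stall = 0, mu_my = NA, v_my0 = 0.5)
  fil <- data.frame(id = 1:2, sigma = c(1L, -1L), length = 1,
                    plus_pos = c(5.5, 4.5), cluster_id = 1:2)
  # both spans cover [4.5, 5.5]; myosin centered at 5: sites at 4.75 / 5.25
  myo <- data.frame(id = 1L, center = 5, f1 = NA_integer_, off1 = NA_real_,
                    f2 = NA_integer_, off2 = NA_real_)
  st <- make_test_state(p, fil, data.frame(id = 1:2, z_pos = c(5.5, 4.5)), myo)
  set.seed(21)
  st2 <- myosin_attach_detach(st, 0.05)
  expect_identical(st2$myo$f2, 1L)   # +1 filament on the right site
  expect_identical(st2$myo$f1, 2L)   # -1 filament on the left site
  expect_equal(st2$myo$off2, 5.5 - 5.25)
  expect_equal(st2$myo$off1, 4.75 - 4.5)
  validate_state(st2)
})

test_that("a single site equilibrates to the two-state bound fraction", {
  p <- bundle_params(N_actin = 1, N_myosin = 1, k0 = 0, k_on = 4, k_off = 6,
                     dt = 0.01, F_stall = 0, mu_my = NA, v_my0 = 0.5,
                     v_tread = 0)
  fil <- data.frame(id = 1L, sigma = 1L, length = 2, plus_pos = 6,
                    cluster_id = 1L)
  myo <- data.frame(id = 1L, center = 5 - 0.25, f1 = NA_integer_,
                    off1 = NA_real_, f2 = 1L, off2 = 1)
  st <- make_test_state(p, fil, data.frame(id = 1L, z_pos = 6), myo)
  set.seed(22)
  n_steps <- 6000
  bound <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    st <- myosin_attach_detach(st, p$dt)
    if (!is.na(st$myo$f2)) st$myo$off2 <- 1  # re-center, keep permanently eligible
    bound[i] <- !is.na(st$myo$f2)
  }
  frac <- mean(bound[-(1:500)])
  target <- 4 / (4 + 6)
  # 3 s.e. with an effective sample size from the O(1/(kon+koff)) correlation time
  n_eff <- (n_steps - 500) * p$dt * (4 + 6) / 2
  expect_lt(abs(frac - target), 3 * sqrt(target * (1 - target) / n_eff))
})

test_that("turnover conserves filament count and follows a Poisson rate", {
  p <- bundle_params(N_actin = 40, N_myosin = 0, k0 = 0, k_turnover = 0.5,
                     dt = 0.01)
  st <- local({ set.seed(23); init_bundle(p) })
  expect_identical(turnover_filaments(
    local({ q <- p; q$k_turnover <- 0; make_test_state(q, st$fil, st$clusters) }),
    0.01)$fil, st$fil)
  set.seed(24)
  n_events <- 0
  s <- st
  for (i in 1:500) {
    before <- s$fil[, c("plus_pos", "sigma")]
    s <- turnover_filaments(s, p$dt)
    n_events <- n_events + sum(before$plus_pos != s$fil$plus_pos |
                                 before$sigma != s$fil$sigma)
    expect_identical(nrow(s$fil), 40L)
  }
  lambda <- 40 * 0.5 * 500 * 0.01  # N * k * t
  expect_lt(abs(n_events - lambda), 3 * sqrt(lambda))
  validate_state(s)
})

test_that("severing cuts uniformly and scales its hazard with length", {
  p <- bundle_params(N_actin = 2, N_myosin = 0, k0 = 0, r_sever = 2,
                     length_mode = "severing", dt = 0.01)
  fil <- data.frame(id = 1:2, sigma = 1L, length = c(2, 1),
                    plus_pos = c(5, 12), cluster_id = 1:2)
  st0 <- make_test_state(p, fil, data.frame(id = 1:2, z_pos = c(5, 12)))
  set.seed(25)
  cuts <- c(0, 0); fracs <- c()
  for (i in 1:4000) {
    s <- sever_filaments(st0, p$dt)
    cut <- s$fil$length < st0$fil$length
    cuts <- cuts + cut
    if (cut[1]) fracs <- c(fracs, s$fil$length[1] / st0$fil$length[1])
  }
  p2 <- 1 - exp(-2 * 2 * 0.01); p1 <- 1 - exp(-2 * 1 * 0.01)
  # antenna property: hazard of the length-2 filament ~ twice the length-1 one
  expect_lt(abs(cuts[1] / 4000 - p2), 3 * sqrt(p2 * (1 - p2) / 4000))
  expect_lt(abs(cuts[2] / 4000 - p1), 3 * sqrt(p1 * (1 - p1) / 4000))
  # surviving fraction uniform on (0, 1)
  expect_gt(suppressWarnings(stats::ks.test(fracs, "punif")$p.value), 1e-4)
})

test_that("dissociation frees clustered filaments at the configured rate", {
  p <- bundle_params(N_actin = 4, N_myosin = 0, k0 = 0, k_diss = 1, dt = 0.01)
  fil <- data.frame(id = 1:4, sigma = 1L, length = 1, plus_pos = 5,
                    cluster_id = 1L)
  st <- make_test_state(p, fil, data.frame(id = 1L, z_pos = 5))
  q <- st; q$params$k_diss <- 0
  expect_identical(dissociate_filaments(q, 0.01)$clusters, st$clusters)
  set.seed(26)
  n_dep <- 0
  for (i in 1:2000) {
    s2 <- dissociate_filaments(st, p$dt)
    n_dep <- n_dep + (cluster_count(s2) - 1)
    # departing filaments keep their position
    expect_true(all(s2$fil$plus_pos == 5))
  }
  lambda <- 4 * 1 * 2000 * 0.01
  expect_lt(abs(n_dep - lambda), 3 * sqrt(lambda))
})

test_that("initial bundles respect the configured length distribution", {
  p <- bundle_params(N_actin = 50, N_myosin = 10)
  set.seed(27)
  st <- init_bundle(p)
  validate_state(st)
  expect_identical(nrow(st$fil), 50L)
  expect_identical(cluster_count(st), 50L)   # all singletons
  expect_true(all(st$fil$length == 1))
  expect_true(all(is.na(st$myo$f1)))
  # sigma_ell = 0 log-normal degenerates to monodisperse
  p2 <- bundle_params(length_mode = "lognormal", sigma_ell = 0)
  expect_true(all(draw_lengths(100, resolve_params(p2)) == 1))
  # moment matching of the log-normal draws
  p3 <- resolve_params(bundle_params(length_mode = "lognormal",
                                     sigma_ell = 0.25))
  x <- draw_lengths(1e5, p3)
  expect_lt(abs(mean(x) - 1), 0.01)
  expect_lt(abs(stats::sd(x) - 0.25), 0.01 * 0.25 + 0.005)
  # exponential mode has the requested mean
  p4 <- resolve_params(bundle_params(length_mode = "exponential"))
  y <- draw_lengths(1e5, p4)
  expect_lt(abs(mean(y) - 1), 0.02)
})

test_that("parameter invariants are enforced", {
  expect_error(bundle_params(dt = 0), "dt")
  expect_error(bundle_params(L_sys = 1.5), "L_sys")
  expect_error(bundle_params(k0 = -1), "negative")
  expect_error(bundle_params(length_mode = "severing", r_sever = 0), "r_sever")
  expect_error(bundle_params(length_mode = "severing", r_sever = 1,
                             k_turnover = 1), "k_turnover")
  expect_error(bundle_params(gama = 1), "gama")
})
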