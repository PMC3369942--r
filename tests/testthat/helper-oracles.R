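# Independent oracles used across tests: each solves the relevant physics
# by a route different from the package implementation.

# cluster velocity by numeric root-finding on the net drag force
oracle_cluster_velocity <- function(lengths_plus, lengths_minus, v_tread,
                                    gamma = 1) {
  force <- function(V) {
    -sum(gamma * lengths_plus * (V - v_tread)) -
      sum(gamma * lengths_minus * (V + v_tread))
  }
  stats::uniroot(force, c(-10, 10) * max(1, v_tread), tol = 1e-15)$root
}

# myosin connector: solve the three linear equations in (F_a, F_b, V_m)
#   sigma_a F_a + sigma_b F_b = 0
#   V_m + (sigma_a v0 / F) F_a = u_a + sigma_a v0
#   V_m + (sigma_b v0 / F) F_b = u_b + sigma_b v0
oracle_myosin_force <- function(sa, sb, ua, ub, F, v0) {
  A <- rbind(c(sa, sb, 0),
             c(sa * v0 / F, 0, 1),
             c(0, sb * v0 / F, 1))
  x <- solve(A, c(0, ua + sa * v0, ub + sb * v0))
  list(f_a = -sa * x[1], f_b = -sb * x[2],
       w_a = v0 * (1 - x[1] / F), w_b = v0 * (1 - x[2] / F), V_m = x[3])
}

# ring-overlap by dense grid enumeration
oracle_overlap_brute <- function(f1, f2, L, n = 2e5) {
  x <- seq(0, L, length.out = n + 1)[-(n + 1)]
  inside <- function(f, x) {
    d <- (f$sigma * (f$plus_pos - x)) %% L
    d <= f$length
  }
  mean(inside(f1, x) & inside(f2, x)) * L
}

# convenience constructor for hand-built states
make_test_state <- function(params, fil, clusters, myo = NULL) {
  p <- resolve_params(params)
  if (is.null(myo)) {
    myo <- data.frame(id = integer(0), center = numeric(0),
                      f1 = integer(0), off1 = numeric(0),
                      f2 = integer(0), off2 = numeric(0))
  }
  st <- new_bundle_state(0, fil, clusters, myo, p)
  validate_state(st)
  st
}

# two balanced clusters at the given gap bridged by one doubly bound myosin
two_cluster_bridge_state <- function(gap = 2, L = 10, F_stall = 0.5,
                                     v_my0 = 0.5, zeta = 0) {
  p <- bundle_params(N_actin = 4, N_myosin = 1, L_sys = L, k0 = 0,
                     k_on = 0, k_off = 0, zeta = zeta, F_stall = F_stall,
                     v_my0 = v_my0, mu_my = NA)
  z1 <- L / 2 - gap / 2; z2 <- L / 2 + gap / 2
  fil <- data.frame(id = 1:4, sigma = c(1L, -1L, 1L, -1L), length = 1,
                    plus_pos = c(z1, z1, z2, z2),
                    cluster_id = c(1L, 1L, 2L, 2L))
  clusters <- data.frame(id = 1:2, z_pos = c(z1, z2))
  ctr <- L / 2
  off1 <- (ctr - 0.25) - z1   # left site on fil 2 (sigma -1 of cluster 1)
  off2 <- z2 - (ctr + 0.25)   # right site on fil 3 (sigma +1 of cluster 2)
  myo <- data.frame(id = 1L, center = ctr, f1 = 2L, off1 = off1,
                    f2 = 3L, off2 = off2)
  make_test_state(p, fil, clusters, myo)
}
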