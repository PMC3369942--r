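#' Monomer velocity of a treadmilling filament
#'
#' Treadmilling makes the plus end advance relative to the filament's
#' monomers at the polymerization speed: in the lab frame the monomers move
#' at `unit_velocity - sigma * v_tread`, where `unit_velocity` is the
#' velocity of the plus end (equivalently of the cluster pinning it).  A
#' free filament whose force balance gives `unit_velocity = sigma * v_tread`
#' therefore has monomers at rest.
#'
#' @param unit_velocity Velocity of the mobile unit (plus end).
#' @param sigma Orientation (+1/-1).
#' @param v_tread Treadmilling speed.
#' @return Monomer (material) velocity.
#' @export
monomer_velocity <- function(unit_velocity, sigma, v_tread) {
  unit_velocity - sigma * v_tread
}

#' Closed-form velocity of an isolated actin cluster
#'
#' Local force balance at the Z-band: each member filament drags on the
#' cytosol with force \eqn{-\gamma l (V - \sigma v)}; setting the sum to
#' zero gives \eqn{V = v (\Sigma l_+ - \Sigma l_-) / (\Sigma l_+ + \Sigma l_-)}.
#' For monodisperse lengths this reduces to \eqn{v (n_+ - n_-)/(n_+ + n_-)}:
#' a cluster moves by the statistical imbalance of its two filament
#' populations.
#'
#' @param lengths_plus Lengths of the `sigma = +1` members.
#' @param lengths_minus Lengths of the `sigma = -1` members.
#' @param v_tread Treadmilling speed.
#' @return Cluster (Z-band) velocity.
#' @examples
#' single_cluster_velocity(rep(1, 3), rep(1, 1), 1)  # 0.5
#' @export
single_cluster_velocity <- function(lengths_plus, lengths_minus, v_tread) {
  tot <- sum(lengths_plus) + sum(lengths_minus)
  if (length(lengths_plus) + length(lengths_minus) == 0 || tot <= 0) {
    stop("cluster must contain at least one filament")
  }
  v_tread * (sum(lengths_plus) - sum(lengths_minus)) / tot
}

#' Forces and kinematics of a doubly bound bipolar myosin
#'
#' Solves the massless-connector subsystem for one myosin bridging
#' filaments a and b with monomer speeds `u_a`, `u_b`:
#' force balance on the connector \eqn{\sigma_a F_a + \sigma_b F_b = 0},
#' shared connector velocity \eqn{V_m = u_a + \sigma_a w_a = u_b + \sigma_b w_b},
#' and the linear force-velocity relation \eqn{w_i = v_0 (1 - F_i/F_{stall})}.
#' The closed form is
#' \eqn{F_a = F_{stall}\,\sigma_a [(u_a-u_b) + v_0(\sigma_a-\sigma_b)]/(2 v_0)};
#' the force exerted on filament a is \eqn{-\sigma_a F_a} and on b its
#' negative (Newton's third law).  Walking speeds may become negative
#' (back-slipping past stall) under strong backward load.
#'
#' @param sigma_a,sigma_b Orientations of the two bound filaments.
#' @param u_a,u_b Monomer velocities of the two filaments.
#' @param F_stall Active myosin (stall) force; `F_stall = 0` gives zero
#'   forces and free walking at `v_my0`.
#' @param v_my0 Unloaded walking speed (> 0).
#' @return List with `f_a`, `f_b` (forces on the filaments), `w_a`, `w_b`
#'   (walking speeds) and `V_m` (connector velocity; `NA` in the
#'   unconstrained `F_stall = 0` case if the two sites disagree).
#' @export
myosin_pair_force <- function(sigma_a, sigma_b, u_a, u_b, F_stall, v_my0) {
  if (v_my0 <= 0) stop("v_my0 must be > 0")
  if (F_stall < 0) stop("F_stall must be >= 0")
  if (F_stall == 0) {
    va <- u_a + sigma_a * v_my0
    vb <- u_b + sigma_b * v_my0
    return(list(f_a = 0, f_b = 0, w_a = v_my0, w_b = v_my0,
                V_m = if (isTRUE(all.equal(va, vb))) va else (va + vb) / 2))
  }
  F_a <- F_stall * sigma_a * ((u_a - u_b) + v_my0 * (sigma_a - sigma_b)) / (2 * v_my0)
  F_b <- -sigma_a * sigma_b * F_a
  w_a <- v_my0 * (1 - F_a / F_stall)
  w_b <- v_my0 * (1 - F_b / F_stall)
  list(f_a = -sigma_a * F_a, f_b = sigma_a * F_a,
       w_a = w_a, w_b = w_b, V_m = u_a + sigma_a * w_a)
}

#' Assemble the per-step linear force balance over all mobile units
#'
#' Every cluster (singletons included) is one mobile unit with unknown
#' velocity.  For unit i the balance reads
#' \deqn{\sum_{m \in i} \gamma l_m (V_i - \sigma_m v)
#'   + \sum_{pairs} \zeta O_{mn} (u_m - u_n)
#'   + \sum_{myosin} (\text{linearized pair force}) = 0,}
#' rearranged into the symmetric system `A V = b` with all myosin internals
#' eliminated via the closed form of [myosin_pair_force()]: a doubly bound
#' myosin bridging units i and j contributes `kappa = F_stall / (2 v_my0)`
#' to `A[i,i]`, `A[j,j]` and `-kappa` to the off-diagonals, plus the
#' constant drive `kappa (sigma_a - sigma_b)(v - v_my0)` to `b`.  Myosins
#' bridging two filaments of the same unit contribute zero net force, as do
#' friction pairs within one unit.
#'
#' @param state A `bundle_state`.
#' @return List of class `force_system`: `A` (force per speed), `b` (force),
#'   `unit_ids` (cluster ids indexing rows).
#' @export
assemble_force_system <- function(state) {
  p <- state$params
  fil <- state$fil
  cl <- state$clusters
  n <- nrow(cl)
  unit <- match(fil$cluster_id, cl$id)
  A <- matrix(0, n, n)
  b <- numeric(n)
  # cytosolic drag
  for (k in seq_len(nrow(fil))) {
    i <- unit[k]
    A[i, i] <- A[i, i] + p$gamma * fil$length[k]
    b[i] <- b[i] + p$gamma * p$v_tread * fil$sigma[k] * fil$length[k]
  }
  # inter-filament sliding friction, couples monomer velocities
  if (p$zeta > 0 && nrow(fil) > 1) {
    for (k in seq_len(nrow(fil) - 1)) {
      for (l in seq((k + 1), nrow(fil))) {
        i <- unit[k]; j <- unit[l]
        if (i == j) next
        ov <- overlap_ring(fil$plus_pos[k] - fil$sigma[k] * fil$length[k] / 2,
                           fil$length[k],
                           fil$plus_pos[l] - fil$sigma[l] * fil$length[l] / 2,
                           fil$length[l], p$L_sys)
        if (ov <= 0) next
        A[i, i] <- A[i, i] + p$zeta * ov
        A[j, j] <- A[j, j] + p$zeta * ov
        A[i, j] <- A[i, j] - p$zeta * ov
        A[j, i] <- A[j, i] - p$zeta * ov
        drive <- p$zeta * ov * p$v_tread * (fil$sigma[k] - fil$sigma[l])
        b[i] <- b[i] + drive
        b[j] <- b[j] - drive
      }
    }
  }
  # doubly bound myosins bridging two units
  if (nrow(state$myo) > 0 && p$F_stall > 0) {
    kappa <- p$F_stall / (2 * p$v_my0)
    for (m in seq_len(nrow(state$myo))) {
      f1 <- state$myo$f1[m]; f2 <- state$myo$f2[m]
      if (is.na(f1) || is.na(f2)) next
      ka <- match(f1, fil$id); kb <- match(f2, fil$id)
      i <- unit[ka]; j <- unit[kb]
      if (i == j) next
      sa <- fil$sigma[ka]; sb <- fil$sigma[kb]
      A[i, i] <- A[i, i] + kappa
      A[j, j] <- A[j, j] + kappa
      A[i, j] <- A[i, j] - kappa
      A[j, i] <- A[j, i] - kappa
      b[i] <- b[i] + kappa * (sa - sb) * (p$v_tread - p$v_my0)
      b[j] <- b[j] + kappa * (sb - sa) * (p$v_tread - p$v_my0)
    }
  }
  structure(list(A = A, b = b, unit_ids = cl$id), class = "force_system")
}

#' Solve a force system exactly
#'
#' Direct dense solve of the symmetric positive definite velocity system;
#' the residual `max |A V - b|` is attached as an attribute and must be
#' below 1e-9 in simulation force units for any well-posed state.
#'
#' @param sys A `force_system` from [assemble_force_system()].
#' @return Named numeric vector of unit velocities (names = cluster ids),
#'   with attribute `residual`.
#' @export
solve_velocities <- function(sys) {
  V <- tryCatch(solve(sys$A, sys$b), error = function(e) {
    d <- diag(sys$A)
    stop("singular force system; offending unit id ",
         sys$unit_ids[which.min(abs(d))], " (", conditionMessage(e), ")")
  })
  V <- as.numeric(V)
  names(V) <- as.character(sys$unit_ids)
  attr(V, "residual") <- if (length(V)) max(abs(sys$A %*% V - sys$b)) else 0
  V
}

# per-myosin kinematics given solved unit velocities:
# returns data.frame(V_m, w1, w2) aligned with state$myo rows
myosin_kinematics <- function(state, velocities) {
  p <- state$params
  fil <- state$fil
  m <- nrow(state$myo)
  out <- data.frame(V_m = rep(0, m), w1 = rep(NA_real_, m), w2 = rep(NA_real_, m))
  if (m == 0) return(out)
  uv <- function(fid) {
    k <- match(fid, fil$id)
    V <- velocities[as.character(fil$cluster_id[k])]
    monomer_velocity(as.numeric(V), fil$sigma[k], p$v_tread)
  }
  for (i in seq_len(m)) {
    f1 <- state$myo$f1[i]; f2 <- state$myo$f2[i]
    if (!is.na(f1) && !is.na(f2)) {
      k1 <- match(f1, fil$id); k2 <- match(f2, fil$id)
      pf <- myosin_pair_force(fil$sigma[k1], fil$sigma[k2], uv(f1), uv(f2),
                              p$F_stall, p$v_my0)
      out$V_m[i] <- if (is.na(pf$V_m)) 0 else pf$V_m
      out$w1[i] <- pf$w_a
      out$w2[i] <- pf$w_b
    } else if (!is.na(f1)) {
      k1 <- match(f1, fil$id)
      out$V_m[i] <- uv(f1) + fil$sigma[k1] * p$v_my0
      out$w1[i] <- p$v_my0
    } else if (!is.na(f2)) {
      k2 <- match(f2, fil$id)
      out$V_m[i] <- uv(f2) + fil$sigma[k2] * p$v_my0
      out$w2[i] <- p$v_my0
    }
  }
  out
}

#' Advance positions, myosins and lengths by one time step
#'
#' Explicit Euler update at the solved velocities: cluster positions (and
#' with them every member plus end) advance by `V dt`; doubly bound myosin
#' centers advance by the connector velocity `V_m dt` and each bound site
#' offset by `(v_tread - w) dt` (conveyor-belt relation: a stalled site,
#' `w = 0`, is swept toward the minus end at exactly the treadmilling
#' speed); singly bound myosins advect with their filament at
#' `u + sigma * v_my0`; unbound myosins are static.  In
#' `length_mode = "severing"` every filament grows by `v_tread * dt`.
#' Sites whose offset leaves `[0, length]` detach (drop-off at either end).
#'
#' @param state A `bundle_state`.
#' @param velocities Named unit velocities from [solve_velocities()].
#' @return The state at `time + dt`.
#' @export
advance_state <- function(state, velocities) {
  p <- state$params
  if (p$dt <= 0) stop("dt must be > 0")
  L <- p$L_sys
  kin <- myosin_kinematics(state, velocities)  # uses pre-move velocities
  V <- velocities[as.character(state$clusters$id)]
  state$clusters$z_pos <- wrap_ring(state$clusters$z_pos + as.numeric(V) * p$dt, L)
  state$fil$plus_pos <- state$clusters$z_pos[match(state$fil$cluster_id,
                                                   state$clusters$id)]
  if (p$length_mode == "severing") {
    state$fil$length <- state$fil$length + p$v_tread * p$dt
  }
  m <- nrow(state$myo)
  if (m > 0) {
    bound_any <- !is.na(state$myo$f1) | !is.na(state$myo$f2)
    state$myo$center[bound_any] <- wrap_ring(
      state$myo$center[bound_any] + kin$V_m[bound_any] * p$dt, L)
    for (s in c(1, 2)) {
      fcol <- paste0("f", s); ocol <- paste0("off", s)
      b <- !is.na(state$myo[[fcol]])
      w <- kin[[paste0("w", s)]][b]
      state$myo[[ocol]][b] <- state$myo[[ocol]][b] + (p$v_tread - w) * p$dt
      # drop-off at filament ends
      k <- match(state$myo[[fcol]][b], state$fil$id)
      bad <- state$myo[[ocol]][b] < 0 | state$myo[[ocol]][b] > state$fil$length[k]
      if (any(bad)) {
        idx <- which(b)[bad]
        state$myo[[fcol]][idx] <- NA_integer_
        state$myo[[ocol]][idx] <- NA_real_
      }
    }
  }
  state$time <- state$time + p$dt
  state
}
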