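#' Plus-end crosslinking rate
#'
#' Two filaments whose plus ends are a (minimum-image) distance `d` apart
#' become irreversibly crosslinked at rate `k0 * exp(-(d/delta)^2)`;
#' the precise kernel shape matters little, only that it is a smooth,
#' monotone-decreasing function with capture range `delta`.
#'
#' @param d Plus-end separation (>= 0).
#' @param k0 Rate amplitude.
#' @param delta Capture range (> 0).
#' @return Crosslinking rate.
#' @export
crosslink_rate <- function(d, k0, delta) {
  if (delta <= 0) stop("delta must be > 0")
  if (any(d < 0)) stop("d must be >= 0")
  k0 * exp(-(d / delta)^2)
}

#' Sample this step's crosslinking events
#'
#' Every pair of filaments in *different* clusters whose plus ends are
#' within the eligibility cutoff `4 * delta` (beyond which the rate is
#' below `2e-7 * k0`) links independently with probability
#' `1 - exp(-k(d) * dt)`.  Warns if the per-pair probability at contact
#' exceeds 0.1 (time step too coarse for event sampling).
#'
#' @param state A `bundle_state`.
#' @param dt Time step.
#' @return Data frame of filament id pairs (`f1`, `f2`), possibly empty.
#' @export
sample_crosslink_events <- function(state, dt) {
  p <- state$params
  out <- data.frame(f1 = integer(0), f2 = integer(0))
  if (p$k0 <= 0 || nrow(state$fil) < 2) return(out)
  if (1 - exp(-p$k0 * dt) > 0.1) {
    warning("per-pair crosslink probability exceeds 0.1; reduce dt")
  }
  fil <- state$fil
  n <- nrow(fil)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (fil$cluster_id[i] == fil$cluster_id[j]) next
      d <- abs(min_image(fil$plus_pos[i] - fil$plus_pos[j], p$L_sys))
      if (d > 4 * p$delta) next
      pr <- 1 - exp(-crosslink_rate(d, p$k0, p$delta) * dt)
      if (stats::runif(1) < pr) {
        out <- rbind(out, data.frame(f1 = fil$id[i], f2 = fil$id[j]))
      }
    }
  }
  out
}

#' Merge two clusters into one
#'
#' The merged Z-band coordinate is the weighted circular average of the two
#' cluster coordinates with weights equal to their filament numbers:
#' `z = wrap(z_a + N_b/(N_a+N_b) * min_image(z_b - z_a))`.  Member sets are
#' united; the surviving id is `a$id`.
#'
#' @param a,b Cluster records: lists with `id`, `z_pos`, `members`
#'   (vector of filament ids).
#' @param L_sys Domain size.
#' @return Merged cluster record.
#' @examples
#' merge_clusters(list(id = 1, z_pos = 0,   members = 1),
#'                list(id = 2, z_pos = 0.1, members = 2:4), 20)$z_pos  # 0.075
#' @export
merge_clusters <- function(a, b, L_sys) {
  if (identical(a$id, b$id)) stop("cannot merge a cluster with itself")
  na <- length(a$members); nb <- length(b$members)
  z <- wrap_ring(a$z_pos + nb / (na + nb) * min_image(b$z_pos - a$z_pos, L_sys),
                 L_sys)
  list(id = a$id, z_pos = z, members = c(a$members, b$members))
}

# merge cluster cid_b into cid_a inside a state: weighted position, member
# snap, myosin offsets recomputed at fixed site lab position (detach if the
# site falls off the filament).
merge_clusters_in_state <- function(state, cid_a, cid_b) {
  p <- state$params
  L <- p$L_sys
  cl <- state$clusters
  ia <- match(cid_a, cl$id); ib <- match(cid_b, cl$id)
  ma <- cluster_members(state, cid_a); mb <- cluster_members(state, cid_b)
  merged <- merge_clusters(list(id = cid_a, z_pos = cl$z_pos[ia], members = ma),
                           list(id = cid_b, z_pos = cl$z_pos[ib], members = mb),
                           L)
  state$clusters$z_pos[ia] <- merged$z_pos
  state$clusters <- state$clusters[-ib, , drop = FALSE]
  sel <- state$fil$cluster_id %in% c(cid_a, cid_b)
  state$fil$cluster_id[sel] <- cid_a
  state$fil$plus_pos[sel] <- merged$z_pos
  # re-derive offsets of sites bound to snapped filaments
  if (nrow(state$myo) > 0) {
    for (s in c(1, 2)) {
      fcol <- paste0("f", s); ocol <- paste0("off", s)
      b <- !is.na(state$myo[[fcol]]) &
        state$myo[[fcol]] %in% state$fil$id[sel]
      if (!any(b)) next
      k <- match(state$myo[[fcol]][b], state$fil$id)
      x <- wrap_ring(state$myo$center[b] + (if (s == 1) -1 else 1) * p$L_my / 2, L)
      d <- wrap_ring(state$fil$sigma[k] * (state$fil$plus_pos[k] - x), L)
      keep <- d <= state$fil$length[k]
      idx <- which(b)
      state$myo[[ocol]][idx[keep]] <- d[keep]
      state$myo[[fcol]][idx[!keep]] <- NA_integer_
      state$myo[[ocol]][idx[!keep]] <- NA_real_
    }
  }
  state
}

#' Apply sampled crosslink events by iterated pairwise merging
#'
#' Filament pairs are mapped to cluster pairs and merged sequentially in
#' ascending `(id, id)` order; simultaneous multi-way merges therefore
#' resolve deterministically, and the result is independent of the order in
#' which the events were sampled (associativity is a tested property).
#'
#' @param state A `bundle_state`.
#' @param pairs Data frame from [sample_crosslink_events()].
#' @return Updated state.
#' @export
apply_crosslinks <- function(state, pairs) {
  if (nrow(pairs) == 0) return(state)
  ca <- state$fil$cluster_id[match(pairs$f1, state$fil$id)]
  cb <- state$fil$cluster_id[match(pairs$f2, state$fil$id)]
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  ord <- order(lo, hi)
  for (k in ord) {
    a <- state$fil$cluster_id[match(pairs$f1[k], state$fil$id)]
    b <- state$fil$cluster_id[match(pairs$f2[k], state$fil$id)]
    if (a == b) next
    state <- merge_clusters_in_state(state, min(a, b), max(a, b))
  }
  state
}

#' Spontaneous dissociation of single filaments from clusters
#'
#' When `k_diss > 0` each clustered filament (in a cluster of two or more)
#' leaves its cluster with probability `1 - exp(-k_diss * dt)`, becoming a
#' free unit — bookkept as a fresh singleton cluster — at unchanged
#' position.
#'
#' @param state A `bundle_state`.
#' @param dt Time step.
#' @return Updated state.
#' @export
dissociate_filaments <- function(state, dt) {
  p <- state$params
  if (p$k_diss <= 0) return(state)
  pr <- 1 - exp(-p$k_diss * dt)
  counts <- table(state$fil$cluster_id)
  multi <- state$fil$cluster_id %in% as.integer(names(counts)[counts >= 2])
  leave <- multi & stats::runif(nrow(state$fil)) < pr
  for (k in which(leave)) {
    # cluster may have shrunk to a singleton meanwhile
    if (sum(state$fil$cluster_id == state$fil$cluster_id[k]) < 2) next
    nid <- max(state$clusters$id) + 1L
    state$clusters <- rbind(state$clusters,
                            data.frame(id = nid, z_pos = state$fil$plus_pos[k]))
    state$fil$cluster_id[k] <- nid
  }
  state
}

#' Myosin site detachment and attachment
#'
#' Attachment and detachment are simple Poisson processes with constant
#' rates: each bound site unbinds with probability `1 - exp(-k_off * dt)`;
#' each unbound site binds with probability `1 - exp(-k_on * dt)` to a
#' uniformly chosen eligible filament.  Eligibility is polarity-specific
#' (the left site at `center - L_my/2` binds only `sigma = -1` filaments,
#' the right site only `sigma = +1`) and requires the filament span to
#' cover the site's lab position; the offset is then set from geometry.
#' Detachment is processed before attachment within a step.
#'
#' @param state A `bundle_state`.
#' @param dt Time step.
#' @return Updated state.
#' @export
myosin_attach_detach <- function(state, dt) {
  p <- state$params
  if (nrow(state$myo) == 0) return(state)
  L <- p$L_sys
  p_off <- 1 - exp(-p$k_off * dt)
  p_on <- 1 - exp(-p$k_on * dt)
  for (s in c(1, 2)) {
    fcol <- paste0("f", s); ocol <- paste0("off", s)
    b <- which(!is.na(state$myo[[fcol]]))
    if (p$k_off > 0 && length(b) > 0) {
      off <- b[stats::runif(length(b)) < p_off]
      state$myo[[fcol]][off] <- NA_integer_
      state$myo[[ocol]][off] <- NA_real_
    }
  }
  if (p$k_on > 0) {
    want <- c(-1L, 1L)
    for (s in c(1, 2)) {
      fcol <- paste0("f", s); ocol <- paste0("off", s)
      for (m in which(is.na(state$myo[[fcol]]))) {
        if (stats::runif(1) >= p_on) next
        x <- wrap_ring(state$myo$center[m] + (if (s == 1) -1 else 1) * p$L_my / 2, L)
        cand <- which(state$fil$sigma == want[s])
        if (length(cand) == 0) next
        d <- wrap_ring(state$fil$sigma[cand] * (state$fil$plus_pos[cand] - x), L)
        keep <- d <= state$fil$length[cand]
        cand <- cand[keep]; d <- d[keep]
        if (length(cand) == 0) next
        j <- if (length(cand) == 1) 1L else sample.int(length(cand), 1)
        state$myo[[fcol]][m] <- state$fil$id[cand[j]]
        state$myo[[ocol]][m] <- d[j]
      }
    }
  }
  state
}

#' Catastrophe-style filament turnover
#'
#' Each filament undergoes a catastrophe — instantaneous complete
#' depolymerization — with probability `1 - exp(-k_turnover * dt)`.  Bound
#' myosin sites detach, the filament leaves its cluster (the cluster is
#' deleted if emptied), and one replacement filament nucleates de novo at a
#' uniform random position with fair-coin orientation and a fresh length
#' from the configured distribution, as its own singleton cluster.  The
#' total filament count is strictly conserved.
#'
#' @param state A `bundle_state`.
#' @param dt Time step.
#' @return Updated state.
#' @export
turnover_filaments <- function(state, dt) {
  p <- state$params
  if (p$k_turnover <= 0) return(state)
  if (p$length_mode == "severing") stop("turnover is disabled in severing mode")
  pr <- 1 - exp(-p$k_turnover * dt)
  for (k in seq_len(nrow(state$fil))) {
    if (stats::runif(1) >= pr) next
    fid <- state$fil$id[k]
    for (s in c(1, 2)) {
      fcol <- paste0("f", s); ocol <- paste0("off", s)
      hit <- which(state$myo[[fcol]] %in% fid)
      state$myo[[fcol]][hit] <- NA_integer_
      state$myo[[ocol]][hit] <- NA_real_
    }
    old <- state$fil$cluster_id[k]
    state$fil$plus_pos[k] <- stats::runif(1) * p$L_sys
    state$fil$sigma[k] <- if (stats::runif(1) < 0.5) 1L else -1L
    state$fil$length[k] <- draw_lengths(1, p)
    nid <- max(state$clusters$id) + 1L
    state$clusters <- rbind(state$clusters,
                            data.frame(id = nid, z_pos = state$fil$plus_pos[k]))
    state$fil$cluster_id[k] <- nid
    if (!any(state$fil$cluster_id == old)) {
      state$clusters <- state$clusters[state$clusters$id != old, , drop = FALSE]
    }
  }
  state
}

#' Length-dependent filament severing
#'
#' A severing agent binds anywhere along a filament at rate `r_sever` per
#' unit length, so a filament of length `l` is cut with probability
#' `1 - exp(-r_sever * l * dt)` per step (the "binding antenna" effect:
#' severing hazard is proportional to length).  The cut position is uniform
#' along the filament; the minus-end fragment depolymerizes instantly, so
#' the new length is the distance from the cut to the plus end — uniform on
#' `(0, l)` — with `plus_pos` and cluster membership unchanged.  Myosin
#' sites whose offset exceeds the new length detach.
#'
#' @param state A `bundle_state`.
#' @param dt Time step.
#' @return Updated state.
#' @export
sever_filaments <- function(state, dt) {
  p <- state$params
  if (p$r_sever <= 0) stop("sever_filaments requires r_sever > 0")
  for (k in seq_len(nrow(state$fil))) {
    pr <- 1 - exp(-p$r_sever * state$fil$length[k] * dt)
    if (stats::runif(1) >= pr) next
    newlen <- stats::runif(1) * state$fil$length[k]
    state$fil$length[k] <- max(newlen, 1e-12)
    fid <- state$fil$id[k]
    for (s in c(1, 2)) {
      fcol <- paste0("f", s); ocol <- paste0("off", s)
      hit <- which(state$myo[[fcol]] %in% fid & state$myo[[ocol]] > newlen)
      state$myo[[fcol]][hit] <- NA_integer_
      state$myo[[ocol]][hit] <- NA_real_
    }
  }
  state
}

#' One full simulation step (reference implementation)
#'
#' Applies the fixed per-step event ordering: (1) myosin detachment,
#' (2) myosin attachment, (3) crosslinking and cluster merging,
#' (4) cluster dissociation, (5) turnover or severing, (6) exact solve of
#' the force balance on the post-event topology, (7) Euler advance.  This
#' pure-R stepper defines the semantics; the compiled engine used by
#' [simulate_bundle()] implements the same ordering.
#'
#' @param state A `bundle_state`.
#' @return List with the advanced `state` and the step's force-balance
#'   `residual`.
#' @export
step_bundle <- function(state) {
  p <- state$params
  state <- myosin_attach_detach(state, p$dt)
  state <- apply_crosslinks(state, sample_crosslink_events(state, p$dt))
  state <- dissociate_filaments(state, p$dt)
  if (p$length_mode == "severing") {
    state <- sever_filaments(state, p$dt)
  } else if (p$k_turnover > 0) {
    state <- turnover_filaments(state, p$dt)
  }
  V <- solve_velocities(assemble_force_system(state))
  state <- advance_state(state, V)
  list(state = state, residual = attr(V, "residual"))
}
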