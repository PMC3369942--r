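#' Bundle state container
#'
#' A `bundle_state` is a plain list with components
#' \describe{
#'   \item{time}{current simulation time}
#'   \item{fil}{data frame of filaments: `id`, `sigma` (+1/-1), `length`,
#'     `plus_pos` in `[0, L_sys)`, `cluster_id`}
#'   \item{clusters}{data frame of plus-end crosslinked clusters (Z-bands):
#'     `id`, `z_pos`; membership is carried by `fil$cluster_id`.  Singleton
#'     clusters are allowed: a free filament is bookkept as a cluster of one,
#'     and a single filament counts as one cluster.}
#'   \item{myo}{data frame of bipolar myosin filaments: `id`, `center`,
#'     `f1`/`off1` (left binding site, binds only `sigma = -1` filaments;
#'     site position `center - L_my/2`), `f2`/`off2` (right site, binds only
#'     `sigma = +1`; position `center + L_my/2`).  `f1`/`f2` are filament ids
#'     or `NA`; offsets are distances from the bound filament's plus end to
#'     the attachment point, measured along the filament.}
#'   \item{params}{the resolved [bundle_params()]}
#'   \item{rng_state}{opaque RNG snapshot (may be `NULL`)}
#' }
#'
#' @param time Simulation time.
#' @param fil,clusters,myo Data frames as described above.
#' @param params A `bundle_params` object.
#' @param rng_state Optional RNG snapshot.
#' @return An object of class `bundle_state`.
#' @export
new_bundle_state <- function(time, fil, clusters, myo, params, rng_state = NULL) {
  structure(list(time = time, fil = fil, clusters = clusters, myo = myo,
                 params = params, rng_state = rng_state),
            class = "bundle_state")
}

#' Initialize a bundle with random filament and myosin positions
#'
#' Places `N_actin` filaments at independent uniform positions on the ring
#' with fair-coin orientations, each in its own singleton cluster, and
#' `N_myosin` unbound myosins at uniform positions.  Filament lengths follow
#' `length_mode`: monodisperse (`ell_mean`), log-normal (moment-matched to
#' mean `ell_mean` and s.d. `sigma_ell * ell_mean`), exponential (mean
#' `ell_mean`), or severing (initialized at `ell_mean`; the severing/growth
#' dynamics then take over).
#'
#' @param params A `bundle_params` object (resolved internally).
#' @return A valid `bundle_state` at `time = 0`.
#' @export
init_bundle <- function(params) {
  p <- resolve_params(params)
  n <- p$N_actin
  fil <- data.frame(
    id = seq_len(n),
    sigma = ifelse(stats::runif(n) < 0.5, 1L, -1L),
    length = draw_lengths(n, p),
    plus_pos = stats::runif(n) * p$L_sys,
    cluster_id = seq_len(n)
  )
  clusters <- data.frame(id = seq_len(n), z_pos = fil$plus_pos)
  m <- p$N_myosin
  myo <- data.frame(id = seq_len(m),
                    center = if (m > 0) stats::runif(m) * p$L_sys else numeric(0),
                    f1 = rep(NA_integer_, m), off1 = rep(NA_real_, m),
                    f2 = rep(NA_integer_, m), off2 = rep(NA_real_, m))
  new_bundle_state(0, fil, clusters, myo, p)
}

#' Draw filament lengths from the configured distribution
#'
#' @param n Number of draws.
#' @param params Resolved `bundle_params`.
#' @return Numeric vector of lengths.
#' @export
draw_lengths <- function(n, params) {
  switch(params$length_mode,
    monodisperse = rep(params$ell_mean, n),
    lognormal = if (attr(params, "sdlog") == 0) rep(params$ell_mean, n) else
      stats::rlnorm(n, attr(params, "meanlog"), attr(params, "sdlog")),
    exponential = stats::rexp(n, rate = 1 / params$ell_mean),
    severing = rep(params$ell_mean, n)
  )
}

#' Check all structural invariants of a bundle state
#'
#' Verifies coordinate ranges, referential integrity of cluster and myosin
#' references, that every clustered filament's plus end coincides with its
#' cluster's position, that no cluster is empty, and that bound myosin site
#' offsets lie within the bound filament and reproduce the site's lab
#' position `plus_pos - sigma * offset` (mod `L_sys`).
#'
#' @param state A `bundle_state`.
#' @param tol Positional tolerance.
#' @return `TRUE` invisibly; errors describing the first violation otherwise.
#' @export
validate_state <- function(state, tol = 1e-9) {
  p <- state$params
  L <- p$L_sys
  fil <- state$fil; cl <- state$clusters; myo <- state$myo
  if (any(fil$plus_pos < 0 | fil$plus_pos >= L)) stop("filament position outside [0, L_sys)")
  if (any(cl$z_pos < 0 | cl$z_pos >= L)) stop("cluster position outside [0, L_sys)")
  if (any(fil$length <= 0)) stop("non-positive filament length")
  if (!all(fil$sigma %in% c(-1L, 1L))) stop("sigma must be +1 or -1")
  if (anyDuplicated(fil$id)) stop("duplicate filament id")
  if (anyDuplicated(cl$id)) stop("duplicate cluster id")
  if (!all(fil$cluster_id %in% cl$id)) stop("dangling cluster reference")
  if (!all(cl$id %in% fil$cluster_id)) stop("empty cluster present")
  z <- cl$z_pos[match(fil$cluster_id, cl$id)]
  if (any(abs(min_image(fil$plus_pos - z, L)) > tol)) {
    stop("clustered filament plus_pos does not equal its cluster z_pos")
  }
  for (s in c(1, 2)) {
    f <- myo[[paste0("f", s)]]
    off <- myo[[paste0("off", s)]]
    b <- !is.na(f)
    if (!all(f[b] %in% fil$id)) stop("myosin site bound to unknown filament")
    i <- match(f[b], fil$id)
    if (any(off[b] < -tol | off[b] > fil$length[i] + tol)) {
      stop("myosin site offset outside [0, filament length]")
    }
    site <- wrap_ring(myo$center[b] + (if (s == 1) -1 else 1) * p$L_my / 2, L)
    lab <- wrap_ring(fil$plus_pos[i] - fil$sigma[i] * off[b], L)
    if (any(abs(min_image(site - lab, L)) > max(tol, 1e-7))) {
      stop("myosin site lab position inconsistent with its offset")
    }
    if (any(fil$sigma[i] != (if (s == 1) -1L else 1L))) {
      stop("myosin site bound to filament of wrong polarity")
    }
  }
  invisible(TRUE)
}

#' @export
print.bundle_state <- function(x, ...) {
  cat(sprintf("bundle_state at t = %.4g: %d filaments in %d clusters, %d myosins\n",
              x$time, nrow(x$fil), nrow(x$clusters), nrow(x$myo)))
  invisible(x)
}

# rows of fil belonging to cluster cid
cluster_members <- function(state, cid) which(state$fil$cluster_id == cid)
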