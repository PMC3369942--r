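#' Simulate an actomyosin bundle
#'
#' Runs the full model from a fresh random initial condition for
#' `T_end / dt` steps, with the fixed per-step ordering documented in
#' [step_bundle()].  The default engine is the compiled core; `engine =
#' "r"` runs the pure-R reference stepper (identical semantics, used for
#' cross-validation and small systems).  Observables are sampled every
#' `sample_dt` time units: cluster positions and weights, myosin centers
#' and bound-site counts, the sarcomeric and myosin order parameters, the
#' cluster count, the Bragg spacing, and the myosin minus-end localization.
#'
#' @param params A [bundle_params()] object.
#' @param T_end Termination time (in units of `ell_mean / v_tread`).
#' @param sample_dt Observable sampling interval.
#' @param seed Integer RNG seed (`set.seed`); `NULL` continues the current
#'   RNG stream.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference stepper).
#' @param log_events Keep a per-event log (time, kind, participants).
#' @param state Optional initial `bundle_state`; default is
#'   [init_bundle()] from `params`.
#' @return An object of class `bundle_trajectory`: list with `series`
#'   (per-sample observables), `clusters` and `myosins` (long tables),
#'   `final_state`, `max_residual`, `counts`, `params`, `seed`.
#' @examples
#' \donttest{
#' tr <- simulate_bundle(bundle_params(N_actin = 30, N_myosin = 0, L_sys = 10),
#'                       T_end = 5, seed = 1)
#' utils::tail(tr$series)
#' }
#' @export
simulate_bundle <- function(params, T_end, sample_dt = 0.5, seed = NULL,
                            engine = c("cpp", "r"), log_events = FALSE,
                            state = NULL) {
  engine <- match.arg(engine)
  p <- resolve_params(params)
  if (T_end <= 0) stop("T_end must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- init_bundle(p) else state$params <- p
  n_steps <- max(1L, as.integer(round(T_end / p$dt)))
  sample_every <- max(1L, as.integer(round(sample_dt / p$dt)))
  if (engine == "cpp") {
    res <- run_core_engine(state, p, n_steps, sample_every, log_events)
  } else {
    res <- run_r_engine(state, p, n_steps, sample_every, log_events)
  }
  res$params <- p
  res$seed <- seed
  res$T_end <- T_end
  res$sample_dt <- sample_dt
  res$engine <- engine
  class(res) <- "bundle_trajectory"
  res
}

# --- compiled engine ---------------------------------------------------------
run_core_engine <- function(state, p, n_steps, sample_every, log_events) {
  fil <- state$fil
  cid0 <- match(fil$cluster_id, state$clusters$id) - 1L
  f1 <- match(state$myo$f1, fil$id) - 1L
  f2 <- match(state$myo$f2, fil$id) - 1L
  f1[is.na(f1)] <- -1L; f2[is.na(f2)] <- -1L
  off1 <- state$myo$off1; off1[is.na(off1)] <- 0
  off2 <- state$myo$off2; off2[is.na(off2)] <- 0
  cst <- list(time = state$time, plus_pos = fil$plus_pos,
              sigma = as.integer(fil$sigma), length = fil$length,
              cluster_id = as.integer(cid0),
              center = state$myo$center, f1 = as.integer(f1),
              f2 = as.integer(f2), off1 = off1, off2 = off2)
  cp <- unclass(p)
  cp$length_mode_code <- length_mode_code(p$length_mode)
  cp$meanlog <- attr(p, "meanlog")
  cp$sdlog <- attr(p, "sdlog")
  out <- core_run(cst, cp, n_steps, sample_every, log_events)
  clusters <- data.frame(sample = out$cl_sample + 1L,
                         time = out$sample_time[out$cl_sample + 1L],
                         z = out$cl_z, w = out$cl_w)
  myosins <- if (length(out$my_sample)) {
    data.frame(sample = out$my_sample + 1L,
               time = out$sample_time[out$my_sample + 1L],
               center = out$my_center, n_bound = out$my_nbound)
  } else {
    data.frame(sample = integer(0), time = numeric(0),
               center = numeric(0), n_bound = integer(0))
  }
  fin <- out$final
  nf <- length(fin$plus_pos)
  final_state <- new_bundle_state(
    time = fin$time,
    fil = data.frame(id = seq_len(nf), sigma = fin$sigma,
                     length = fin$length, plus_pos = fin$plus_pos,
                     cluster_id = fin$cluster_id),
    clusters = data.frame(id = seq_along(fin$cluster_z), z_pos = fin$cluster_z),
    myo = data.frame(id = seq_along(fin$center), center = fin$center,
                     f1 = fin$f1, off1 = fin$off1,
                     f2 = fin$f2, off2 = fin$off2),
    params = p, rng_state = get_rng_snapshot())
  ev <- out$events
  list(series = build_series(out$sample_time, clusters, myosins,
                             out$localization, p),
       clusters = clusters, myosins = myosins,
       final_state = final_state, max_residual = out$max_residual,
       counts = out$counts, events = ev)
}

# --- pure-R reference engine -------------------------------------------------
run_r_engine <- function(state, p, n_steps, sample_every, log_events) {
  times <- c(state$time)
  cl_list <- list(snapshot_clusters(state, 1L))
  my_list <- list(snapshot_myosins(state, 1L))
  loc <- c(localization_or_na(state))
  max_resid <- 0
  isample <- 1L
  for (step in seq_len(n_steps)) {
    st <- step_bundle(state)
    state <- st$state
    max_resid <- max(max_resid, st$residual)
    if (step %% sample_every == 0 || step == n_steps) {
      isample <- isample + 1L
      times <- c(times, state$time)
      cl_list[[isample]] <- snapshot_clusters(state, isample)
      my_list[[isample]] <- snapshot_myosins(state, isample)
      loc <- c(loc, localization_or_na(state))
    }
  }
  clusters <- do.call(rbind, cl_list)
  clusters$time <- times[clusters$sample]
  myosins <- do.call(rbind, my_list)
  if (nrow(myosins)) myosins$time <- times[myosins$sample]
  state$rng_state <- get_rng_snapshot()
  list(series = build_series(times, clusters, myosins, loc, p),
       clusters = clusters, myosins = myosins,
       final_state = state, max_residual = max_resid,
       counts = NULL, events = NULL)
}

snapshot_clusters <- function(state, isample) {
  w <- as.integer(table(factor(state$fil$cluster_id, levels = state$clusters$id)))
  data.frame(sample = isample, time = state$time,
             z = state$clusters$z_pos, w = w)
}

snapshot_myosins <- function(state, isample) {
  m <- nrow(state$myo)
  if (m == 0) {
    return(data.frame(sample = integer(0), time = numeric(0),
                      center = numeric(0), n_bound = integer(0)))
  }
  data.frame(sample = isample, time = state$time, center = state$myo$center,
             n_bound = (!is.na(state$myo$f1)) + (!is.na(state$myo$f2)))
}

localization_or_na <- function(state) {
  tryCatch(myosin_localization(state), error = function(e) NA_real_)
}

get_rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

# per-sample scalar observables from the long tables
build_series <- function(times, clusters, myosins, localization, p) {
  ns <- length(times)
  win <- c(1, 4) * p$ell_mean
  S_star <- lambda_star <- S_my <- rep(NA_real_, ns)
  n_cl <- integer(ns)
  for (i in seq_len(ns)) {
    cl <- clusters[clusters$sample == i, , drop = FALSE]
    n_cl[i] <- nrow(cl)
    if (nrow(cl) > 0) {
      op <- order_parameter(structure_factor(cl$z, cl$w, p$L_sys), win)
      S_star[i] <- op$S_star
      lambda_star[i] <- op$lambda_star
    }
    my <- myosins[myosins$sample == i, , drop = FALSE]
    if (nrow(my) > 0) {
      opm <- order_parameter(structure_factor(my$center, rep(1, nrow(my)),
                                              p$L_sys), win)
      S_my[i] <- opm$S_star
    }
  }
  data.frame(time = times, n_clusters = n_cl, S_star = S_star,
             lambda_star = lambda_star, S_my = S_my,
             nn_mean = p$L_sys / pmax(n_cl, 1),
             localization = localization)
}

#' @export
print.bundle_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf("bundle_trajectory: %d samples to t = %.3g (engine %s)\n",
              nrow(s), max(s$time), x$engine))
  cat(sprintf("  final: %d clusters, S* = %.3f, S*_my = %s\n",
              s$n_clusters[nrow(s)], s$S_star[nrow(s)],
              ifelse(is.na(s$S_my[nrow(s)]), "NA",
                     sprintf("%.3f", s$S_my[nrow(s)]))))
  invisible(x)
}

#' Summarize a trajectory: terminal observables and the ordering time scale
#'
#' "Terminal" values are means over the final `tail_window` time units of
#' the sampled series (the cluster count is reported as its last value,
#' together with its change over the window — zero change indicates a
#' kinetically arrested configuration).  The ordering time scale `tau`
#' comes from [fit_saturation()] on the full `S*(t)` series.
#'
#' @param traj A `bundle_trajectory`.
#' @param tail_window Width of the terminal averaging window (time units).
#' @return One-row data frame of summary observables.
#' @export
summarize_trajectory <- function(traj, tail_window = 10) {
  s <- traj$series
  t_end <- max(s$time)
  tail_sel <- s$time >= t_end - tail_window
  fit <- tryCatch(fit_saturation(s$time, ifelse(is.na(s$S_star), 0, s$S_star)),
                  error = function(e) list(S_sat = NA, tau = NA))
  data.frame(
    T_end = t_end,
    S_star = mean(s$S_star[tail_sel], na.rm = TRUE),
    S_my = if (all(is.na(s$S_my))) NA_real_ else
      mean(s$S_my[tail_sel], na.rm = TRUE),
    n_clusters = s$n_clusters[nrow(s)],
    n_clusters_tail_change = s$n_clusters[which(tail_sel)[1]] -
      s$n_clusters[nrow(s)],
    lambda_star = stats::median(s$lambda_star[tail_sel], na.rm = TRUE),
    nn_mean = s$nn_mean[nrow(s)],
    localization = if (all(is.na(s$localization))) NA_real_ else
      mean(s$localization[tail_sel], na.rm = TRUE),
    tau = fit$tau,
    S_sat = fit$S_sat,
    max_residual = traj$max_residual
  )
}
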