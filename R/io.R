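#' Write a sampled trajectory as delimited text
#'
#' Long format, one row per sampled object:
#' `time, kind, id, position, weight, extra` where `kind` is `"cluster"`
#' (position = Z-band coordinate, weight = filament number) or `"myosin"`
#' (position = center, weight = number of bound sites, extra unused).
#' Output is deterministic: identical trajectories give byte-identical
#' files.
#'
#' @param traj A `bundle_trajectory`.
#' @param dir Output directory (created if needed).
#' @param file File name within `dir`.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, dir, file = "trajectory.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- traj$clusters
  my <- traj$myosins
  long <- rbind(
    data.frame(time = cl$time, kind = "cluster",
               id = stats::ave(cl$sample, cl$sample, FUN = seq_along),
               position = cl$z, weight = cl$w, extra = NA_real_),
    if (nrow(my) > 0) data.frame(time = my$time, kind = "myosin",
                                 id = stats::ave(my$sample, my$sample,
                                                 FUN = seq_along),
                                 position = my$center, weight = my$n_bound,
                                 extra = NA_real_)
  )
  path <- file.path(dir, file)
  utils::write.csv(format_num_df(long), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory file written by [write_trajectory()]
#'
#' The analysis layer operates on these plain tables, so trajectories can
#' be post-processed independently of the simulator.
#'
#' @param path Path to the CSV file (or the directory containing
#'   `trajectory.csv`).
#' @return Data frame with columns `time, kind, id, position, weight, extra`.
#' @export
read_trajectory <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "trajectory.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Order-parameter series from a plain trajectory table
#'
#' Recomputes the sarcomeric and myosin order parameters, cluster counts
#' and spacing from a long trajectory table (as read by
#' [read_trajectory()]), without access to the simulator state.
#'
#' @param tab Long trajectory data frame.
#' @param L_sys Domain size used in the run.
#' @param ell_mean Mean filament length (sets the peak window).
#' @return Per-sample data frame as in `bundle_trajectory$series`.
#' @export
analyze_trajectory_table <- function(tab, L_sys, ell_mean = 1) {
  times <- sort(unique(tab$time))
  win <- c(1, 4) * ell_mean
  rows <- lapply(seq_along(times), function(i) {
    cl <- tab[tab$time == times[i] & tab$kind == "cluster", , drop = FALSE]
    my <- tab[tab$time == times[i] & tab$kind == "myosin", , drop = FALSE]
    op <- if (nrow(cl)) order_parameter(
      structure_factor(cl$position, cl$weight, L_sys), win) else
      list(S_star = NA_real_, lambda_star = NA_real_)
    opm <- if (nrow(my)) order_parameter(
      structure_factor(my$position, rep(1, nrow(my)), L_sys), win)$S_star else
      NA_real_
    data.frame(time = times[i], n_clusters = nrow(cl), S_star = op$S_star,
               lambda_star = op$lambda_star, S_my = opm,
               nn_mean = L_sys / max(nrow(cl), 1))
  })
  do.call(rbind, rows)
}

write_manifest <- function(traj, sc, path) {
  p <- unclass(traj$params)
  p$mu_my <- if (is.na(p$mu_my)) NULL else p$mu_my
  manifest <- list(
    scenario = sc$name,
    params = p,
    T_end = traj$T_end,
    sample_dt = traj$sample_dt,
    seed = traj$seed,
    engine = traj$engine,
    package_version = as.character(utils::packageVersion("sarcsim")),
    rng_kind = RNGkind(),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a flat key-value run configuration
#'
#' Reads a YAML (or JSON) document of `bundle_params` fields plus the run
#' keys `scenario`, `T_end`, `sample_dt`, `replicates`, `seed`.  Unknown
#' keys are rejected with their names.
#'
#' @param path Path to the config file.
#' @return List with `scenario` (a `scenario` object) and `seed`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value document")
  run_keys <- c("scenario", "T_end", "sample_dt", "replicates", "seed")
  par_keys <- names(unclass(bundle_params()))
  unknown <- setdiff(names(cfg), c(run_keys, par_keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  name <- if (!is.null(cfg$scenario)) cfg$scenario else "fig3_myosin"
  overrides <- cfg[setdiff(names(cfg), c("scenario", "seed"))]
  sc <- scenario(name, overrides)
  list(scenario = sc, seed = cfg$seed)
}

#' Save a run configuration
#'
#' Writes a flat YAML document that [load_config()] restores exactly
#' (doubles are serialized at full precision).
#'
#' @param sc A `scenario` object.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return The path, invisibly.
#' @export
save_config <- function(sc, path, seed = NULL) {
  p <- unclass(sc$params)
  p$mu_my <- if (is.na(p$mu_my)) NULL else p$mu_my
  cfg <- c(list(scenario = sc$name), p,
           list(T_end = sc$T_end, sample_dt = sc$sample_dt,
                replicates = sc$replicates))
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

# fixed-notation formatting so written CSVs are platform-stable
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
    }
  }
  df
}
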