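#' Scenario presets
#'
#' Frozen named configurations mirroring the model's canonical numerical
#' experiments:
#' \describe{
#'   \item{fig2_no_friction}{actin-only bundle (no myosin), frictionless
#'     sliding: clusters coalesce into a few very large ones.}
#'   \item{fig2_friction}{same with inter-filament friction `zeta = gamma`:
#'     coalescence arrests kinetically at a finite cluster number.}
#'   \item{fig3_myosin}{full actomyosin bundle at moderate myosin force;
#'     sarcomeric ordering with minus-end (A-band) myosin localization.}
#'   \item{fig3_force_scan}{scan of the active myosin force under the motor
#'     mobility coupling (`v_my0 = mu_my * F_stall`), so the ordering time
#'     scale grows toward the critical force `F* = v_tread / mu_my` (= 5 at
#'     the default `mu_my = 0.2`) beyond which active walking beats
#'     treadmilling and order is lost.}
#'   \item{fig4_polydisperse}{log-normal filament lengths; scan of the
#'     length variability `sigma_ell`.}
#'   \item{fig5_turnover}{catastrophe/renewal turnover; scan of
#'     `k_turnover`.}
#'   \item{fig6_severing}{filament growth plus length-dependent severing
#'     (`r_sever = pi/2` makes the stationary mean length equal
#'     `ell_mean`).}
#' }
#' Changing a preset is a versioned act; use `overrides` for ad-hoc
#' variations.
#'
#' @param name Preset name.
#' @param overrides Named list of `bundle_params` overrides (or `T_end`,
#'   `sample_dt`, `replicates`).
#' @return An object of class `scenario`: list with `name`, `params`,
#'   `T_end`, `sample_dt`, `replicates` and optional `scan`
#'   (`list(param, values)`).
#' @export
scenario <- function(name, overrides = list()) {
  presets <- scenario_presets()
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; see scenario_list()")
  }
  sc <- presets[[name]]
  run_keys <- c("T_end", "sample_dt", "replicates")
  for (key in names(overrides)) {
    if (key %in% run_keys) {
      sc[[key]] <- overrides[[key]]
    } else if (key %in% names(unclass(sc$params))) {
      sc$params[[key]] <- overrides[[key]]
    } else {
      stop("unknown override key '", key, "'")
    }
  }
  validate_params(sc$params)
  sc
}

scenario_presets <- function() {
  base <- bundle_params()
  mk <- function(name, params, T_end = 100, sample_dt = 0.5,
                 replicates = 5, scan = NULL) {
    structure(list(name = name, params = params, T_end = T_end,
                   sample_dt = sample_dt, replicates = replicates,
                   scan = scan), class = "scenario")
  }
  list(
    fig2_no_friction = mk("fig2_no_friction",
      bundle_params(N_actin = 60, N_myosin = 0, zeta = 0), T_end = 50),
    fig2_friction = mk("fig2_friction",
      bundle_params(N_actin = 60, N_myosin = 0, zeta = 1), T_end = 50),
    fig3_myosin = mk("fig3_myosin", base),
    fig3_force_scan = mk("fig3_force_scan",
      bundle_params(),
      scan = list(param = "F_stall", values = c(1.25, 3, 4.75))),
    fig4_polydisperse = mk("fig4_polydisperse",
      bundle_params(length_mode = "lognormal", sigma_ell = 0.25),
      scan = list(param = "sigma_ell", values = c(0, 0.2, 0.4))),
    fig5_turnover = mk("fig5_turnover",
      bundle_params(k_turnover = 0.1),
      scan = list(param = "k_turnover", values = c(0.02, 0.1, 0.3))),
    fig6_severing = mk("fig6_severing",
      bundle_params(length_mode = "severing", r_sever = pi / 2))
  )
}

#' List available scenario presets
#'
#' @return Data frame with one row per preset (name, key parameter
#'   deviations from the defaults, termination time).
#' @export
scenario_list <- function() {
  presets <- scenario_presets()
  base <- unclass(bundle_params())
  rows <- lapply(presets, function(sc) {
    p <- unclass(sc$params)
    diff <- names(p)[vapply(names(p), function(nm) {
      !identical(p[[nm]], base[[nm]])
    }, logical(1))]
    data.frame(name = sc$name,
               overrides = paste(vapply(diff, function(nm) {
                 paste0(nm, "=", format(p[[nm]])) }, character(1)),
                 collapse = ", "),
               T_end = sc$T_end,
               scan = if (is.null(sc$scan)) "" else
                 paste0(sc$scan$param, " in {",
                        paste(sc$scan$values, collapse = ", "), "}"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario '", x$name, "': T_end = ", x$T_end,
      ", sample_dt = ", x$sample_dt, "\n", sep = "")
  if (!is.null(x$scan)) {
    cat("  scan: ", x$scan$param, " in {",
        paste(x$scan$values, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Run a scenario
#'
#' Executes one seeded replicate of a scenario and summarizes it; when
#' `out_dir` is given, writes the sampled trajectory, the summary and a
#' run manifest (resolved parameters, seed, package version) — identical
#' `(scenario, seed)` pairs produce byte-identical trajectory and summary
#' files.
#'
#' @param sc A `scenario` (or preset name).
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param engine Simulation engine, see [simulate_bundle()].
#' @return List with `trajectory` and one-row `summary`.
#' @export
run_scenario <- function(sc, seed, out_dir = NULL, engine = "cpp") {
  if (is.character(sc)) sc <- scenario(sc)
  traj <- simulate_bundle(sc$params, T_end = sc$T_end,
                          sample_dt = sc$sample_dt, seed = seed,
                          engine = engine)
  summ <- cbind(data.frame(scenario = sc$name, seed = seed),
                summarize_trajectory(traj))
  if (!is.null(out_dir)) {
    write_trajectory(traj, out_dir)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    write_manifest(traj, sc, file.path(out_dir, "manifest.json"))
  }
  list(trajectory = traj, summary = summ)
}

#' Scan one parameter across replicate runs
#'
#' Runs `length(values) * length(seeds)` seeded replicates, summarizing
#' each, and aggregates mean and standard error of every observable per
#' parameter value.  The scanned parameter interacts with the motor
#' mobility coupling: in scenarios with `mu_my` set, scanning `F_stall`
#' co-varies the unloaded walking speed.
#'
#' @param sc A `scenario` (or preset name); its `scan` field provides
#'   defaults for `param`/`values`.
#' @param param Name of the `bundle_params` field to vary.
#' @param values Values to scan.
#' @param seeds Integer seeds (replicates per value).
#' @param engine Simulation engine.
#' @return Data frame of per-run summaries (one row per value x seed) with
#'   attribute `aggregate` (mean and s.e. per value).
#' @export
scan_parameter <- function(sc, param = NULL, values = NULL, seeds = 1:5,
                           engine = "cpp") {
  if (is.character(sc)) sc <- scenario(sc)
  if (is.null(param)) {
    if (is.null(sc$scan)) stop("no scan defined; give param/values")
    param <- sc$scan$param
    if (is.null(values)) values <- sc$scan$values
  }
  if (is.null(values) || length(values) == 0) stop("empty value list")
  if (!param %in% names(unclass(sc$params))) {
    stop("unknown parameter '", param, "'")
  }
  rows <- list()
  for (val in values) {
    p <- sc$params
    p[[param]] <- val
    validate_params(p)
    for (sd in seeds) {
      traj <- simulate_bundle(p, T_end = sc$T_end, sample_dt = sc$sample_dt,
                              seed = sd, engine = engine)
      summ <- summarize_trajectory(traj)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(param = param, value = val, seed = sd), summ)
    }
  }
  out <- do.call(rbind, rows)
  num <- c("S_star", "S_my", "n_clusters", "lambda_star", "localization", "tau")
  agg <- do.call(rbind, lapply(split(out, out$value), function(d) {
    row <- data.frame(value = d$value[1], n = nrow(d))
    for (nm in num) {
      x <- d[[nm]]
      row[[paste0(nm, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(nm, "_se")]] <- stats::sd(x, na.rm = TRUE) /
        sqrt(sum(!is.na(x)))
    }
    row
  }))
  agg <- agg[order(agg$value), ]
  rownames(agg) <- NULL
  attr(out, "aggregate") <- agg
  out
}
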