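#' Model parameters for a simulated actomyosin bundle
#'
#' Collects every model constant in simulation units: lengths are measured in
#' the mean actin filament length \eqn{\ell}, time in \eqn{T = \ell/v}, where
#' \eqn{v} is the actin treadmilling speed, and forces in \eqn{\gamma \ell v},
#' where \eqn{\gamma} is the cytosolic drag coefficient per unit filament
#' length.  With the defaults `v_tread = 1`, `gamma = 1`, `ell_mean = 1` all
#' three base units are 1.
#'
#' @param v_tread Actin treadmilling (net polymerization) speed; sets the
#'   time unit \eqn{T = \ell/v}.
#' @param gamma Cytosolic drag coefficient per unit filament length.
#' @param zeta Inter-filament sliding friction per unit overlap length
#'   (0 disables the friction force).
#' @param k0 Plus-end crosslinking rate amplitude.
#' @param delta Crosslinking capture range: two plus-ends at separation
#'   \eqn{d} link at rate \eqn{k_0 \exp(-(d/\delta)^2)}.
#' @param F_stall Active myosin force; equals the myosin stall force.
#' @param v_my0 Unloaded myosin walking speed.  Ignored (recomputed as
#'   `mu_my * F_stall`) when `mu_my` is set.
#' @param mu_my Optional motor mobility (speed per unit force).  When not
#'   `NA`, the unloaded walking speed is tied to the active force,
#'   `v_my0 = mu_my * F_stall`, so that scanning `F_stall` co-varies force
#'   and speed as for a motor whose velocity scale is set by its force scale.
#' @param k_on,k_off Myosin binding-site attachment / detachment rates
#'   (Poisson, constant).
#' @param L_my Length of the bipolar myosin filament (distance between its
#'   two binding sites).
#' @param ell_mean Mean actin filament length (the length unit).
#' @param sigma_ell Relative standard deviation of the filament length
#'   distribution (dimensionless; used by `length_mode = "lognormal"`).
#' @param k_turnover Catastrophe/renewal rate per filament: a filament is
#'   removed wholesale and replaced by a fresh one elsewhere.
#' @param r_sever Severing-agent binding rate per unit filament length
#'   (used by `length_mode = "severing"`).
#' @param k_diss Optional rate at which a single filament spontaneously
#'   dissociates from its cluster (0 = irreversible crosslinking).
#' @param L_sys Size of the periodic simulation domain.
#' @param N_actin,N_myosin Numbers of actin and myosin filaments.
#' @param dt Time step of the fixed-step integrator.
#' @param length_mode One of `"monodisperse"`, `"lognormal"`,
#'   `"exponential"`, `"severing"`.
#' @param ... Ignored; present so that unknown arguments raise an error.
#'
#' @return An object of class `bundle_params` (a named list).
#' @examples
#' p <- bundle_params(N_actin = 20, N_myosin = 0)
#' p$L_sys
#' @export
bundle_params <- function(v_tread = 1, gamma = 1, zeta = 0,
                          k0 = 10, delta = 0.1,
                          F_stall = 0.5, v_my0 = 0.1, mu_my = 0.2,
                          k_on = 10, k_off = 2.5, L_my = 0.5,
                          ell_mean = 1, sigma_ell = 0,
                          k_turnover = 0, r_sever = 0, k_diss = 0,
                          L_sys = 20, N_actin = 100, N_myosin = 100,
                          dt = 1e-3,
                          length_mode = c("monodisperse", "lognormal",
                                          "exponential", "severing"),
                          ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
  }
  length_mode <- match.arg(length_mode)
  p <- list(v_tread = v_tread, gamma = gamma, zeta = zeta,
            k0 = k0, delta = delta,
            F_stall = F_stall, v_my0 = v_my0, mu_my = mu_my,
            k_on = k_on, k_off = k_off, L_my = L_my,
            ell_mean = ell_mean, sigma_ell = sigma_ell,
            k_turnover = k_turnover, r_sever = r_sever, k_diss = k_diss,
            L_sys = L_sys, N_actin = as.integer(N_actin),
            N_myosin = as.integer(N_myosin), dt = dt,
            length_mode = length_mode)
  class(p) <- "bundle_params"
  validate_params(p)
  p
}

#' Validate a `bundle_params` object
#'
#' Checks positivity/sign constraints and mode-specific requirements
#' (`length_mode = "severing"` requires `r_sever > 0` and `k_turnover = 0`).
#'
#' @param p A `bundle_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  num <- c("v_tread", "gamma", "zeta", "k0", "delta", "F_stall", "v_my0",
           "k_on", "k_off", "L_my", "ell_mean", "sigma_ell", "k_turnover",
           "r_sever", "k_diss", "L_sys", "dt")
  for (nm in num) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop("parameter '", nm, "' must be a finite numeric scalar")
    }
  }
  nonneg <- setdiff(num, c("L_sys", "dt"))
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad) > 0) stop("negative parameter(s): ", paste(bad, collapse = ", "))
  if (p$N_actin < 0 || p$N_myosin < 0) stop("filament counts must be >= 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$ell_mean <= 0) stop("ell_mean must be > 0")
  if (p$L_sys <= 2 * p$ell_mean) stop("L_sys must exceed 2 * ell_mean")
  if (p$length_mode == "severing") {
    if (p$r_sever <= 0) stop("length_mode = 'severing' requires r_sever > 0")
    if (p$k_turnover != 0) stop("length_mode = 'severing' requires k_turnover = 0")
  }
  if (!is.na(p$mu_my) && p$mu_my < 0) stop("mu_my must be >= 0 (or NA)")
  invisible(p)
}

#' Resolve derived parameters before a run
#'
#' Applies the optional motor-mobility coupling (`v_my0 = mu_my * F_stall`
#' when `mu_my` is set) and precomputes the log-normal length parameters by
#' moment matching: `meanlog = log(m^2 / sqrt(m^2 + s^2))`,
#' `sdlog = sqrt(log(1 + s^2/m^2))` with `m = ell_mean`,
#' `s = sigma_ell * ell_mean`, so the draws have exactly the requested mean
#' and standard deviation.
#'
#' @param p A `bundle_params` object.
#' @return A `bundle_params` object with `v_my0` resolved and attributes
#'   `meanlog`/`sdlog` set.
#' @export
resolve_params <- function(p) {
  validate_params(p)
  if (!is.na(p$mu_my)) p$v_my0 <- p$mu_my * p$F_stall
  if (p$N_myosin > 0 && p$F_stall > 0 && p$v_my0 <= 0) {
    stop("v_my0 must be > 0 when myosins with F_stall > 0 are present")
  }
  m <- p$ell_mean
  s <- p$sigma_ell * p$ell_mean
  if (s > 0) {
    attr(p, "meanlog") <- log(m^2 / sqrt(m^2 + s^2))
    attr(p, "sdlog") <- sqrt(log(1 + s^2 / m^2))
  } else {
    attr(p, "meanlog") <- log(m)
    attr(p, "sdlog") <- 0
  }
  p
}

#' @export
print.bundle_params <- function(x, ...) {
  cat("Actomyosin bundle parameters (simulation units: ell, T = ell/v, gamma*ell*v)\n")
  flat <- unclass(x)
  for (nm in names(flat)) {
    cat(sprintf("  %-11s %s\n", nm, format(flat[[nm]])))
  }
  invisible(x)
}

# integer code used by the C++ core
length_mode_code <- function(mode) {
  match(mode, c("monodisperse", "lognormal", "exponential", "severing")) - 1L
}
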