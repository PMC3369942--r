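#' Structure factor of weighted positions on the ring
#'
#' The regularity of the cluster arrangement is quantified by the squared
#' amplitude of the weighted Fourier sum of cluster positions,
#' \deqn{S(q_m) = \left| \sum_a w_a e^{i q_m X_a} \right|^2 / \left(\sum_a w_a\right)^2,}
#' evaluated only at ring-commensurate wave vectors
#' \eqn{q_m = 2\pi m / L_{sys}}, `m = 1..m_max`, so that periodicity is
#' exact.  Weights are cluster filament numbers and positions the cluster
#' (plus-end) coordinates.  `S` is translation invariant and bounded in
#' `[0, 1]`; a perfectly periodic lattice shows Bragg peaks with `S = 1`.
#'
#' @param positions Coordinates of the clusters.
#' @param weights Non-negative weights (filament numbers); must not sum to 0.
#' @param L_sys Domain size.
#' @param m_max Largest mode index (default: modes down to wavelength
#'   `L_sys/m_max = 0.5`).
#' @return Data frame of class `structure_factor_curve`: `m`, `q`,
#'   `wavelength`, `S`.
#' @export
structure_factor <- function(positions, weights, L_sys, m_max = NULL) {
  if (length(positions) == 0) stop("empty input")
  if (length(weights) != length(positions)) stop("positions/weights length mismatch")
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be >= 0 and sum > 0")
  if (is.null(m_max)) m_max <- max(1L, floor(2 * L_sys))
  m <- seq_len(m_max)
  q <- 2 * pi * m / L_sys
  ph <- outer(q, positions)  # m_max x n
  amp2 <- (as.vector(cos(ph) %*% weights))^2 + (as.vector(sin(ph) %*% weights))^2
  out <- data.frame(m = m, q = q, wavelength = L_sys / m, S = amp2 / sum(weights)^2)
  class(out) <- c("structure_factor_curve", class(out))
  out
}

#' Sarcomeric order parameter from the principal Bragg peak
#'
#' The height of the principal Bragg peak of the structure factor within a
#' wavelength window defines the sarcomeric order parameter `S*`; the peak
#' wavelength `lambda*` estimates the sarcomere spacing.  The default
#' window `[1, 4] * ell_mean` excludes the trivial long-wavelength modes: a
#' fully coalesced two-blob state would otherwise score as "ordered" even
#' though it has no sarcomeric repeat.  Ties take the smallest mode index
#' (longest wavelength); peaks within a relative 1e-12 of the maximum count
#' as tied, so that a perfect lattice — whose fundamental and harmonics are
#' analytically equal but differ by rounding — reports the fundamental.
#'
#' @param curve A `structure_factor_curve` from [structure_factor()].
#' @param wavelength_window `c(lambda_min, lambda_max)`.
#' @return List with `S_star` in `[0, 1]` and `lambda_star`.
#' @export
order_parameter <- function(curve, wavelength_window = c(1, 4)) {
  sel <- curve$wavelength >= wavelength_window[1] &
    curve$wavelength <= wavelength_window[2]
  if (!any(sel)) stop("wavelength window contains no ring-commensurate mode")
  cs <- curve[sel, , drop = FALSE]
  top <- max(cs$S)
  best <- which(cs$S >= top * (1 - 1e-12))
  best <- best[which.min(cs$m[best])]
  list(S_star = cs$S[best], lambda_star = cs$wavelength[best])
}

#' Sarcomeric order parameter of a bundle state
#'
#' Convenience wrapper: structure factor over cluster positions with
#' filament-number weights, windowed peak per [order_parameter()].
#'
#' @param state A `bundle_state`.
#' @param wavelength_window Passed to [order_parameter()].
#' @return List with `S_star` and `lambda_star`.
#' @export
bundle_order_parameter <- function(state, wavelength_window = NULL) {
  p <- state$params
  if (is.null(wavelength_window)) wavelength_window <- c(1, 4) * p$ell_mean
  w <- as.numeric(table(factor(state$fil$cluster_id, levels = state$clusters$id)))
  sf <- structure_factor(state$clusters$z_pos, w, p$L_sys)
  order_parameter(sf, wavelength_window)
}

#' Order parameter for myosin positions
#'
#' The analogously defined order parameter computed from myosin centers
#' with unit weights and the same wavelength window: regular A-bands give a
#' myosin Bragg peak even when the actin cluster arrangement is imperfect.
#'
#' @param state A `bundle_state`.
#' @param wavelength_window Passed to [order_parameter()].
#' @return List with `S_star` and `lambda_star`.
#' @export
myosin_order_parameter <- function(state, wavelength_window = NULL) {
  if (nrow(state$myo) < 1) stop("no myosins in state")
  p <- state$params
  if (is.null(wavelength_window)) wavelength_window <- c(1, 4) * p$ell_mean
  sf <- structure_factor(state$myo$center, rep(1, nrow(state$myo)), p$L_sys)
  order_parameter(sf, wavelength_window)
}

#' Number of actin clusters
#'
#' Single (uncrosslinked) filaments are singleton clusters and count as one
#' cluster each.
#'
#' @param state A `bundle_state`.
#' @return Integer cluster count.
#' @export
cluster_count <- function(state) nrow(state$clusters)

#' Sarcomere spacing estimates
#'
#' Returns the Bragg-peak wavelength `lambda_star` (the informative spacing
#' estimate) together with the mean ring gap between circularly sorted
#' cluster positions.  Note that on a ring the gaps telescope, so
#' `nn_mean = L_sys / M` exactly regardless of the arrangement — it is
#' reported for completeness and as a consistency check, while `lambda_star`
#' carries the actual spacing information.
#'
#' @param state A `bundle_state`.
#' @return List with `lambda_star` and `nn_mean`.
#' @export
sarcomere_spacing <- function(state) {
  lam <- bundle_order_parameter(state)$lambda_star
  if (nrow(state$clusters) < 2) {
    stop("nn_mean undefined for fewer than 2 clusters (lambda_star = ",
         format(lam), ")")
  }
  z <- sort(state$clusters$z_pos)
  gaps <- c(diff(z), state$params$L_sys - (z[length(z)] - z[1]))
  list(lambda_star = lam, nn_mean = mean(gaps))
}

#' Fraction of bound myosin heads near actin minus ends
#'
#' Mean over bound myosin sites of `offset / filament_length`, a number in
#' `[0, 1]`: values near 1 mean myosin sits at the depolymerizing minus
#' ends (correct, A-band-like localization produced by the actin conveyor
#' belt), values near 0 mean myosin has been pulled to the plus ends at the
#' Z-bands (wrong polarity sorting, as when active walking beats
#' treadmilling).
#'
#' @param state A `bundle_state`.
#' @return Mean relative offset; errors when no site is bound.
#' @export
myosin_localization <- function(state) {
  fil <- state$fil
  vals <- c()
  for (s in c(1, 2)) {
    f <- state$myo[[paste0("f", s)]]
    off <- state$myo[[paste0("off", s)]]
    b <- !is.na(f)
    if (any(b)) vals <- c(vals, off[b] / fil$length[match(f[b], fil$id)])
  }
  if (length(vals) == 0) stop("no bound myosin site; localization undefined")
  mean(vals)
}

#' Fit an exponential saturation curve to an order-parameter time series
#'
#' Least-squares fit of \eqn{S(t) = S_{sat} (1 - e^{-t/\tau})}, the
#' saturation law that describes the growth of sarcomeric order; `tau` is
#' the ordering time scale.  The fit is deterministic given the data: fixed
#' initialization `S_sat0 = max(S)`, `tau0` = time at half-maximum, with
#' `tau` bounded positive (Levenberg-Marquardt via [minpack.lm::nlsLM]).
#'
#' @param times Sample times (>= 0, length >= 5).
#' @param S_values Order parameter values.
#' @return List with `S_sat`, `tau`, `rms_residual`, and `degenerate`
#'   (`TRUE` with `tau = NA` for all-zero or constant data).
#' @export
fit_saturation <- function(times, S_values) {
  if (length(times) < 5) stop("need at least 5 points")
  if (any(times < 0)) stop("times must be >= 0")
  if (length(times) != length(S_values)) stop("length mismatch")
  if (all(S_values == 0)) {
    return(list(S_sat = 0, tau = NA_real_, rms_residual = 0, degenerate = TRUE))
  }
  if (stats::sd(S_values) == 0) {
    # constant nonzero data: the tau -> 0 step-function limit
    return(list(S_sat = S_values[1], tau = NA_real_,
                rms_residual = 0, degenerate = TRUE))
  }
  S0 <- max(S_values)
  half <- which(S_values >= S0 / 2)
  tau0 <- if (length(half)) max(times[half[1]], min(times[times > 0])) else
    stats::median(times)
  df <- data.frame(t = times, S = S_values)
  fit <- tryCatch(
    minpack.lm::nlsLM(S ~ Ssat * (1 - exp(-t / tau)), data = df,
                      start = list(Ssat = S0, tau = tau0),
                      lower = c(0, 1e-8), upper = c(1.5, 1e6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(S_sat = mean(S_values), tau = NA_real_,
                rms_residual = stats::sd(S_values), degenerate = TRUE))
  }
  co <- stats::coef(fit)
  res <- df$S - co[["Ssat"]] * (1 - exp(-df$t / co[["tau"]]))
  list(S_sat = co[["Ssat"]], tau = co[["tau"]],
       rms_residual = sqrt(mean(res^2)),
       degenerate = co[["tau"]] <= 1e-6)
}

#' Stationary filament length distribution under severing
#'
#' For filaments that grow at their plus end at speed `v` and are cut at a
#' uniformly distributed point at total hazard `r * l` (severing agents
#' bind anywhere along the filament, so long filaments are better
#' "antennas"), the stationary density obeys the balance
#' \deqn{v\,p'(l) = r\,(1 - P(l)) - r\,l\,p(l),}
#' with CDF `P`, `p(0) = 0`, `p'(0) = r/v`, and `p -> 0` at infinity.  The
#' closed first-order system `(p, P)` is integrated from `l = 0` (deSolve)
#' up to `8 * sqrt(v/r)` and normalized; this turns the integro-differential
#' stationary equation into an ODE.  The solution is unimodal with mean
#' proportional to `sqrt(v/r)`.
#'
#' @param v_tread Growth speed (> 0).
#' @param r_sever Severing rate per unit length (> 0).
#' @param l_grid Optional grid of lengths; default 2001 points on
#'   `[0, 8 * sqrt(v/r)]`.
#' @return Data frame `l`, `pdf`, `cdf`.
#' @export
severing_steady_pdf <- function(v_tread, r_sever, l_grid = NULL) {
  if (v_tread <= 0 || r_sever <= 0) stop("v_tread and r_sever must be > 0")
  lam <- sqrt(v_tread / r_sever)
  if (is.null(l_grid)) l_grid <- seq(0, 8 * lam, length.out = 2001)
  if (l_grid[1] != 0) l_grid <- c(0, l_grid)
  deriv <- function(l, y, parms) {
    list(c(dp = (r_sever * (1 - y[2]) - r_sever * l * y[1]) / v_tread,
           dP = y[1]))
  }
  sol <- deSolve::ode(y = c(p = 0, P = 0), times = l_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  p <- pmax(sol[, "p"], 0)
  l <- sol[, "time"]
  norm <- sum(diff(l) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  p <- p / norm
  cdf <- c(0, cumsum(diff(l) * (utils::head(p, -1) + utils::tail(p, -1)) / 2))
  data.frame(l = l, pdf = p, cdf = pmin(cdf, 1))
}

#' Sample stationary filament lengths from the severing process
#'
#' Event-driven (exact) simulation of a single filament growing at
#' `v_tread` with severing hazard `r_sever * l(t)`: waiting times come from
#' inverting the integrated hazard \eqn{r (l_0 t + v t^2/2)} against a unit
#' exponential, the surviving length after a cut is uniform on `(0, l)`.
#' Lengths are recorded at regular time intervals after a burn-in, giving
#' draws from the stationary distribution.
#'
#' @param n Number of samples.
#' @param v_tread,r_sever Process rates (> 0).
#' @param spacing Time between recorded samples (default: the relaxation
#'   scale `sqrt(v/r) / v`).
#' @param burn_in Equilibration time before sampling starts.
#' @param l0 Initial length.
#' @return Numeric vector of `n` sampled lengths.
#' @export
sample_severing_lengths <- function(n, v_tread, r_sever, spacing = NULL,
                                    burn_in = NULL, l0 = NULL) {
  if (v_tread <= 0 || r_sever <= 0) stop("v_tread and r_sever must be > 0")
  lam <- sqrt(v_tread / r_sever)
  if (is.null(spacing)) spacing <- lam / v_tread
  if (is.null(burn_in)) burn_in <- 50 * lam / v_tread
  if (is.null(l0)) l0 <- lam
  t_now <- 0
  l <- l0
  next_cut_time <- function() {
    E <- stats::rexp(1)
    # solve r*(l*t + v*t^2/2) = E for t > 0
    (-l + sqrt(l^2 + 2 * v_tread * E / r_sever)) / v_tread
  }
  t_cut <- t_now + next_cut_time()
  out <- numeric(n)
  k <- 0
  t_sample <- burn_in
  while (k < n) {
    if (t_cut <= t_sample) {
      l <- l + v_tread * (t_cut - t_now)
      l <- stats::runif(1) * l
      t_now <- t_cut
      t_cut <- t_now + next_cut_time()
    } else {
      k <- k + 1
      out[k] <- l + v_tread * (t_sample - t_now)
      t_sample <- t_sample + spacing
    }
  }
  out
}
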