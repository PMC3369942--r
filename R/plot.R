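#' Kymograph of cluster trajectories
#'
#' Space-time plot of the sampled cluster positions; point size and color
#' encode the cluster filament number, so coalescence appears as merging
#' world lines and kinetic arrest as parallel tilted lines (a small
#' orientation imbalance moves the whole arrested bundle).
#'
#' @param traj A `bundle_trajectory`.
#' @param file Optional PNG path; default plots to the active device.
#' @param show_myosin Overlay myosin centers (grey).
#' @return `NULL`, invisibly.
#' @export
plot_kymograph <- function(traj, file = NULL, show_myosin = TRUE) {
  cl <- traj$clusters
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(max(cl$w), "viridis")
  graphics::plot(cl$time, cl$z, pch = 16, cex = 0.3 + 0.8 * sqrt(cl$w / max(cl$w)),
                 col = pal[cl$w], xlab = "time [ell/v]", ylab = "position [ell]",
                 main = "cluster kymograph")
  if (show_myosin && nrow(traj$myosins) > 0) {
    my <- traj$myosins[traj$myosins$n_bound > 0, ]
    graphics::points(my$time, my$center, pch = ".", col = "grey50")
  }
  invisible(NULL)
}
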