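#' Wrap a coordinate onto the periodic ring [0, L)
#'
#' @param x Numeric vector of coordinates (must be finite).
#' @param L_sys Positive domain size.
#' @return `x` reduced modulo `L_sys` into `[0, L_sys)`.
#' @examples
#' wrap_ring(21, 20)    # 1
#' wrap_ring(-0.5, 20)  # 19.5
#' wrap_ring(20, 20)    # 0
#' @export
wrap_ring <- function(x, L_sys) {
  if (L_sys <= 0) stop("L_sys must be > 0")
  if (any(!is.finite(x))) stop("non-finite coordinate")
  r <- x - floor(x / L_sys) * L_sys
  r[r >= L_sys] <- r[r >= L_sys] - L_sys
  r[r < 0] <- r[r < 0] + L_sys
  r
}

#' Minimum-image displacement on a periodic ring
#'
#' Returns the representative of `dx` modulo `L_sys` lying in
#' `[-L_sys/2, L_sys/2)`; the tie at exactly `L_sys/2` is broken toward the
#' negative value so results are bit-reproducible.
#'
#' @param dx Numeric vector of displacements.
#' @param L_sys Positive domain size.
#' @return Signed displacements in `[-L_sys/2, L_sys/2)`.
#' @examples
#' min_image(19 - 1, 20)  # -2
#' min_image(3, 20)       # 3
#' min_image(10, 20)      # -10
#' @export
min_image <- function(dx, L_sys) {
  if (L_sys <= 0) stop("L_sys must be > 0")
  if (any(!is.finite(dx))) stop("non-finite displacement")
  m <- dx - floor(dx / L_sys) * L_sys
  m[m >= L_sys / 2] <- m[m >= L_sys / 2] - L_sys
  m
}

#' Axial span of a filament
#'
#' A filament of orientation `sigma = +1` has its plus-end facing +x and its
#' body behind it: span `[plus_pos - length, plus_pos]`; for `sigma = -1` the
#' span is `[plus_pos, plus_pos + length]`.  Both are interpreted modulo
#' `L_sys`.  Endpoints are always derived from `(plus_pos, sigma, length)`;
#' the minus end is never stored.
#'
#' @param plus_pos Plus-end coordinate.
#' @param sigma Orientation, `+1` or `-1`.
#' @param length Filament length (> 0).
#' @return `c(lo, hi)` of the unwrapped span (lo <= hi, may exceed domain).
#' @export
filament_span <- function(plus_pos, sigma, length) {
  if (sigma == 1) c(plus_pos - length, plus_pos) else c(plus_pos, plus_pos + length)
}

#' Mutual overlap length of two filaments on the ring
#'
#' Length of the intersection of the two axial spans under the
#' minimum-image convention (two filaments can interact only where their
#' projections on the bundle axis overlap); 0 when disjoint.  Handles spans
#' that wrap across the periodic boundary, including the degenerate case
#' where the combined length exceeds the domain and the spans intersect on
#' both sides of the ring.
#'
#' @param f1,f2 Lists with fields `plus_pos`, `sigma`, `length`.
#' @param L_sys Domain size.
#' @return Overlap length `>= 0` (at most `min(l1, l2)`).
#' @export
filament_overlap <- function(f1, f2, L_sys) {
  overlap_ring(span_center(f1), f1$length, span_center(f2), f2$length, L_sys)
}

span_center <- function(f) f$plus_pos - f$sigma * f$length / 2

# overlap of two arcs given centers and lengths (vectorized)
overlap_ring <- function(c1, l1, c2, l2, L_sys) {
  dc <- abs(min_image(c1 - c2, L_sys))
  cap <- pmin(l1, l2)
  ov <- pmin(pmax((l1 + l2) / 2 - dc, 0), cap)
  # second image: arcs so long that they also meet on the far side
  second <- (l1 + l2) / 2 - (L_sys - dc)
  sel <- second > 0
  if (any(sel)) ov[sel] <- pmin(ov[sel] + second[sel], cap[sel])
  ov
}
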