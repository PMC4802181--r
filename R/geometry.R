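#' Estimate an equivalent-disc radius from a projected area
#'
#' 2D-projected nuclear and chromosome-territory regions are summarized by
#' the radius of the disc with the same area: `r = sqrt(area / pi)`.
#'
#' @param area Projected area (> 0), any squared length unit.
#' @return Radius in the corresponding length unit.
#' @export
radius_from_area <- function(area) {
  if (any(area <= 0)) stop("area must be > 0")
  sqrt(area / pi)
}

#' Projected nuclear/territory geometry for the association null
#'
#' @param nuc_rad Average nuclear radius.
#' @param ct_rad Average chromosome-territory radius (0 < ct_rad <=
#'   nuc_rad).
#' @param delta Edge-edge distance threshold between a nuclear body and
#'   the territory (>= 0). All three in the same length unit (pixels or
#'   microns).
#' @return An object of class `projected_geometry`.
#' @export
projected_geometry <- function(nuc_rad, ct_rad, delta) {
  stopifnot(nuc_rad > 0, ct_rad > 0, ct_rad <= nuc_rad, delta >= 0)
  structure(list(nuc_rad = nuc_rad, ct_rad = ct_rad, delta = delta),
            class = "projected_geometry")
}

#' Theoretical random body-territory association probability
#'
#' Under the concentric-disc model, a body centre placed uniformly in the
#' nuclear disc is "associated" with the territory when its edge-edge
#' distance to the concentric territory disc is at most `delta`, i.e. when
#' the centre falls within radius `ct_rad + delta`. The probability is the
#' area ratio `min(1, (ct_rad + delta)^2 / nuc_rad^2)`, invariant under
#' joint rescaling of all lengths and monotone in `delta` and `ct_rad`.
#'
#' @param g A [projected_geometry()].
#' @return Probability in [0, 1].
#' @export
expected_association_probability <- function(g) {
  stopifnot(inherits(g, "projected_geometry"))
  min(1, (g$ct_rad + g$delta)^2 / g$nuc_rad^2)
}

#' Monte-Carlo oracle for the association probability
#'
#' Places body centres uniformly in the nuclear disc and measures the
#' fraction within edge distance `delta` of the territory. Under the
#' default concentric placement this estimates the closed form of
#' [expected_association_probability()]; with `placement = "random"` the
#' territory centre is itself drawn uniformly subject to containment in
#' the nucleus.
#'
#' @param g A [projected_geometry()].
#' @param n_draws Number of draws (> 0).
#' @param placement `"concentric"` (default) or `"random"`.
#' @param seed Integer seed.
#' @return List: `estimate`, `se` (binomial), `n_draws`, `placement`.
#' @export
monte_carlo_association <- function(g, n_draws = 1e6,
                                    placement = c("concentric", "random"),
                                    seed = 1L) {
  stopifnot(inherits(g, "projected_geometry"), n_draws > 0)
  placement <- match.arg(placement)
  withr::local_seed(seed)
  th <- stats::runif(n_draws, 0, 2 * pi)
  rr <- g$nuc_rad * sqrt(stats::runif(n_draws))
  x <- rr * cos(th); y <- rr * sin(th)
  if (placement == "concentric") {
    ctx <- 0; cty <- 0
  } else {
    maxc <- g$nuc_rad - g$ct_rad
    th2 <- stats::runif(n_draws, 0, 2 * pi)
    rc <- maxc * sqrt(stats::runif(n_draws))
    ctx <- rc * cos(th2); cty <- rc * sin(th2)
  }
  edge <- sqrt((x - ctx)^2 + (y - cty)^2) - g$ct_rad
  assoc <- edge <= g$delta
  p <- mean(assoc)
  list(estimate = p, se = sqrt(p * (1 - p) / n_draws),
       n_draws = n_draws, placement = placement)
}
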