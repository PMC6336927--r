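# Shared fixtures: small axis-aligned square-lattice module sets keep
# phase arithmetic exact and oracles computable by hand.

sq_ms <- function(scale, bins_a = 5L, bins_b = bins_a) {
  suppressWarnings(
    module_set(scale = scale, orientation = 0, lattice = "square",
               bins_a = bins_a, bins_b = bins_b)
  )
}

# One-axis "1D" modules: integer period along x, trivial y axis.
line_ms <- function(periods) {
  sq_ms(scale = periods, bins_a = as.integer(periods), bins_b = 1L)
}

phase_mat_of <- function(code) cbind(code$pa, code$pb)

lc <- function(..., frame = "environment") {
  location_code(matrix(c(...), ncol = 2, byrow = TRUE), frame = frame)
}

# Exploration trace from a matrix of absolute integer waypoints, with a
# feature sensed at each.
waypoint_trace <- function(points, features) {
  prev <- rbind(c(0, 0), points[-nrow(points), , drop = FALSE])
  exploration_trace(data.frame(
    dx = points[, 1] - prev[, 1],
    dy = points[, 2] - prev[, 2],
    feature = features
  ))
}
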