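# Internal helpers shared across the package.

# Reduce into [0, 1).  Guard against the float artefact where x %% 1
# returns exactly 1 for tiny negative x.
mod1 <- function(x) {
  r <- x %% 1
  r[r >= 1] <- 0
  r
}

# Edge tolerance for binning: a phase within this of a bin edge is
# assigned to the upper bin, so that exact rational phases survive
# floating-point round-off (e.g. 4/3 mod 1 times 3 is 0.999...98).
BIN_EPS <- 1e-9

# Phase -> bin index, half-open bins [k/bins, (k+1)/bins).
bin_index <- function(p, bins) {
  floor(p * bins + BIN_EPS) %% bins
}

# Circular distance on the unit phase circle, elementwise.
circ_dist <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 1 - d)
}

assert_len2 <- function(v, what = "movement") {
  if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v))) {
    rlang::abort(
      sprintf("`%s` must be a finite numeric vector of length 2.", what),
      class = "cortexgrid_bad_vector"
    )
  }
  invisible(v)
}

`%||%` <- rlang::`%||%`
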