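#' Location codes: joint phase across a module set
#'
#' A location code holds one phase pair per module plus a reference-frame
#' tag (an object identifier, or the distinguished frames `"body"` /
#' `"environment"`).  The same physical point has a different code in each
#' frame; frames are carried data and are never inferred.
#'
#' @param phases An `M x 2` numeric matrix (or a data frame with columns
#'   `pa`, `pb`) of per-module phases; values are reduced modulo 1.
#' @param frame Reference-frame tag (single string).
#' @return A tibble of class `location_code` with columns `module`, `pa`,
#'   `pb` and a `frame` attribute (see [code_frame()]).
#' @examples
#' location_code(matrix(c(0.2, 0.7), 1), frame = "environment")
#' @export
location_code <- function(phases, frame = "environment") {
  if (is.data.frame(phases)) {
    phases <- cbind(phases$pa, phases$pb)
  }
  phases <- matrix(as.double(phases), ncol = 2)
  code <- tibble::tibble(
    module = seq_len(nrow(phases)),
    pa = mod1(phases[, 1]),
    pb = mod1(phases[, 2])
  )
  attr(code, "frame") <- as.character(frame)
  class(code) <- c("location_code", class(tibble::tibble()))
  code
}

#' @rdname location_code
#' @param code A `location_code` or `displacement_code`.
#' @export
code_frame <- function(code) attr(code, "frame")

# Interleaved phase vector (a1, b1, a2, b2, ...), matching wtl_matrix().
phase_vec <- function(code) {
  as.vector(rbind(code$pa, code$pb))
}

phase_mat <- function(code) cbind(code$pa, code$pb)

check_conforms <- function(code, ms, what = "code") {
  if (nrow(code) != nrow(ms)) {
    rlang::abort(
      sprintf("`%s` has %d modules but the module set has %d.",
              what, nrow(code), nrow(ms)),
      class = "cortexgrid_length_mismatch"
    )
  }
  invisible(code)
}

#' Path-integrate a location code
#'
#' Updates every module's phase from a self-motion (efference copy)
#' vector: the world movement is converted to each module's lattice
#' coordinates, added to the phase, and reduced modulo 1.  Because the
#' update is linear in the movement, returning to the same physical point
#' restores the same code regardless of the path taken.  Optional additive
#' Gaussian phase noise (per module, per axis) models integration drift;
#' it is off whenever `noise_sd` is 0 in the module set.
#'
#' @param code A `location_code`.
#' @param ms The owning `module_set`.
#' @param movement 2D world vector `c(dx, dy)`.
#' @return The updated `location_code`; the frame tag is preserved.
#' @examples
#' ms <- module_set(scale = 2)
#' integrate_code(location_code(matrix(0, 1, 2)), ms, c(1, 0))
#' @export
integrate_code <- function(code, ms, movement) {
  check_conforms(code, ms)
  assert_len2(movement)
  lat <- wtl_matrix(ms) %*% movement
  p <- phase_vec(code) + as.vector(lat)
  if (any(ms$noise_sd > 0)) {
    p <- p + stats::rnorm(length(p), sd = rep(ms$noise_sd, each = 2))
  }
  out <- location_code(matrix(mod1(p), ncol = 2, byrow = TRUE),
                       frame = code_frame(code))
  out
}

#' Discretize a location code to its active cells
#'
#' Each module activates the single cell whose half-open phase bin
#' `[k/bins, (k+1)/bins)` contains the module's phase.  The resulting
#' per-module cell indices form the code key used as an identity for
#' associative storage: exact on bins, stable under phase perturbations
#' smaller than the distance to the nearest bin edge.
#'
#' @inheritParams integrate_code
#' @return A tibble of class `code_key` with columns `module`, `ca`, `cb`
#'   (0-based cell indices).
#' @seealso [key_string()] for the canonical serialized form.
#' @examples
#' ms <- module_set(scale = 1, bins_a = 5)
#' discretize(location_code(matrix(c(0.999, 0.5), 1)), ms)
#' @export
discretize <- function(code, ms) {
  check_conforms(code, ms)
  key <- tibble::tibble(
    module = ms$module,
    ca = as.integer(bin_index(code$pa, ms$bins_a)),
    cb = as.integer(bin_index(code$pb, ms$bins_b))
  )
  class(key) <- c("code_key", class(tibble::tibble()))
  key
}

#' Canonical string form of a code key
#'
#' Serializes per-module cell indices as `"ca.cb|ca.cb|..."`; used as the
#' associative-map key in object models and as the sequence symbol for
#' behaviors.
#'
#' @param key A `code_key` (or displacement key) tibble.
#' @return A single string.
#' @export
key_string <- function(key) {
  paste(key$ca, key$cb, sep = ".", collapse = "|")
}

parse_key_string <- function(s) {
  parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ".", fixed = TRUE)
  m <- vapply(parts, function(p) as.integer(p), integer(2))
  key <- tibble::tibble(module = seq_len(ncol(m)),
                        ca = m[1, ], cb = m[2, ])
  class(key) <- c("code_key", class(tibble::tibble()))
  key
}

# Phase code at the centers of a key's bins.
bin_center_code <- function(key, ms, frame = "environment") {
  location_code(
    cbind((key$ca + 0.5) / ms$bins_a, (key$cb + 0.5) / ms$bins_b),
    frame = frame
  )
}

#' Circular phase distance between two codes
#'
#' The maximum, over modules and lattice axes, of the circular distance
#' `min(|d|, 1 - |d|)` between corresponding phases.  Symmetric, zero iff
#' the codes are equal; used for tolerance comparisons of continuous
#' phases (key equality is exact on bins instead).
#'
#' @param a,b Location codes (or displacement codes) over the same module
#'   set.
#' @return A single non-negative number, at most 0.5.
#' @examples
#' phase_distance(location_code(matrix(c(0.99, 0), 1)),
#'                location_code(matrix(c(0.01, 0), 1)))
#' @export
phase_distance <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    rlang::abort("Codes have different module counts.",
                 class = "cortexgrid_length_mismatch")
  }
  max(circ_dist(delta_vec(a), delta_vec(b)))
}

# Phase vector for either location or displacement codes.
delta_vec <- function(code) {
  if ("pa" %in% names(code)) {
    as.vector(rbind(code$pa, code$pb))
  } else {
    as.vector(rbind(code$da, code$db))
  }
}

#' Representational capacity of a module set
#'
#' The number of distinct code keys, i.e. the product over modules of
#' `bins_a * bins_b`.  Capacity grows exponentially with the number of
#' modules: ten modules of 20 cells each already distinguish 20^10
#' locations before the joint code repeats.
#'
#' @param ms A `module_set`.
#' @return A double (capacities overflow 32-bit integers quickly).
#' @examples
#' capacity(module_set(scale = rep(1, 10), bins_a = 5, bins_b = 4))
#' @export
capacity <- function(ms) {
  prod(as.double(ms$bins_a) * as.double(ms$bins_b))
}

#' Draw a random location code (anchoring)
#'
#' Anchoring selects which cell in each module is active at the current
#' location; entering a novel object or environment is modeled as drawing
#' independent uniform phases per module.  Randomness comes from R's
#' global RNG, so results are reproducible under `set.seed()`.
#'
#' @param ms A `module_set`.
#' @param frame Frame tag for the new code.
#' @return A `location_code`.
#' @examples
#' set.seed(1)
#' random_code(default_module_set(2), frame = "cup")
#' @export
random_code <- function(ms, frame = "environment") {
  location_code(matrix(stats::runif(2 * nrow(ms)), ncol = 2),
                frame = frame)
}

#' Count distinct code keys over an arena
#'
#' Brute-force oracle for capacity: sweeps a rectangular arena on a
#' regular grid of sample points, encodes each point (world position
#' pushed through each module's lattice transform, reduced mod 1,
#' discretized) and counts distinct keys.  Never exceeds [capacity()];
#' equality is reached when the arena spans the joint period of modules
#' with commensurate coprime integer periods.
#'
#' @param ms A `module_set`.
#' @param xlim,ylim Arena extent `c(lo, hi)`; a degenerate limit (lo ==
#'   hi) gives a line or a single point.
#' @param step Sample spacing (must tile the arena evenly).
#' @return Number of distinct keys (double).
#' @examples
#' ms <- module_set(scale = c(2, 3, 5), bins_a = c(2, 3, 5), bins_b = 1)
#' enumerate_unique_keys(ms, xlim = c(0, 29), ylim = c(0, 0), step = 1)
#' @export
enumerate_unique_keys <- function(ms, xlim, ylim = c(0, 0), step = 1) {
  if (xlim[2] < xlim[1] || ylim[2] < ylim[1] || step <= 0) {
    rlang::abort("Empty arena.", class = "cortexgrid_bad_arena")
  }
  xs <- seq(xlim[1], xlim[2], by = step)
  ys <- seq(ylim[1], ylim[2], by = step)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  tm <- wtl_matrix(ms)
  lat <- mod1(pts %*% t(tm)) # n x 2M, interleaved a,b per module
  a_idx <- seq(1, ncol(lat), by = 2)
  keys <- character(nrow(pts))
  ka <- sapply(seq_along(a_idx), function(m) {
    bin_index(lat[, a_idx[m]], ms$bins_a[m])
  })
  kb <- sapply(seq_along(a_idx), function(m) {
    bin_index(lat[, a_idx[m] + 1], ms$bins_b[m])
  })
  ka <- matrix(ka, nrow = nrow(pts))
  kb <- matrix(kb, nrow = nrow(pts))
  keys <- apply(cbind(ka, kb), 1, paste, collapse = "|")
  length(unique(keys))
}
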