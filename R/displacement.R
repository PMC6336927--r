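#' Displacement codes: module-wise phase differences
#'
#' A displacement code is the module-by-module phase difference between
#' two location codes.  It plays two roles: within one frame it encodes a
#' movement vector (navigation); across frames it encodes the relative
#' placement of one object in another's space (composition).  Grid and
#' displacement operations are complementary:
#' `location1 + displacement = location2` ([apply_displacement()]) and
#' `location2 - location1 = displacement` ([displacement_between()]).
#'
#' @param deltas `M x 2` matrix of per-module phase differences (reduced
#'   mod 1).
#' @param frame_from,frame_to Frame tags of the subtracted and target
#'   codes.
#' @return A tibble of class `displacement_code` with columns `module`,
#'   `da`, `db` and attributes `frame_from`, `frame_to`.
#' @export
displacement_code <- function(deltas, frame_from = "environment",
                              frame_to = "environment") {
  deltas <- matrix(as.double(deltas), ncol = 2)
  d <- tibble::tibble(
    module = seq_len(nrow(deltas)),
    da = mod1(deltas[, 1]),
    db = mod1(deltas[, 2])
  )
  attr(d, "frame_from") <- as.character(frame_from)
  attr(d, "frame_to") <- as.character(frame_to)
  class(d) <- c("displacement_code", class(tibble::tibble()))
  d
}

#' @rdname displacement_code
#' @param d A `displacement_code`.
#' @export
frame_from <- function(d) attr(d, "frame_from")

#' @rdname displacement_code
#' @export
frame_to <- function(d) attr(d, "frame_to")

#' Displacement between two location codes
#'
#' Per module, `delta = (phase_b - phase_a) mod 1`.  The two codes may be
#' anchored in different frames — that is how object composition is
#' expressed: the result maps any point in `a`'s space to the equivalent
#' point in `b`'s space.
#'
#' @param a,b Location codes over `ms`.
#' @param ms The `module_set`.
#' @return A `displacement_code` with `frame_from = code_frame(a)`,
#'   `frame_to = code_frame(b)`.
#' @examples
#' ms <- module_set(scale = 1)
#' a <- location_code(matrix(c(0.2, 0.2), 1))
#' b <- location_code(matrix(c(0.1, 0.9), 1))
#' displacement_between(a, b, ms)
#' @export
displacement_between <- function(a, b, ms) {
  check_conforms(a, ms, "a")
  check_conforms(b, ms, "b")
  displacement_code(
    cbind(mod1(b$pa - a$pa), mod1(b$pb - a$pb)),
    frame_from = code_frame(a), frame_to = code_frame(b)
  )
}

#' Apply a displacement to a location code
#'
#' Per module, `(phase + delta) mod 1`; the result is re-tagged with the
#' displacement's target frame.  The source frame must match the code's
#' frame — mixing frames implicitly is a plumbing error this check
#' catches.
#'
#' @param a A `location_code` with `code_frame(a) == frame_from(d)`.
#' @param d A `displacement_code`.
#' @param ms The `module_set`.
#' @return A `location_code` in frame `frame_to(d)`.
#' @examples
#' ms <- module_set(scale = 1)
#' a <- location_code(matrix(c(0.2, 0.2), 1), frame = "cup")
#' b <- location_code(matrix(c(0.1, 0.9), 1), frame = "logo")
#' d <- displacement_between(a, b, ms)
#' apply_displacement(a, d, ms)
#' @export
apply_displacement <- function(a, d, ms) {
  check_conforms(a, ms, "a")
  check_conforms(d, ms, "d")
  if (!identical(code_frame(a), frame_from(d))) {
    rlang::abort(
      sprintf("Code frame '%s' does not match displacement frame_from '%s'.",
              code_frame(a), frame_from(d)),
      class = "cortexgrid_frame_mismatch"
    )
  }
  location_code(cbind(mod1(a$pa + d$da), mod1(a$pb + d$db)),
                frame = frame_to(d))
}

#' Discretize a displacement code
#'
#' Bins each module's delta with the module's own bin counts (displacement
#' cell modules are paired one-to-one with grid cell modules and reuse
#' their resolution).  A single displacement module is as ambiguous as a
#' single grid module: with period 3, a displacement of "two right, one
#' up" activates the same cell as "five over, four up".  Across modules
#' the joint key is unique to a displacement — and, between object frames,
#' to the particular object pair.
#'
#' @param d A `displacement_code`.
#' @param ms The `module_set`.
#' @return A tibble of class `displacement_key` with columns `module`,
#'   `ca`, `cb`.
#' @export
displacement_key <- function(d, ms) {
  check_conforms(d, ms, "d")
  key <- tibble::tibble(
    module = ms$module,
    ca = as.integer(bin_index(d$da, ms$bins_a)),
    cb = as.integer(bin_index(d$db, ms$bins_b))
  )
  class(key) <- c("displacement_key", "code_key", class(tibble::tibble()))
  key
}

#' Encode a world vector as a displacement code
#'
#' Convenience wrapper: the displacement between any code and that code
#' integrated by `v` — independent of the starting code, since the phase
#' update is linear in the movement.
#'
#' @param ms The `module_set`.
#' @param v 2D world vector.
#' @inheritParams displacement_code
#' @return A `displacement_code`.
#' @export
encode_displacement <- function(ms, v, frame_from = "environment",
                                frame_to = frame_from) {
  assert_len2(v, "v")
  lat <- as.vector(wtl_matrix(ms) %*% v)
  displacement_code(matrix(mod1(lat), ncol = 2, byrow = TRUE),
                    frame_from = frame_from, frame_to = frame_to)
}

# Displacement code at a key's bin centers.
key_to_displacement <- function(key, ms, frame_from = "environment",
                                frame_to = frame_from) {
  displacement_code(
    cbind((key$ca + 0.5) / ms$bins_a, (key$cb + 0.5) / ms$bins_b),
    frame_from = frame_from, frame_to = frame_to
  )
}

#' Decode a displacement code to a motor vector
#'
#' Recovers the 2D world movement that a displacement code represents —
#' the vector needed to move the body (or sensor) from point a to point b.
#' The search is an explicit grid scan: candidate vectors on a grid of
#' spacing `grid_step` within a disc of radius `search_radius` are
#' encoded, and the minimum-norm candidate whose per-module phases match
#' `d` within `tol` (circular distance) wins; ties break lexicographically
#' on `(norm, vx, vy)`.  Because the phase code is periodic, decoding is
#' only unique up to the modules' joint period; a radius beyond it, or an
#' out-of-range true vector, yields an "undecodable" error.
#'
#' @param d A `displacement_code`.
#' @param ms The `module_set`.
#' @param search_radius Maximum candidate norm (world units).
#' @param grid_step Candidate grid spacing; default `min(scale) / 20`.
#' @param tol Phase match tolerance; default `grid_step / (2 * min(scale))`,
#'   the tightest tolerance that still always admits the candidate nearest
#'   the true vector, so a successful decode is within `grid_step / 2` per
#'   axis.
#' @return A one-row tibble with columns `vx`, `vy`, `norm`,
#'   `matched_tolerance` (the achieved worst-module phase mismatch).
#' @section Errors: Signals a condition of class `cortexgrid_undecodable`
#'   when no candidate within the radius matches.
#' @examples
#' ms <- module_set(scale = c(3, 4), bins_a = c(3, 4), bins_b = 1)
#' d <- encode_displacement(ms, c(5, 0))
#' decode_vector(d, ms, search_radius = 6, grid_step = 1)
#' @export
decode_vector <- function(d, ms, search_radius,
                          grid_step = min(ms$scale) / 20,
                          tol = grid_step / (2 * min(ms$scale))) {
  stopifnot(search_radius > 0, grid_step > 0)
  check_conforms(d, ms, "d")
  n <- floor(search_radius / grid_step)
  g <- seq(-n, n) * grid_step
  cand <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  cand <- cand[cand[, 1]^2 + cand[, 2]^2 <= search_radius^2 + 1e-12, ,
               drop = FALSE]
  lat <- mod1(cand %*% t(wtl_matrix(ms))) # n x 2M
  target <- rep(delta_vec(d), each = 1)
  mism <- circ_dist(lat, matrix(delta_vec(d), nrow(cand), ncol(lat),
                                byrow = TRUE))
  worst <- apply(mism, 1, max)
  ok <- worst <= tol
  if (!any(ok)) {
    rlang::abort(
      sprintf("Displacement undecodable within radius %g.", search_radius),
      class = "cortexgrid_undecodable"
    )
  }
  cand <- cand[ok, , drop = FALSE]
  worst <- worst[ok]
  nrm <- sqrt(rowSums(cand^2))
  pick <- order(nrm, cand[, 1], cand[, 2])[1]
  tibble::tibble(
    vx = cand[pick, 1], vy = cand[pick, 2],
    norm = nrm[pick], matched_tolerance = worst[pick]
  )
}
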