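#' Define a set of grid-cell modules
#'
#' A grid-cell module is a population of cells that tile 2D space with a
#' shared periodic lattice; position within one lattice tile is a phase in
#' `[0, 1)^2` along the two lattice axes.  A module set combines several
#' modules with different spacings and/or orientations so that the joint
#' phase pattern disambiguates locations far beyond any single module's
#' period.
#'
#' @param scale Lattice period length per module, in world-distance units
#'   (strictly positive).  Recycled against the other arguments.
#' @param orientation Lattice orientation in radians; reduced into
#'   `[0, 2*pi)`.
#' @param lattice `"square"` or `"rhombic60"`.  `"rhombic60"` uses a 60
#'   degree rhombus as the unit tile, emulating the triangular firing-field
#'   lattice of entorhinal grid cells; `"square"` keeps worked examples
#'   exact.
#' @param bins_a,bins_b Number of phase bins (distinct cells) along each
#'   lattice axis; a module has `bins_a * bins_b` cells.
#' @param noise_sd Standard deviation of additive phase noise applied per
#'   path-integration step (phase units, default 0 = noiseless).
#' @return A tibble of class `module_set`, one row per module, with columns
#'   `module`, `scale`, `orientation`, `lattice`, `bins_a`, `bins_b`,
#'   `noise_sd`.
#' @examples
#' module_set(scale = c(1, 1.4, 2), bins_a = 5)
#' @export
module_set <- function(scale, orientation = 0, lattice = "square",
                       bins_a = 5L, bins_b = bins_a, noise_sd = 0) {
  ms <- tibble::tibble(
    scale = as.double(scale),
    orientation = as.double(orientation) %% (2 * pi),
    lattice = as.character(lattice),
    bins_a = as.integer(bins_a),
    bins_b = as.integer(bins_b),
    noise_sd = as.double(noise_sd)
  )
  ms <- tibble::add_column(ms, module = seq_len(nrow(ms)), .before = 1)
  validate_module_set(ms)
}

validate_module_set <- function(ms) {
  if (nrow(ms) < 1) {
    rlang::abort("A module set needs at least one module.",
                 class = "cortexgrid_bad_module_set")
  }
  if (any(ms$scale <= 0)) {
    rlang::abort("Module scales must be strictly positive.",
                 class = "cortexgrid_bad_module_set")
  }
  if (any(ms$bins_a < 1L) || any(ms$bins_b < 1L)) {
    rlang::abort("Bin counts must be >= 1.",
                 class = "cortexgrid_bad_module_set")
  }
  bad <- setdiff(unique(ms$lattice), c("square", "rhombic60"))
  if (length(bad)) {
    rlang::abort(
      sprintf("Unknown lattice type(s): %s.", paste(bad, collapse = ", ")),
      class = "cortexgrid_bad_module_set"
    )
  }
  if (any(ms$noise_sd < 0)) {
    rlang::abort("noise_sd must be non-negative.",
                 class = "cortexgrid_bad_module_set")
  }
  if (anyDuplicated(ms[c("scale", "orientation")])) {
    rlang::warn(paste(
      "Some modules share both scale and orientation;",
      "they add no disambiguation capacity."
    ))
  }
  class(ms) <- c("module_set", class(tibble::tibble()))
  ms
}

#' Default module set
#'
#' Six modules with scales in geometric progression (ratio 1.4, a common
#' convention for entorhinal module spacing ratios), fixed distinct
#' orientations spread by the golden angle, 5 x 5 phase bins each, and no
#' phase noise.  Every parameter can be overridden; this default exists so
#' examples and experiments share one reproducible configuration.
#'
#' @param n_modules Number of modules.
#' @param base_scale Scale of the smallest module (world units).
#' @param ratio Geometric scale ratio between successive modules.
#' @param bins Phase bins per lattice axis (same for both axes).
#' @param lattice Lattice type for all modules.
#' @param noise_sd Per-step phase noise standard deviation.
#' @return A `module_set` tibble.
#' @examples
#' default_module_set()
#' @export
default_module_set <- function(n_modules = 6L, base_scale = 1, ratio = 1.4,
                               bins = 5L, lattice = "rhombic60",
                               noise_sd = 0) {
  i <- seq_len(n_modules) - 1L
  golden <- pi * (3 - sqrt(5))
  module_set(
    scale = base_scale * ratio^i,
    orientation = (i * golden) %% (2 * pi),
    lattice = lattice,
    bins_a = bins,
    bins_b = bins,
    noise_sd = noise_sd
  )
}

# Lattice basis matrix: columns are the two lattice axis vectors of a
# unit-period tile.
lattice_basis <- function(lattice) {
  switch(lattice,
    square = diag(2),
    rhombic60 = cbind(c(1, 0), c(0.5, sqrt(3) / 2)),
    rlang::abort(sprintf("Unknown lattice type '%s'.", lattice),
                 class = "cortexgrid_bad_module_set")
  )
}

# Stacked world->lattice transform: a (2M x 2) matrix T such that
# T %*% v gives the per-module lattice displacement (a1, b1, a2, b2, ...)
# for world vector v.  Row-pairs are B^{-1} R(-theta) / scale.
wtl_matrix <- function(ms) {
  mats <- lapply(seq_len(nrow(ms)), function(i) {
    th <- ms$orientation[i]
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2,
                  byrow = TRUE) # R(-theta)
    solve(lattice_basis(ms$lattice[i])) %*% rot / ms$scale[i]
  })
  do.call(rbind, mats)
}

#' Convert a world vector to per-module lattice coordinates
#'
#' Expresses a 2D world displacement in each module's (possibly oblique,
#' rotated, scaled) lattice basis.  Linear in the input; this is the
#' coordinate change that path integration applies before reducing phases
#' modulo 1.
#'
#' @param ms A `module_set`.
#' @param v 2D world vector `c(x, y)`.
#' @return A tibble with columns `module`, `la`, `lb` (lattice
#'   coordinates, unreduced).
#' @examples
#' world_to_lattice(module_set(scale = 2), c(1, 0))
#' @export
world_to_lattice <- function(ms, v) {
  assert_len2(v, "v")
  lat <- wtl_matrix(ms) %*% v
  tibble::tibble(
    module = ms$module,
    la = lat[seq(1, length(lat), by = 2)],
    lb = lat[seq(2, length(lat), by = 2)]
  )
}

#' Read / write a module-set configuration
#'
#' Module sets are declared in YAML as a list of mappings with keys
#' `scale`, `orientation_deg`, `lattice`, `bins_a`, `bins_b`, `noise_sd`
#' (missing keys take the `module_set()` defaults; orientation is in
#' degrees in the file, radians in the object).
#'
#' @param path File path.
#' @param ms A `module_set` (for writing).
#' @return `read_module_config()` returns a `module_set`;
#'   `write_module_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_module_config(default_module_set(2), f)
#' read_module_config(f)
#' @export
read_module_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mods <- cfg$modules %||% cfg
  module_set(
    scale = vapply(mods, function(m) as.double(m$scale), 0),
    orientation = vapply(mods, function(m) {
      as.double(m$orientation_deg %||% 0) * pi / 180
    }, 0),
    lattice = vapply(mods, function(m) m$lattice %||% "square", ""),
    bins_a = vapply(mods, function(m) as.integer(m$bins_a %||% 5L), 0L),
    bins_b = vapply(mods, function(m) as.integer(m$bins_b %||% 5L), 0L),
    noise_sd = vapply(mods, function(m) as.double(m$noise_sd %||% 0), 0)
  )
}

#' @rdname read_module_config
#' @export
write_module_config <- function(ms, path) {
  mods <- lapply(seq_len(nrow(ms)), function(i) {
    list(
      scale = ms$scale[i],
      orientation_deg = ms$orientation[i] * 180 / pi,
      lattice = ms$lattice[i],
      bins_a = ms$bins_a[i],
      bins_b = ms$bins_b[i],
      noise_sd = ms$noise_sd[i]
    )
  })
  yaml::write_yaml(list(modules = mods), path, precision = 15L)
  invisible(path)
}
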