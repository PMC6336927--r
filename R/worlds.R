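#' Generate a synthetic object as feature placements
#'
#' Objects are defined the way the framework models them: a set of
#' located features.  Placements are distinct integer points on a
#' rectangular canvas (integer coordinates keep worked examples exact),
#' with labels drawn uniformly from a finite alphabet.  The coordinate
#' convention throughout the package is 2D Cartesian, x right, y up,
#' movements as allocentric world vectors.
#'
#' @param n_features Number of feature points (0 gives an empty
#'   placement).
#' @param alphabet Character vector of feature labels to draw from.
#' @param canvas `c(width, height)`: points are drawn from
#'   `0..(width-1)` by `0..(height-1)`.
#' @param min_spacing Minimum Euclidean distance between any two points
#'   (default 1, i.e. distinct integer points).
#' @return A tibble of class `feature_placements` with columns `x`, `y`,
#'   `feature`.  Deterministic given the RNG state.
#' @examples
#' set.seed(7)
#' make_object(5, alphabet = LETTERS[1:4])
#' @export
make_object <- function(n_features, alphabet = LETTERS[1:8],
                        canvas = c(10, 10), min_spacing = 1) {
  stopifnot(n_features >= 0, min_spacing >= 1, all(canvas >= 1))
  grid <- expand.grid(x = seq_len(canvas[1]) - 1L,
                      y = seq_len(canvas[2]) - 1L)
  if (n_features == 0) {
    out <- tibble::tibble(x = integer(), y = integer(),
                          feature = character())
    class(out) <- c("feature_placements", class(tibble::tibble()))
    return(out)
  }
  chosen <- integer()
  avail <- seq_len(nrow(grid))
  for (i in seq_len(n_features)) {
    if (!length(avail)) {
      rlang::abort(
        sprintf("Cannot place %d features at spacing %g on a %dx%d canvas.",
                n_features, min_spacing, canvas[1], canvas[2]),
        class = "cortexgrid_infeasible_object"
      )
    }
    pick <- avail[sample.int(length(avail), 1L)]
    chosen <- c(chosen, pick)
    d2 <- (grid$x[avail] - grid$x[pick])^2 + (grid$y[avail] - grid$y[pick])^2
    avail <- avail[d2 >= min_spacing^2]
  }
  out <- tibble::tibble(
    x = as.integer(grid$x[chosen]),
    y = as.integer(grid$y[chosen]),
    feature = sample(alphabet, n_features, replace = TRUE)
  )
  class(out) <- c("feature_placements", class(tibble::tibble()))
  out
}

#' Build an exploration trace over feature placements
#'
#' Produces the (movement, sensed feature) pairs a sensor would emit
#' while exploring an object: movements run between placement points,
#' with the point's feature emitted on arrival.  The `"sweep"` policy
#' visits every placement exactly once in row-major order (y, then x),
#' so the resulting trace covers all features; `"random_walk"` hops
#' between uniformly drawn placement points for `n_steps` steps.
#'
#' @param placements A `feature_placements` tibble (non-empty).
#' @param policy `"sweep"` or `"random_walk"`.
#' @param n_steps Number of steps for the random-walk policy (>= 1);
#'   ignored by `"sweep"`.
#' @return An [exploration_trace()] starting from the object's origin
#'   (offset `c(0, 0)`), whose first movement reaches the first visited
#'   point.
#' @export
scripted_trace <- function(placements, policy = c("sweep", "random_walk"),
                           n_steps = nrow(placements)) {
  policy <- match.arg(policy)
  if (!nrow(placements)) {
    rlang::abort("Feature-seeking policies need non-empty placements.",
                 class = "cortexgrid_bad_trace")
  }
  if (n_steps < 1) {
    rlang::abort("n_steps must be >= 1.", class = "cortexgrid_bad_trace")
  }
  visit <- switch(policy,
    sweep = order(placements$y, placements$x),
    random_walk = sample.int(nrow(placements), n_steps, replace = TRUE)
  )
  pts <- cbind(placements$x[visit], placements$y[visit])
  prev <- rbind(c(0, 0), pts[-nrow(pts), , drop = FALSE])
  exploration_trace(
    data.frame(
      dx = pts[, 1] - prev[, 1],
      dy = pts[, 2] - prev[, 2],
      feature = placements$feature[visit]
    ),
    start_offset = c(0, 0)
  )
}

#' Experiment configuration
#'
#' Bundles and validates the knobs shared by the experiment runners, and
#' carries a content hash so every report can state exactly which
#' configuration produced it.
#'
#' @param seed Integer RNG seed; every run is bit-reproducible given
#'   (config, seed).
#' @param ms A `module_set` (default [default_module_set()]).
#' @param n_objects,n_features,alphabet_size,canvas,min_spacing Object
#'   generation: library size, features per object, label alphabet size,
#'   canvas extent, minimum feature spacing.
#' @param n_columns Integer vector of column counts to compare in
#'   recognition experiments.
#' @param n_trials Trials per condition.
#' @param max_sensations Recognition step cap.
#' @param policy Exploration policy for learning traces.
#' @return A list of class `world_config` (with `$hash`).
#' @export
world_config <- function(seed = 1L, ms = default_module_set(),
                         n_objects = 50L, n_features = 10L,
                         alphabet_size = 8L, canvas = c(10L, 10L),
                         min_spacing = 1, n_columns = c(1L, 3L),
                         n_trials = 20L, max_sensations = 50L,
                         policy = "sweep") {
  cfg <- list(
    seed = as.integer(seed), ms = ms, n_objects = as.integer(n_objects),
    n_features = as.integer(n_features),
    alphabet_size = as.integer(alphabet_size),
    canvas = as.integer(canvas), min_spacing = min_spacing,
    n_columns = as.integer(n_columns), n_trials = as.integer(n_trials),
    max_sensations = as.integer(max_sensations), policy = policy
  )
  stopifnot(cfg$n_objects >= 1, cfg$n_features >= 1,
            cfg$alphabet_size >= 1, all(cfg$n_columns >= 1),
            cfg$n_trials >= 1, cfg$min_spacing >= 1)
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "world_config"
  cfg
}

#' @rdname world_config
#' @param path YAML file with any subset of the `world_config()` fields
#'   (module set under a `modules` key, as in [read_module_config()]).
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ms <- if (!is.null(raw$modules)) read_module_config(path)
        else default_module_set()
  args <- raw[setdiff(names(raw), "modules")]
  args <- args[names(args) %in% names(formals(world_config))]
  do.call(world_config, c(args, list(ms = ms)))
}

#' Learn a library of synthetic objects
#'
#' Generates `n_objects` feature placements, explores each with the
#' configured policy, and learns them all into one library (objects are
#' named `"obj001"`, `"obj002"`, ...).  Used by the recognition
#' experiment and handy for examples.
#'
#' @param cfg A `world_config`.
#' @return A list with `lib` (the `object_library`) and `placements`
#'   (named list of `feature_placements` keyed by object id).
#' @export
build_world <- function(cfg) {
  alphabet <- LETTERS[seq_len(cfg$alphabet_size)]
  lib <- object_library()
  placements <- list()
  for (i in seq_len(cfg$n_objects)) {
    id <- sprintf("obj%03d", i)
    pl <- make_object(cfg$n_features, alphabet, cfg$canvas,
                      cfg$min_spacing)
    tr <- scripted_trace(pl, policy = cfg$policy)
    lib <- learn_object(lib, id, tr, cfg$ms)
    placements[[id]] <- pl
  }
  list(lib = lib, placements = placements)
}
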