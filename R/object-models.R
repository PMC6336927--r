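#' Object models and object libraries
#'
#' A cortical column's model of an object is a set of location
#' representations unique to that object, some of which carry an
#' observable feature: an associative map from discretized location keys
#' to feature labels, anchored by a random location code drawn when the
#' object is first learned.  Composite structure is explicit: a component
#' is a child object plus one displacement code that converts any point in
#' the parent's space to the equivalent point in the child's space.
#' Recursion (a logo containing a picture of the cup that bears it) is
#' legal and bounded only by the query depth limit.
#'
#' @param id Object identifier (non-empty string); also the frame tag of
#'   every location in the model.
#' @param anchor A `location_code` with `code_frame(anchor) == id`.
#' @return `object_model()` returns an empty model; `object_library()` an
#'   empty library.
#' @export
object_model <- function(id, anchor) {
  stopifnot(is.character(id), nzchar(id))
  if (!identical(code_frame(anchor), id)) {
    rlang::abort("Anchor frame must equal the object id.",
                 class = "cortexgrid_frame_mismatch")
  }
  structure(
    list(id = id, anchor = anchor,
         features = character(),   # named: key_string -> label
         locations = list(),       # named: key_string -> exact phase code
         components = list(),      # list of (child_id, placement)
         behaviors = list()),      # named: behavior id -> behavior_sequence
    class = "object_model"
  )
}

#' @rdname object_model
#' @export
object_library <- function() {
  structure(list(objects = list()), class = "object_library")
}

#' @rdname object_model
#' @param lib An `object_library`.
#' @param model An `object_model` to insert (its id must be new).
#' @export
add_object <- function(lib, model) {
  if (model$id %in% names(lib$objects)) {
    rlang::abort(sprintf("Object '%s' already in library.", model$id),
                 class = "cortexgrid_duplicate_object")
  }
  lib$objects[[model$id]] <- model
  lib
}

#' @rdname object_model
#' @export
get_object <- function(lib, id) {
  if (!id %in% names(lib$objects)) {
    rlang::abort(sprintf("Unknown object '%s'.", id),
                 class = "cortexgrid_unknown_object")
  }
  lib$objects[[id]]
}

# Write one feature (and its exact phase code) into a model.
model_set_feature <- function(model, loc, feature, ms, force = FALSE) {
  key <- key_string(discretize(loc, ms))
  existing <- model$features[key]
  if (!is.na(existing) && !identical(unname(existing), feature) && !force) {
    rlang::abort(
      sprintf(
        "Feature conflict at key [%s] of object '%s': '%s' vs '%s'.",
        key, model$id, existing, feature
      ),
      class = "cortexgrid_feature_conflict"
    )
  }
  model$features[key] <- feature
  model$locations[[key]] <- loc
  model
}

#' Add a feature observation to an object at a location
#'
#' Low-level writer used to build models by hand (learning from traces
#' uses [learn_object()]).  Writing a different feature at an
#' already-written key is an error unless `force = TRUE` — surfacing
#' discretization collisions early beats silently overwriting.
#'
#' @param lib An `object_library`.
#' @param id Object id (must exist).
#' @param loc A `location_code` in the object's frame.
#' @param feature Feature label (non-empty string).
#' @param ms The `module_set`.
#' @param force Overwrite on conflict instead of erroring.
#' @return The updated library.
#' @export
add_feature <- function(lib, id, loc, feature, ms, force = FALSE) {
  model <- get_object(lib, id)
  if (!identical(code_frame(loc), id)) {
    rlang::abort("Location frame must equal the object id.",
                 class = "cortexgrid_frame_mismatch")
  }
  lib$objects[[id]] <- model_set_feature(model, loc, feature, ms, force)
  lib
}

#' Exploration traces
#'
#' A trace records how a sensor explored an object: a start offset
#' relative to the object's anchor point, then movements each followed by
#' the feature sensed on arrival (`"none"` over featureless locations —
#' an object's space includes locations one can move to that carry no
#' feature).
#'
#' @param steps A data frame with columns `dx`, `dy` (world movement) and
#'   `feature` (label or `"none"`); at least one row.
#' @param start_offset 2D world offset of the trace start from the
#'   object's anchor point.
#' @return A tibble of class `exploration_trace` with columns `step`,
#'   `dx`, `dy`, `feature` and a `start_offset` attribute.
#' @export
exploration_trace <- function(steps, start_offset = c(0, 0)) {
  stopifnot(nrow(steps) >= 1)
  assert_len2(start_offset, "start_offset")
  tr <- tibble::tibble(
    step = seq_len(nrow(steps)),
    dx = as.double(steps$dx), dy = as.double(steps$dy),
    feature = as.character(steps$feature)
  )
  if (any(!is.finite(tr$dx)) || any(!is.finite(tr$dy))) {
    rlang::abort("Trace movements must be finite.",
                 class = "cortexgrid_bad_trace")
  }
  attr(tr, "start_offset") <- as.double(start_offset)
  class(tr) <- c("exploration_trace", class(tibble::tibble()))
  tr
}

#' @rdname exploration_trace
#' @param trace An `exploration_trace`.
#' @param path CSV file path.  The file has columns `step`, `dx`, `dy`,
#'   `feature`; row `step = 0` carries the start offset.
#' @export
write_trace <- function(trace, path) {
  so <- attr(trace, "start_offset")
  out <- dplyr::bind_rows(
    tibble::tibble(step = 0L, dx = so[1], dy = so[2], feature = "none"),
    tibble::as_tibble(trace)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname exploration_trace
#' @export
read_trace <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    step = readr::col_integer(), dx = readr::col_double(),
    dy = readr::col_double(), feature = readr::col_character()
  ))
  start <- raw[raw$step == 0L, ]
  so <- if (nrow(start)) c(start$dx[1], start$dy[1]) else c(0, 0)
  exploration_trace(raw[raw$step > 0L, ], start_offset = so)
}

#' Learn an object from an exploration trace
#'
#' Models the sensorimotor learning loop: entering a novel object draws a
#' random anchor code; each movement updates the location code by path
#' integration; each sensed feature is stored at the discretized current
#' location.  Revisiting a point (by any path) reactivates the same code,
#' so repeated observations are idempotent; a different feature at an
#' already-written key raises a conflict error naming the key.
#'
#' @param lib An `object_library`; `id` must not already be present.
#' @param id New object id.
#' @param trace An `exploration_trace`.
#' @param ms The `module_set`.
#' @param force Passed to the feature writer (overwrite on conflict).
#' @return The updated library; the learned model is
#'   `get_object(lib, id)`.
#' @examples
#' set.seed(1)
#' ms <- default_module_set(3)
#' tr <- exploration_trace(data.frame(dx = c(1, 1), dy = c(0, 1),
#'                                    feature = c("edge", "none")))
#' lib <- learn_object(object_library(), "pen", tr, ms)
#' @export
learn_object <- function(lib, id, trace, ms, force = FALSE) {
  if (id %in% names(lib$objects)) {
    rlang::abort(sprintf("Object '%s' already in library.", id),
                 class = "cortexgrid_duplicate_object")
  }
  model <- object_model(id, random_code(ms, frame = id))
  current <- integrate_code(model$anchor, ms, attr(trace, "start_offset"))
  for (i in seq_len(nrow(trace))) {
    current <- integrate_code(current, ms, c(trace$dx[i], trace$dy[i]))
    if (trace$feature[i] != "none") {
      model <- model_set_feature(model, current, trace$feature[i], ms,
                                 force = force)
    }
  }
  lib$objects[[id]] <- model
  lib
}

#' Declare a component: child object at a displacement
#'
#' Stores one displacement code that maps parent-frame locations to
#' child-frame locations.  The same child may appear several times at
#' different placements, and cycles are allowed (recursive objects);
#' [feature_at()] bounds traversal by its depth limit.
#'
#' @param lib An `object_library` containing both objects.
#' @param parent_id,child_id Object ids.
#' @param placement A `displacement_code` with
#'   `frame_from == parent_id`, `frame_to == child_id`.
#' @return The updated library.
#' @export
add_component <- function(lib, parent_id, child_id, placement) {
  parent <- get_object(lib, parent_id)
  get_object(lib, child_id) # existence check
  if (!identical(frame_from(placement), parent_id) ||
      !identical(frame_to(placement), child_id)) {
    rlang::abort(
      "Placement frames must be (parent_id, child_id).",
      class = "cortexgrid_frame_mismatch"
    )
  }
  parent$components[[length(parent$components) + 1L]] <-
    list(child_id = child_id, placement = placement)
  lib$objects[[parent_id]] <- parent
  lib
}

#' Resolve the feature at a location, through composite structure
#'
#' Looks up the discretized location in the object's own feature map
#' first (direct observations shadow component features); failing that,
#' translates the location into each component child's frame via its
#' placement displacement and recurses, depth-first in component
#' insertion order, decrementing the depth limit per translation.  The
#' first non-`"none"` answer wins, making resolution a pure function of
#' the library.
#'
#' @param lib An `object_library`.
#' @param id Object id.
#' @param loc A `location_code` in the object's frame.
#' @param ms The `module_set`.
#' @param depth_limit Maximum number of frame translations (default 5);
#'   the only guard on recursive composites.
#' @return A feature label, or `"none"`.
#' @export
feature_at <- function(lib, id, loc, ms, depth_limit = 5L) {
  model <- get_object(lib, id)
  if (!identical(code_frame(loc), id)) {
    rlang::abort("Location frame must equal the object id.",
                 class = "cortexgrid_frame_mismatch")
  }
  key <- key_string(discretize(loc, ms))
  hit <- model$features[key]
  if (!is.na(hit)) {
    return(unname(hit))
  }
  if (depth_limit > 0L) {
    for (comp in model$components) {
      child_loc <- apply_displacement(loc, comp$placement, ms)
      res <- feature_at(lib, comp$child_id, child_loc, ms,
                        depth_limit - 1L)
      if (res != "none") {
        return(res)
      }
    }
  }
  "none"
}

#' @export
print.object_model <- function(x, ...) {
  cat(sprintf(
    "<object_model '%s': %d features, %d components, %d behaviors>\n",
    x$id, length(x$features), length(x$components), length(x$behaviors)
  ))
  invisible(x)
}

#' @export
print.object_library <- function(x, ...) {
  cat(sprintf("<object_library: %d objects>\n", length(x$objects)))
  for (m in x$objects) print(m)
  invisible(x)
}

phase_list <- function(code) {
  lapply(seq_len(nrow(code)), function(i) c(code$pa[i], code$pb[i]))
}

delta_list <- function(d) {
  lapply(seq_len(nrow(d)), function(i) c(d$da[i], d$db[i]))
}

#' Read / write an object library as JSON
#'
#' The on-disk schema stores, per object: the anchor phases, the feature
#' map (canonical key strings to labels), the exact location codes backing
#' each key, the components (child id plus per-module delta pairs) and the
#' behaviors (ordered displacement-key strings).  Objects and map keys are
#' written sorted, so write - read - write round-trips byte-identically.
#'
#' @param lib An `object_library`.
#' @param path JSON file path.
#' @return `write_object_library()` returns `path` invisibly;
#'   `read_object_library()` returns the library.
#' @export
write_object_library <- function(lib, path) {
  objs <- lib$objects[order(names(lib$objects))]
  out <- list(objects = lapply(objs, function(m) {
    keys <- sort(names(m$features))
    list(
      id = m$id,
      anchor = phase_list(m$anchor),
      features = as.list(m$features[keys]),
      locations = lapply(m$locations[keys], phase_list),
      components = lapply(m$components, function(comp) {
        list(child_id = comp$child_id,
             deltas = delta_list(comp$placement))
      }),
      behaviors = lapply(
        m$behaviors[sort(names(m$behaviors) %||% character())],
        function(b) as.list(unclass(b)$steps)
      )
    )
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_object_library
#' @export
read_object_library <- function(path) {
  raw <- jsonlite::read_json(path)
  lib <- object_library()
  for (o in raw$objects) {
    anchor <- location_code(
      do.call(rbind, lapply(o$anchor, unlist)), frame = o$id
    )
    m <- object_model(o$id, anchor)
    for (key in names(o$features)) {
      m$features[key] <- o$features[[key]]
      m$locations[[key]] <- location_code(
        do.call(rbind, lapply(o$locations[[key]], unlist)), frame = o$id
      )
    }
    m$components <- lapply(o$components, function(comp) {
      list(
        child_id = comp$child_id,
        placement = displacement_code(
          do.call(rbind, lapply(comp$deltas, unlist)),
          frame_from = o$id, frame_to = comp$child_id
        )
      )
    })
    for (bid in names(o$behaviors)) {
      m$behaviors[[bid]] <- behavior_sequence(
        bid, unlist(o$behaviors[[bid]])
      )
    }
    lib$objects[[o$id]] <- m
  }
  lib
}
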