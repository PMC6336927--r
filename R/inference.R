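#' Cortical columns and candidate hypothesis sets
#'
#' A column learns complete object models and recognizes objects
#' sensorimotorically: sensing a feature activates the union of every
#' (object, location) at which that feature was ever stored; each
#' subsequent movement path-integrates every hypothesis and each
#' sensation eliminates the hypotheses whose model predicts something
#' else.  Recognition is reached when the surviving hypotheses all name
#' one object.
#'
#' @param ms The column's `module_set`.
#' @param lib The column's `object_library`.
#' @param mode `"strict"` (a hypothesis predicting `"none"` at a sensed
#'   feature is eliminated — appropriate when learning traces covered the
#'   object) or `"lenient"` (such hypotheses survive).
#' @return `column()` returns an empty column.
#' @export
column <- function(ms, lib, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  structure(
    list(ms = ms, lib = lib, mode = mode, tm = wtl_matrix(ms),
         state = empty_candidates(nrow(ms))),
    class = "column"
  )
}

empty_candidates <- function(n_modules) {
  structure(
    list(object_id = character(), origin_key = character(),
         phases = matrix(numeric(), 0, 2 * n_modules)),
    class = "candidate_set"
  )
}

#' @rdname column
#' @param col A `column`.
#' @return `hypotheses()` returns a tibble with one row per live
#'   hypothesis: `object_id` and the current discretized `key`.
#' @export
hypotheses <- function(col) {
  st <- col$state
  tibble::tibble(
    object_id = st$object_id,
    key = phases_to_keys(st$phases, col$ms)
  )
}

#' @rdname column
#' @return `n_hypotheses()` returns the current hypothesis count.
#' @export
n_hypotheses <- function(col) length(col$state$object_id)

# Row-wise canonical key strings for an n x 2M phase matrix.
phases_to_keys <- function(phases, ms) {
  if (!nrow(phases)) {
    return(character())
  }
  cols_a <- seq(1, ncol(phases), by = 2)
  ka <- vapply(seq_along(cols_a), function(m) {
    as.integer(bin_index(phases[, cols_a[m]], ms$bins_a[m]))
  }, integer(nrow(phases)))
  kb <- vapply(seq_along(cols_a), function(m) {
    as.integer(bin_index(phases[, cols_a[m] + 1], ms$bins_b[m]))
  }, integer(nrow(phases)))
  ka <- matrix(ka, nrow = nrow(phases))
  kb <- matrix(kb, nrow = nrow(phases))
  parts <- vapply(seq_len(ncol(ka)), function(m) {
    paste(ka[, m], kb[, m], sep = ".")
  }, character(nrow(phases)))
  apply(matrix(parts, nrow = nrow(phases)), 1, paste, collapse = "|")
}

#' Initialize hypotheses from a sensed feature
#'
#' Activates one hypothesis per stored (object, key) whose feature equals
#' the sensation — the full union of poses consistent with a single
#' sensation.  An empty result is legal and means the feature is unknown
#' to the library.
#'
#' @inheritParams column
#' @param col A `column`.
#' @param feature The sensed feature label.
#' @param pose `"stored"` starts each hypothesis at the exact phase code
#'   recorded when the feature was learned (the default; keeps noiseless
#'   elimination exact), `"bin_center"` at the key's bin centers.
#' @return The column with its candidate set replaced.
#' @export
init_from_feature <- function(col, feature,
                              pose = c("stored", "bin_center")) {
  pose <- match.arg(pose)
  ids <- character()
  keys <- character()
  rows <- list()
  for (model in col$lib$objects) {
    hit <- names(model$features)[model$features == feature]
    for (key in hit) {
      loc <- if (pose == "stored") {
        model$locations[[key]]
      } else {
        bin_center_code(parse_key_string(key), col$ms, frame = model$id)
      }
      ids <- c(ids, model$id)
      keys <- c(keys, key)
      rows[[length(rows) + 1L]] <- phase_vec(loc)
    }
  }
  st <- empty_candidates(nrow(col$ms))
  if (length(rows)) {
    st$object_id <- ids
    st$origin_key <- keys
    st$phases <- do.call(rbind, rows)
    dup <- duplicated(paste(ids, keys))
    st <- filter_candidates(st, !dup)
  }
  col$state <- st
  col
}

filter_candidates <- function(st, keep) {
  st$object_id <- st$object_id[keep]
  st$origin_key <- st$origin_key[keep]
  st$phases <- st$phases[keep, , drop = FALSE]
  st
}

#' Move and sense: one sensorimotor step
#'
#' Path-integrates every hypothesis by the movement (each hypothesis
#' tracks the sensor's location in its own object's frame), then — if a
#' feature was sensed — eliminates the hypotheses whose model resolves a
#' different feature at the predicted location.  In strict mode a model
#' predicting `"none"` is also eliminated; in lenient mode it survives.
#' An empty candidate set passes through unchanged, and the set never
#' grows.
#'
#' @param col A `column`.
#' @param movement 2D world vector the sensor moved by.
#' @param sensed Feature label sensed after the movement, or `"none"`.
#' @return The updated column.
#' @export
column_step <- function(col, movement, sensed = "none") {
  st <- col$state
  if (!length(st$object_id)) {
    return(col)
  }
  assert_len2(movement)
  lat <- as.vector(col$tm %*% movement)
  st$phases <- mod1(st$phases + matrix(lat, nrow(st$phases),
                                       ncol(st$phases), byrow = TRUE))
  if (!identical(sensed, "none")) {
    predicted <- predicted_features(st, col)
    keep <- if (col$mode == "strict") {
      predicted == sensed
    } else {
      predicted == sensed | predicted == "none"
    }
    st <- filter_candidates(st, keep)
  }
  col$state <- st
  col
}

# Predicted feature per hypothesis.  Objects without components use a
# direct vectorized key lookup; composite objects fall back to the
# recursive resolver.
predicted_features <- function(st, col) {
  keys <- phases_to_keys(st$phases, col$ms)
  out <- character(length(keys))
  for (id in unique(st$object_id)) {
    sel <- st$object_id == id
    model <- col$lib$objects[[id]]
    if (!length(model$components)) {
      hit <- model$features[keys[sel]]
      hit[is.na(hit)] <- "none"
      out[sel] <- unname(hit)
    } else {
      idx <- which(sel)
      for (i in idx) {
        loc <- location_code(matrix(st$phases[i, ], ncol = 2,
                                    byrow = TRUE), frame = id)
        out[i] <- feature_at(col$lib, id, loc, col$ms)
      }
    }
  }
  out
}

#' Current recognition verdict of a column
#'
#' @param col A `column`.
#' @return The unique object id shared by all live hypotheses, or
#'   `"undecided"` when the set is empty or heterogeneous.
#' @export
recognized <- function(col) {
  ids <- unique(col$state$object_id)
  if (length(ids) == 1) ids else "undecided"
}

#' Networks of columns and lateral voting
#'
#' Columns observing the same object through different sensors keep
#' private location hypotheses but share their object-identity sets over
#' lateral connections.  A vote intersects the object sets of all
#' non-empty columns and prunes every column to the intersection; an
#' empty intersection flags disagreement and leaves states untouched.
#'
#' @param columns A list of `column` objects (at least one; module sets
#'   may differ between columns).
#' @return `column_network()` returns the network; `vote()` the updated
#'   network (with `$disagreement` set).
#' @export
column_network <- function(columns) {
  stopifnot(length(columns) >= 1)
  structure(list(columns = columns, disagreement = FALSE),
            class = "column_network")
}

#' @rdname column_network
#' @param net A `column_network`.
#' @export
vote <- function(net) {
  sets <- lapply(net$columns, function(col) unique(col$state$object_id))
  active <- lengths(sets) > 0
  net$disagreement <- FALSE
  if (!any(active)) {
    return(net)
  }
  consensus <- Reduce(intersect, sets[active])
  if (!length(consensus)) {
    net$disagreement <- TRUE
    return(net)
  }
  net$columns <- lapply(net$columns, function(col) {
    col$state <- filter_candidates(col$state,
                                   col$state$object_id %in% consensus)
    col
  })
  net
}

#' Run sensorimotor recognition on a target object
#'
#' Simulates each column's sensor exploring the target's feature points
#' (each column from its own start point, visiting points in its own
#' random order), updating hypotheses after every sensation and voting
#' across columns, until every column recognizes the target.
#'
#' @param net A `column_network` whose libraries contain `target_id`.
#' @param target_id True object being observed.
#' @param placements The target's true feature placements: a data frame
#'   with columns `x`, `y`, `feature` (see [make_object()]).
#' @param start_indices Optional integer vector, one placement row index
#'   per column, fixing where each sensor starts; defaults to distinct
#'   random points (recycled if there are more columns than points).
#' @param max_sensations Step cap before giving up (default 50).
#' @return The 1-based sensation index at which consensus on
#'   `target_id` was reached, or `NA_integer_` if the cap was hit
#'   (recognition failure).
#' @export
sensations_to_recognition <- function(net, target_id, placements,
                                      start_indices = NULL,
                                      max_sensations = 50L) {
  n_pts <- nrow(placements)
  stopifnot(n_pts >= 1)
  n_cols <- length(net$columns)
  if (is.null(start_indices)) {
    start_indices <- rep(sample.int(n_pts), length.out = n_cols)
  }
  # sample() on a length-1 vector would sample 1:x instead.
  resample <- function(x) x[sample.int(length(x))]
  # Per-column visiting order: start point, then a random tour of the
  # remaining points, refreshed if the cap outlasts one tour.
  orders <- lapply(start_indices, function(s) {
    c(s, resample(setdiff(seq_len(n_pts), s)))
  })
  pos <- rep(1L, n_cols) # index into each column's order
  for (s in seq_len(max_sensations)) {
    for (ci in seq_len(n_cols)) {
      if (s == 1L) {
        idx <- orders[[ci]][1L]
        net$columns[[ci]] <- init_from_feature(
          net$columns[[ci]], placements$feature[idx]
        )
      } else if (n_pts == 1L) {
        net$columns[[ci]] <- column_step(
          net$columns[[ci]], c(0, 0), placements$feature[1L]
        )
        next
      } else {
        if (pos[ci] >= length(orders[[ci]])) {
          here <- orders[[ci]][pos[ci]]
          orders[[ci]] <- c(here, resample(setdiff(seq_len(n_pts), here)))
          pos[ci] <- 1L
        }
        from <- orders[[ci]][pos[ci]]
        to <- orders[[ci]][pos[ci] + 1L]
        pos[ci] <- pos[ci] + 1L
        movement <- c(placements$x[to] - placements$x[from],
                      placements$y[to] - placements$y[from])
        net$columns[[ci]] <- column_step(
          net$columns[[ci]], movement, placements$feature[to]
        )
      }
    }
    net <- vote(net)
    verdicts <- vapply(net$columns, recognized, "")
    if (all(verdicts == target_id)) {
      return(s)
    }
  }
  NA_integer_
}

#' @export
print.column <- function(x, ...) {
  cat(sprintf("<column: %d objects, %d hypotheses, %s mode>\n",
              length(x$lib$objects), n_hypotheses(x), x$mode))
  invisible(x)
}

#' @export
print.column_network <- function(x, ...) {
  cat(sprintf("<column_network: %d columns%s>\n", length(x$columns),
              if (x$disagreement) ", disagreement" else ""))
  invisible(x)
}
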