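#' Behavior sequences
#'
#' An object behavior — a stapler opening, a lid rotating — is a learned
#' change of morphology: the component's placement displacement steps
#' through an ordered sequence of displacement keys.  Only the sequence
#' of displacements is learned; the object's identity never changes.
#'
#' @param id Behavior identifier.
#' @param steps Ordered displacement keys (at least 2): either canonical
#'   key strings (see [key_string()]) or a list of `displacement_key`
#'   tibbles.
#' @return An object of class `behavior_sequence`.
#' @export
behavior_sequence <- function(id, steps) {
  if (is.list(steps) && !is.character(steps)) {
    steps <- vapply(steps, key_string, "")
  }
  steps <- as.character(steps)
  if (length(steps) < 2) {
    rlang::abort("A behavior needs at least 2 steps.",
                 class = "cortexgrid_bad_behavior")
  }
  structure(list(id = id, steps = steps), class = "behavior_sequence")
}

#' @rdname behavior_sequence
#' @param lib An `object_library`.
#' @param object_id Owning object.
#' @param behavior A `behavior_sequence`.
#' @export
add_behavior <- function(lib, object_id, behavior) {
  model <- get_object(lib, object_id)
  model$behaviors[[behavior$id]] <- behavior
  lib$objects[[object_id]] <- model
  lib
}

#' Variable-order sequence memory
#'
#' A high-order sequence is one whose next element depends on more than
#' the current element: a sequence and its reverse share every element
#' but differ in context.  The model records, for every observed suffix
#' of length 1 to `max_order`, the set of symbols that followed it;
#' prediction finds the longest stored suffix of the recent history.
#' Order-2 contexts already disambiguate any pair of element-wise
#' reversed sequences at every interior position.
#'
#' @param max_order Longest context length stored (default 3).
#' @return An empty `sequence_model`.
#' @examples
#' m <- sequence_model()
#' m <- learn_sequence(m, c("A", "B", "C", "D", "E"))
#' m <- learn_sequence(m, c("E", "D", "C", "B", "A"))
#' predict_next(m, c("B", "C")) # "D"
#' predict_next(m, c("C"))      # ambiguous: "B" and "D"
#' @export
sequence_model <- function(max_order = 3L) {
  stopifnot(max_order >= 1)
  structure(list(contexts = list(), max_order = as.integer(max_order)),
            class = "sequence_model")
}

# Unit-separator join so multi-character symbols cannot alias
# (e.g. contexts ("AB","C") vs ("A","BC")).
ctx_key <- function(symbols) paste(symbols, collapse = "\x1f")

#' @rdname sequence_model
#' @param model A `sequence_model`.
#' @param seq Ordered character vector of symbols, length >= 2.
#' @export
learn_sequence <- function(model, seq) {
  seq <- as.character(seq)
  if (length(seq) < 2) {
    rlang::abort("Sequences must have at least 2 symbols.",
                 class = "cortexgrid_bad_sequence")
  }
  for (i in 2:length(seq)) {
    for (len in 1:min(i - 1L, model$max_order)) {
      key <- ctx_key(seq[(i - len):(i - 1L)])
      model$contexts[[key]] <-
        sort(unique(c(model$contexts[[key]], seq[i])))
    }
  }
  model
}

#' @rdname sequence_model
#' @param recent Ordered character vector: the most recent symbols, most
#'   recent last.
#' @return `predict_next()` returns the (sorted) set of symbols observed
#'   after the longest stored suffix of `recent`; empty if no suffix is
#'   stored.
#' @export
predict_next <- function(model, recent) {
  recent <- as.character(recent)
  if (!length(recent)) {
    rlang::abort("`recent` must be non-empty.",
                 class = "cortexgrid_bad_sequence")
  }
  for (len in seq(min(length(recent), model$max_order), 1L)) {
    key <- ctx_key(recent[(length(recent) - len + 1L):length(recent)])
    hit <- model$contexts[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
  }
  character()
}

#' @export
predict.sequence_model <- function(object, recent, ...) {
  predict_next(object, recent)
}

#' @rdname sequence_model
#' @param seed Ordered character vector to extend.
#' @param max_len Stop after the recalled sequence reaches this length.
#' @return `recall_sequence()` returns the seed extended while the full
#'   high-order context (the suffix of length `min(length, max_order)`)
#'   has been seen and predicts exactly one continuation; it stops at
#'   the first ambiguity or dead end.  Unlike [predict_next()], recall
#'   does not fall back to shorter contexts — a learned sequence's end
#'   is a dead end, not a license to replay unrelated low-order
#'   transitions.
#' @export
recall_sequence <- function(model, seed, max_len = 100L) {
  out <- as.character(seed)
  if (!length(out)) {
    rlang::abort("`seed` must be non-empty.",
                 class = "cortexgrid_bad_sequence")
  }
  while (length(out) < max_len) {
    len <- min(length(out), model$max_order)
    nxt <- model$contexts[[ctx_key(out[(length(out) - len + 1L):
                                         length(out)])]]
    if (length(nxt) != 1) {
      break
    }
    out <- c(out, nxt)
  }
  out
}

#' Move a component through a behavior step
#'
#' Replaces the placement of the parent's `component_index`-th component
#' with the displacement at `step_index` of the behavior (its key's
#' bin-center displacement code, re-tagged with the component's frames).
#' Stepping through the sequence animates the morphology — e.g. step 1 is
#' the closed stapler, the last step fully open — while [feature_at()]
#' queries always resolve against the current placement.
#'
#' @param lib An `object_library`.
#' @param parent_id Parent object id.
#' @param component_index 1-based component position.
#' @param behavior A `behavior_sequence`.
#' @param step_index 1-based step within the behavior.
#' @param ms The `module_set`.
#' @return The updated library.
#' @export
apply_behavior <- function(lib, parent_id, component_index, behavior,
                           step_index, ms) {
  parent <- get_object(lib, parent_id)
  if (component_index < 1 || component_index > length(parent$components)) {
    rlang::abort("Component index out of range.",
                 class = "cortexgrid_bad_index")
  }
  if (step_index < 1 || step_index > length(behavior$steps)) {
    rlang::abort("Behavior step index out of range.",
                 class = "cortexgrid_bad_index")
  }
  comp <- parent$components[[component_index]]
  key <- parse_key_string(behavior$steps[step_index])
  comp$placement <- key_to_displacement(
    key, ms, frame_from = parent_id, frame_to = comp$child_id
  )
  parent$components[[component_index]] <- comp
  lib$objects[[parent_id]] <- parent
  lib
}
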