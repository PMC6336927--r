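#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize result objects
#'
#' broom-style accessors: `tidy()` returns one row per element (trial,
#' feature, context, ...), `glance()` one row of summary statistics per
#' condition.
#'
#' @param x A cortexgrid result object.
#' @param ... Unused.
#' @return A tibble.
#' @name cortexgrid-tidiers
NULL

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::tidy
tidy.object_library <- function(x, ...) {
  rows <- lapply(x$objects, function(m) {
    tibble::tibble(
      object = m$id,
      key = names(m$features) %||% character(),
      feature = unname(m$features)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::glance
glance.object_library <- function(x, ...) {
  tibble::tibble(
    n_objects = length(x$objects),
    n_features = sum(vapply(x$objects, function(m) length(m$features), 0L)),
    n_components = sum(vapply(x$objects,
                              function(m) length(m$components), 0L)),
    n_behaviors = sum(vapply(x$objects, function(m) length(m$behaviors), 0L))
  )
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::tidy
tidy.sequence_model <- function(x, ...) {
  ctx <- names(x$contexts) %||% character()
  tibble::tibble(
    context = gsub("\x1f", " ", ctx, fixed = TRUE),
    order = vapply(strsplit(ctx, "\x1f", fixed = TRUE), length, 0L),
    successors = vapply(x$contexts, paste, "", collapse = ", ")
  )
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::tidy
tidy.recognition_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::glance
glance.recognition_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$n_columns),
    n_trials = dplyr::n(),
    median_sensations = stats::median(.data$sensations, na.rm = TRUE),
    fraction_at_1 = mean(!is.na(.data$sensations) & .data$sensations == 1),
    failure_rate = mean(.data$outcome == "failed"),
    .groups = "drop"
  )
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::glance
glance.capacity_report <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x),
    max_abs_deviation = max(abs(x$collision_rate - x$predicted)),
    max_z = max(abs(x$collision_rate - x$predicted) / pmax(x$se, 1e-12))
  )
}

#' @rdname cortexgrid-tidiers
#' @exportS3Method generics::glance
glance.navigation_report <- function(x, ...) {
  dec <- x$outcome == "decoded"
  tibble::tibble(
    n_trials = nrow(x),
    decoded_fraction = mean(dec),
    max_arrival_error = if (any(dec)) max(x$arrival_error[dec]) else NA_real_
  )
}
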