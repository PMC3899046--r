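# Walk serialization: JSON with stable key order, reconstructed by replaying
# the step sequence (steps are deterministic given their targets, so replay
# rebuilds the identical state and event log).

#' Serialize a walk to JSON
#'
#' Writes the configuration, the step target sequence, fiber positions, merge
#' events, self-avoiding edges and the stopped flag.  Key order is stable so
#' serialized walks diff cleanly.
#'
#' @param state a `fiber_walk` object (created with `log_events = TRUE`).
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
walk_to_json <- function(state, path = NULL) {
  snap <- walk_snapshot(state, events = TRUE)
  sa <- snap$edges$self_avoiding & !snap$edges$in_fiber
  vpos <- snap$vertices$position
  obj <- list(
    schema = "fiberwalk/walk/v1",
    config = list(dimension = state$dimension, mode = state$mode),
    steps = snap$events$step_targets,
    positions = snap$fiber$position,
    step_lengths = snap$fiber$step_length,
    merge_count = snap$events$merge_count,
    merges = lapply(snap$events$merges, function(m) {
      list(step_index = m$step_index,
           removed_position = m$removed_position,
           via_length = m$via_length,
           inherited_to = m$inherited_to,
           inherited_label = m$inherited_label,
           inherited_length = m$inherited_length,
           inherited_contraction_count = m$inherited_contraction_count)
    }),
    self_avoiding_edges = list(
      a = snap$edges$a[sa], b = snap$edges$b[sa],
      length = snap$edges$length[sa],
      contraction_count = snap$edges$contraction_count[sa]),
    stopped = snap$stopped)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Reconstruct a walk from JSON
#'
#' Replays the serialized step sequence on a fresh lattice; the resulting
#' state (and its event log) is identical to the serialized one.
#'
#' @param json a file path or a JSON string produced by [walk_to_json()].
#' @return a `fiber_walk` object.
#' @export
walk_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (is.null(obj$schema) || !startsWith(obj$schema, "fiberwalk/walk"))
    stop("invalid-input: not a serialized fiberwalk walk")
  state <- walk_state(obj$config$dimension, obj$config$mode,
                      log_events = TRUE, record_undo = TRUE)
  steps <- obj$steps
  if (length(steps)) {
    steps <- matrix(as.integer(steps), ncol = obj$config$dimension)
    for (i in seq_len(nrow(steps))) force_step(state, steps[i, ])
  }
  state
}
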