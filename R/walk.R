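# Walk state: elongation steps, lateral contraction, stopping, undo.
# The mutable state lives in the compiled engine; the R object holds the
# external pointer plus configuration and has reference semantics.

#' Create a walk state
#'
#' Initialises a walk at the origin of a freshly materialized d-dimensional
#' unit lattice.  In mode `"fiber_walk"` every elongation step triggers the
#' lateral contraction of the lattice at the new tip; in mode `"growing_saw"`
#' the process is the plain kinetic growth walk (no contraction ever).
#'
#' @param dimension lattice dimension, 2..5.
#' @param mode `"fiber_walk"` or `"growing_saw"`.
#' @param log_events record step and merge events (needed for serialization).
#' @param record_undo keep per-step undo records (needed for [undo_step()] and
#'   backtracking restarts).
#' @return an object of class `fiber_walk` (reference semantics: stepping
#'   mutates the state in place).
#' @examples
#' w <- walk_state(2, "fiber_walk")
#' feasible_edges(w)
#' @export
walk_state <- function(dimension = 2L,
                       mode = c("fiber_walk", "growing_saw"),
                       log_events = TRUE, record_undo = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(dimension) || length(dimension) != 1L || dimension < 2)
    stop("invalid-configuration: dimension must be an integer >= 2")
  if (dimension > 5)
    stop("invalid-configuration: dimensions above 5 are not supported")
  if (dimension == 5L)
    warning("dimension 5 is a hypercubic generalization; published ensemble ",
            "statistics cover d <= 4", call. = FALSE)
  ptr <- fw_new(as.integer(dimension), mode == "fiber_walk",
                isTRUE(log_events), isTRUE(record_undo))
  structure(list(ptr = ptr, dimension = as.integer(dimension), mode = mode,
                 log_events = isTRUE(log_events),
                 record_undo = isTRUE(record_undo)),
            class = "fiber_walk")
}

#' @export
print.fiber_walk <- function(x, ...) {
  cat(sprintf("<fiber_walk> d = %d, mode = %s, %d steps%s\n",
              x$dimension, x$mode, n_steps(x),
              if (is_stopped(x)) " [stopped]" else ""))
  invisible(x)
}

#' Number of steps taken so far
#' @param state a `fiber_walk` object.
#' @export
n_steps <- function(state) fw_n_steps(state$ptr)

#' Is the walk in a stopping configuration?
#'
#' A walk is stopped when every edge incident to the tip is self-avoiding,
#' i.e. no feasible elongation step remains.
#' @param state a `fiber_walk` object.
#' @export
is_stopped <- function(state) fw_stopped(state$ptr)

#' Feasible elongation edges at the tip
#'
#' All tip-incident edges whose far endpoint is not a fiber vertex
#' (equivalently, the non-self-avoiding tip edges), in deterministic
#' label-lexicographic order.  An empty result means the walk is stopped.
#'
#' @param state a `fiber_walk` object.
#' @return data frame of candidate edges (target coordinates, outgoing label,
#'   length, contraction count).
#' @export
feasible_edges <- function(state) {
  edge_view_df(fw_feasible(state$ptr), state$dimension)
}

#' Take one random elongation step
#'
#' Chooses uniformly among the feasible tip edges, extends the fiber and, in
#' mode `"fiber_walk"`, applies the lateral contraction at the new tip.
#' Consumes R's global random number stream (seed with [set.seed()]).
#'
#' @param state a `fiber_walk` object.
#' @return invisibly, a list with the step index, the step length and the
#'   number of merges the contraction performed.
#' @export
take_step <- function(state) {
  if (is_stopped(state)) stop("illegal-state: walk is stopped")
  invisible(fw_step_random(state$ptr))
}

#' Step deterministically to a given neighbour
#'
#' Extends the fiber along the feasible edge whose far endpoint sits at
#' `target` (no randomness consumed).  Used to construct specific
#' configurations and to replay serialized walks.
#'
#' @param state a `fiber_walk` object.
#' @param target integer coordinate vector of a feasible neighbour.
#' @return invisibly, the step event list.
#' @export
force_step <- function(state, target) {
  invisible(fw_step_to(state$ptr, as.integer(target)))
}

#' Undo the last step
#'
#' Reverts the last elongation step including all merges it caused and any
#' lattice materialized during it; the restored state is bit-identical to the
#' snapshot taken before the step.
#'
#' @param state a `fiber_walk` object created with `record_undo = TRUE`.
#' @return `TRUE` if a step was undone, `FALSE` at the origin.
#' @export
undo_step <- function(state) {
  if (!state$record_undo)
    stop("illegal-state: walk was created with record_undo = FALSE")
  fw_undo(state$ptr)
}

#' Lateral edges the contraction rule selects at the current tip
#'
#' Outgoing, non-self-avoiding tip edges whose label has no entry opposite in
#' sign to a nonzero entry of the last incoming (growth) label and whose
#' label differs from the growth label.  These are the edges "incident from
#' the side"; contracting merges their far endpoints into the tip.  This is a
#' non-mutating preview; in mode `"fiber_walk"` the contraction has already
#' been applied by [take_step()], so the preview is typically empty there.
#'
#' @param state a `fiber_walk` object with at least one step taken.
#' @return data frame of selected edges, label-lexicographic order.
#' @export
select_lateral_edges <- function(state) {
  edge_view_df(fw_lateral(state$ptr), state$dimension)
}

#' Contract the lattice at the current tip
#'
#' Merges the far endpoint of every edge selected by
#' [select_lateral_edges()] into the tip, in label-lexicographic order.
#' Intended for stepwise demonstration on `"growing_saw"` states; in mode
#' `"fiber_walk"` this happens automatically inside [take_step()].
#'
#' @param state a `fiber_walk` object with at least one step taken.
#' @return number of merges performed.
#' @export
contract_tip <- function(state) fw_contract(state$ptr)

#' Combine two edge-label entries
#'
#' Entrywise recalculation rule applied when a merge re-attaches an inherited
#' edge: the new entry is the sign of the sum of the merge-edge entry and the
#' inherited-edge entry, clamping the result to \{-1, 0, 1\}.
#'
#' @param a,b integer vectors with entries in \{-1, 0, 1\} (recycled).
#' @return integer vector of combined entries, each in \{-1, 0, 1\}.
#' @examples
#' combine_label_entries(1, -1)  # 0
#' combine_label_entries(0, 1)   # 1
#' @export
combine_label_entries <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(is.na(a)) || any(is.na(b)) || any(abs(a) > 1L) || any(abs(b) > 1L))
    stop("invalid-label: entries must be -1, 0 or 1")
  as.integer(sign(a + b))
}

#' Fiber positions
#' @param state a `fiber_walk` object.
#' @return integer matrix, one row per fiber vertex (origin first).
#' @export
walk_positions <- function(state) fw_positions(state$ptr)

#' Fiber step lengths
#' @param state a `fiber_walk` object.
#' @export
step_lengths <- function(state) fw_step_lengths(state$ptr)

#' Merges per step
#' @param state a `fiber_walk` object.
#' @export
merge_counts <- function(state) fw_merge_counts(state$ptr)

#' Label of the last elongation step
#' @param state a `fiber_walk` object.
#' @export
last_step_label <- function(state) fw_last_label(state$ptr)

#' Edge-length class tallies of the current state
#'
#' Counts the surviving lattice edges by exact squared length, separately for
#' fiber edges and self-avoiding edges (edges joining two fiber vertices
#' without belonging to the fiber).
#'
#' @param state a `fiber_walk` object.
#' @return list with data frames `fiber` and `self_avoiding`
#'   (`length_sq`, `length`, `count`).
#' @export
edge_classes <- function(state) {
  res <- fw_edge_classes(state$ptr)
  reshape_classes(res$fiber, res$self_avoiding)
}

reshape_classes <- function(fib, sa) {
  list(
    fiber = data.frame(length_sq = fib$length_sq,
                       length = sqrt(fib$length_sq), count = fib$count),
    self_avoiding = data.frame(length_sq = sa$length_sq,
                               length = sqrt(sa$length_sq), count = sa$count)
  )
}

#' Full state snapshot
#'
#' Materializes the engine state as plain R data: surviving vertices with
#' positions and absorbed (merged-in) original positions, surviving edges
#' with labels, lengths, contraction counts and self-avoiding flags, the
#' fiber, and (optionally) the event log of steps and merges.
#'
#' @param state a `fiber_walk` object.
#' @param events include the event log (requires `log_events = TRUE` for the
#'   merge details).
#' @return nested list; see the fields in the description.
#' @export
walk_snapshot <- function(state, events = TRUE) {
  fw_snapshot(state$ptr, isTRUE(events))
}

#' Simulate a single walk
#'
#' Runs elongation steps until the walk reaches a natural stopping
#' configuration or `max_steps`, with an optional restart policy:
#' `"backtrack"` undoes trapped steps (excluding the undone choice and
#' resampling, repeatedly) until the walk reaches `max_steps`;
#' `"rejection"` discards trapped walks and restarts from the origin.
#'
#' @param dimension lattice dimension, 2..5.
#' @param mode `"fiber_walk"` or `"growing_saw"`.
#' @param max_steps maximum walk length in steps.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param restart `"none"`, `"backtrack"` or `"rejection"`.
#' @param max_backtracks budget for backtrack undos / rejection restarts.
#' @param log_events record the event log on the returned state.
#' @return the final `fiber_walk` state; attributes `run` carries the run
#'   report (length, stopped, backtrack/restart counts).
#' @examples
#' w <- simulate_walk(2, "fiber_walk", max_steps = 20, seed = 1)
#' n_steps(w)
#' @export
simulate_walk <- function(dimension = 2L,
                          mode = c("fiber_walk", "growing_saw"),
                          max_steps = 300L, seed = NULL,
                          restart = c("none", "backtrack", "rejection"),
                          max_backtracks = 1e6, log_events = TRUE) {
  mode <- match.arg(mode)
  restart <- match.arg(restart)
  if (!is.null(seed)) set.seed(seed)
  state <- walk_state(dimension, mode, log_events = log_events,
                      record_undo = TRUE)
  rc <- fw_run(state$ptr, as.integer(max_steps), restart_code(restart),
               max_backtracks)
  if (!rc$ok)
    stop("unresolvable-walk: restart budget exhausted ",
         "(", rc$n_backtracks, " backtracks, ", rc$n_restarts, " restarts)")
  attr(state, "run") <- rc
  state
}

restart_code <- function(restart) {
  match(restart, c("none", "backtrack", "rejection")) - 1L
}
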