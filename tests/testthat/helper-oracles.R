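# Test oracles and fixtures, independent of the compiled engine wherever the
# quantity they check is produced by the engine.

# ---- pure-R kinetic growth walk (growing SAW) -------------------------------

# all 2d unit directions on Z^2
.dirs2 <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))

# Exhaustively enumerate all growing-SAW paths of exactly `len` steps on Z^2
# together with their path probabilities (product of 1/#feasible at each
# step).  Returns a named numeric vector: signature -> probability.
enumerate_gsaw_configs <- function(len) {
  out <- new.env(parent = emptyenv())
  rec <- function(pos, visited, prob, sig, depth) {
    if (depth == len) {
      assign(sig, prob, envir = out)
      return(invisible())
    }
    free <- Filter(function(d) {
      !exists(paste0(pos[1] + d[1], ",", pos[2] + d[2]), envir = visited)
    }, .dirs2)
    if (!length(free)) return(invisible())  # trapped before target length
    for (d in free) {
      np <- pos + d
      k <- paste0(np[1], ",", np[2])
      assign(k, TRUE, envir = visited)
      rec(np, visited, prob / length(free),
          paste0(sig, d[1], d[2]), depth + 1L)
      rm(list = k, envir = visited)
    }
  }
  visited <- new.env(parent = emptyenv())
  assign("0,0", TRUE, envir = visited)
  rec(c(0L, 0L), visited, 1, "", 0L)
  unlist(as.list(out))
}

# Minimum trapping length of the growing SAW among all walks of <= max_len
# steps (exhaustive enumeration, pure R).
enumerate_gsaw_min_stop <- function(max_len) {
  min_stop <- Inf
  rec <- function(pos, visited, depth) {
    if (depth >= min_stop) return(invisible())
    free <- Filter(function(d) {
      !exists(paste0(pos[1] + d[1], ",", pos[2] + d[2]), envir = visited)
    }, .dirs2)
    if (!length(free)) {
      min_stop <<- min(min_stop, depth)
      return(invisible())
    }
    if (depth == max_len) return(invisible())
    for (d in free) {
      np <- pos + d
      k <- paste0(np[1], ",", np[2])
      assign(k, TRUE, envir = visited)
      rec(np, visited, depth + 1L)
      rm(list = k, envir = visited)
    }
  }
  visited <- new.env(parent = emptyenv())
  assign("0,0", TRUE, envir = visited)
  rec(c(0L, 0L), visited, 0L)
  min_stop
}

# ---- engine-driven helpers --------------------------------------------------

# signatures of n engine-simulated growing-SAW paths of exactly `len` steps
mc_gsaw_signatures <- function(n, len) {
  vapply(seq_len(n), function(i) {
    w <- walk_state(2, "growing_saw", log_events = FALSE, record_undo = FALSE)
    for (s in seq_len(len)) take_step(w)
    p <- walk_positions(w)
    paste0(diff(p[, 1]), diff(p[, 2]), collapse = "")
  }, character(1))
}

# exhaustive minimum stopping length of the fiber walk up to `depth` steps,
# by depth-first search over the engine with undo
fiber_min_stop_exhaustive <- function(depth, dimension = 2) {
  min_stop <- Inf
  rec <- function(w, left) {
    if (is_stopped(w)) {
      min_stop <<- min(min_stop, n_steps(w))
      return(invisible())
    }
    if (left == 0L || n_steps(w) >= min_stop) return(invisible())
    fe <- feasible_edges(w)
    for (i in seq_len(nrow(fe))) {
      force_step(w, as.integer(fe[i, seq_len(w$dimension)]))
      rec(w, left - 1L)
      undo_step(w)
    }
  }
  w <- walk_state(dimension, "fiber_walk", log_events = FALSE)
  rec(w, as.integer(depth))
  min_stop
}

# walk constructed by forcing a given target sequence
make_forced_walk <- function(targets, mode = "fiber_walk", dimension = 2) {
  w <- walk_state(dimension, mode)
  for (i in seq_len(nrow(targets))) force_step(w, targets[i, ])
  w
}

# boundary sanity: closed, simple, fiber strictly inside
boundary_ok <- function(state, boundary = extract_boundary(state)) {
  pts <- boundary$points
  isTRUE(boundary$closed) &&
    all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12) &&
    polyline_is_simple(pts) &&
    all(points_strictly_inside(walk_positions(state), pts))
}
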