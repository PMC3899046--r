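# Hypercubic lattice window: explicit materialization of the integer lattice
# around the origin.  The walk engine grows its own lattice lazily; this
# object exists for inspection, examples and tests.

#' Create a hypercubic lattice window
#'
#' Materializes all integer positions within Chebyshev distance `seed_radius`
#' of the origin, fully edged with unit edges.  Every edge is bi-directed: the
#' stored label is the unit direction from `from` to `to`, the reverse label
#' is its entrywise negation.
#'
#' @param dimension integer dimension d >= 2.
#' @param seed_radius integer radius >= 1 of the materialized window
#'   (Chebyshev distance from the origin).
#' @return an object of class `fw_lattice`: a list with `dimension`,
#'   `vertices` (data frame with `id` and one `x<i>` column per coordinate)
#'   and `edges` (data frame with `from`, `to`, label columns `l<i>`,
#'   `length`, `contraction_count`, `self_avoiding`).
#' @examples
#' lat <- create_lattice(2, 1)
#' nrow(lat$vertices)  # 9
#' nrow(lat$edges)     # 12
#' @export
create_lattice <- function(dimension, seed_radius = 1L) {
  if (!is.numeric(dimension) || length(dimension) != 1L || dimension < 2)
    stop("invalid-configuration: dimension must be an integer >= 2")
  if (!is.numeric(seed_radius) || length(seed_radius) != 1L || seed_radius < 1)
    stop("invalid-configuration: seed_radius must be an integer >= 1")
  d <- as.integer(dimension)
  r <- as.integer(seed_radius)

  grid <- do.call(expand.grid, rep(list(seq.int(-r, r)), d))
  names(grid) <- paste0("x", seq_len(d))
  grid <- grid[do.call(order, as.list(grid[rev(seq_len(d))])), , drop = FALSE]
  rownames(grid) <- NULL
  pos <- as.matrix(grid)

  key <- apply(pos, 1L, paste, collapse = ",")
  id_of <- seq_len(nrow(pos))
  names(id_of) <- key

  from <- integer(0); to <- integer(0); lab <- NULL
  for (ax in seq_len(d)) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= r
    tgt <- id_of[apply(nb[ok, , drop = FALSE], 1L, paste, collapse = ",")]
    from <- c(from, id_of[ok])
    to <- c(to, unname(tgt))
    l <- matrix(0L, sum(ok), d)
    l[, ax] <- 1L
    lab <- rbind(lab, l)
  }
  colnames(lab) <- paste0("l", seq_len(d))
  edges <- data.frame(from = from, to = to, lab,
                      length = 1, contraction_count = 0L,
                      self_avoiding = FALSE)

  structure(list(dimension = d, seed_radius = r,
                 vertices = data.frame(id = id_of[key], grid, row.names = NULL),
                 edges = edges),
            class = "fw_lattice")
}

#' @export
print.fw_lattice <- function(x, ...) {
  cat(sprintf("<fw_lattice> d = %d, radius = %d: %d vertices, %d edges\n",
              x$dimension, x$seed_radius, nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Initial edge label between adjacent lattice positions
#'
#' The label of the edge from `from_pos` to `to_pos` on the uncontracted
#' lattice is the unit difference vector `to_pos - from_pos`.
#'
#' @param from_pos,to_pos integer coordinate vectors differing in exactly one
#'   coordinate by +/-1.
#' @return integer vector in \{-1, 0, 1\}^d.
#' @examples
#' initial_label(c(0, 0), c(1, 0))  # c(1, 0)
#' @export
initial_label <- function(from_pos, to_pos) {
  if (length(from_pos) != length(to_pos))
    stop("invalid-edge: positions have different dimensions")
  dl <- as.integer(to_pos) - as.integer(from_pos)
  if (sum(dl != 0L) != 1L || sum(abs(dl)) != 1L)
    stop("invalid-edge: positions are not adjacent on the unit lattice")
  dl
}

#' Edges incident to a vertex
#'
#' Lists the edges incident to a vertex together with the neighbour and the
#' outgoing label, in deterministic (label-lexicographic) order.  For a walk
#' state, missing neighbours are materialized on demand.
#'
#' @param x an `fw_lattice` or `fiber_walk` object.
#' @param v for an `fw_lattice`, a vertex id or a coordinate vector; for a
#'   `fiber_walk`, a coordinate vector.
#' @param ... unused.
#' @return a data frame with neighbour coordinates (`x<i>`), outgoing label
#'   columns (`l<i>`), `length`, `contraction_count` and `self_avoiding`.
#' @export
incident_edges <- function(x, v, ...) UseMethod("incident_edges")

#' @export
incident_edges.fw_lattice <- function(x, v, ...) {
  d <- x$dimension
  pos <- as.matrix(x$vertices[, paste0("x", seq_len(d)), drop = FALSE])
  if (length(v) == 1L) {
    vid <- as.integer(v)
    if (is.na(vid) || vid < 1L || vid > nrow(pos))
      stop("lookup error: unknown vertex id")
  } else {
    hit <- which(colSums(t(pos) != as.integer(v)) == 0L)
    if (length(hit) != 1L) stop("lookup error: unknown vertex position")
    vid <- hit
  }
  e <- x$edges
  sel <- e$from == vid | e$to == vid
  e <- e[sel, , drop = FALSE]
  lab <- as.matrix(e[, paste0("l", seq_len(d)), drop = FALSE])
  flip <- e$to == vid
  lab[flip, ] <- -lab[flip, , drop = FALSE]
  nb <- ifelse(flip, e$from, e$to)
  out <- data.frame(pos[nb, , drop = FALSE], lab,
                    length = e$length,
                    contraction_count = e$contraction_count,
                    self_avoiding = e$self_avoiding,
                    row.names = NULL)
  out[do.call(order, as.list(as.data.frame(lab))), , drop = FALSE]
}

#' @export
incident_edges.fiber_walk <- function(x, v, ...) {
  res <- fw_incident(x$ptr, as.integer(v))
  edge_view_df(res, x$dimension)
}

# shared formatter for engine edge views
edge_view_df <- function(res, d) {
  tgt <- res$target
  lab <- res$label
  colnames(tgt) <- paste0("x", seq_len(d))
  colnames(lab) <- paste0("l", seq_len(d))
  out <- data.frame(tgt, lab, length = res$length,
                    contraction_count = res$contraction_count,
                    self_avoiding = res$self_avoiding)
  rownames(out) <- NULL
  out
}

#' Export a lattice or walk snapshot as node-link JSON
#'
#' @param x an `fw_lattice` object or a `fiber_walk` state.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
lattice_to_json <- function(x, path = NULL) {
  if (inherits(x, "fiber_walk")) {
    snap <- walk_snapshot(x, events = FALSE)
    nodes <- data.frame(id = snap$vertices$id, snap$vertices$position)
    names(nodes)[-1] <- paste0("x", seq_len(x$dimension))
    nodes$in_fiber <- snap$vertices$in_fiber
    lab <- snap$edges$label
    colnames(lab) <- paste0("l", seq_len(x$dimension))
    links <- data.frame(a = snap$edges$a, b = snap$edges$b, lab,
                        length = snap$edges$length,
                        contraction_count = snap$edges$contraction_count,
                        self_avoiding = snap$edges$self_avoiding,
                        in_fiber = snap$edges$in_fiber)
    obj <- list(dimension = x$dimension, nodes = nodes, links = links)
  } else if (inherits(x, "fw_lattice")) {
    obj <- list(dimension = x$dimension, nodes = x$vertices, links = x$edges)
  } else {
    stop("lattice_to_json() expects an fw_lattice or fiber_walk object")
  }
  js <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
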