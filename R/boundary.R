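# 2D expansion boundary: the closed polyline separating the space claimed by
# the fiber (its vertices plus all merged-in positions) from the rest of the
# plane.  The polyline is assembled face by face on the unit faces of the
# embedding: faces with one or two claimed corners are crossed through their
# centroid (the dual point of the face), crossings sit on the unit edges at
# the intermediate-lattice offset from the claimed end.

# ---- face classification ----------------------------------------------------

#' Classify the lattice faces around a 2D fiber
#'
#' Every unit face sharing an edge or a vertex with the fiber (including
#' merged-in positions) is assigned one of three classes based on its
#' bounding edges: `self_avoiding` when all bounding edges are self-avoiding
#' or fiber edges, `non_self_avoiding` when none are, `mixed` otherwise.
#' Unit edges absorbed by a contraction (both endpoints claimed but no
#' surviving lattice edge covering them) count as fiber-covered.
#'
#' @param state a 2D `fiber_walk` object with at least one step taken.
#' @return data frame with the face's lower-left corner (`fx`, `fy`), its
#'   dual point (`dual_x`, `dual_y` = centroid) and `classification`.
#' @export
classify_faces <- function(state) {
  geo <- boundary_geometry(state)
  faces <- geo$faces
  stat <- geo$edge_status
  cls <- character(nrow(faces))
  for (i in seq_len(nrow(faces))) {
    es <- face_edge_status(faces$fx[i], faces$fy[i], stat, geo$claimed)
    if (all(es %in% c("self_avoiding", "fiber"))) {
      cls[i] <- "self_avoiding"
    } else if (!any(es %in% c("self_avoiding", "fiber"))) {
      cls[i] <- "non_self_avoiding"
    } else {
      cls[i] <- "mixed"
    }
  }
  data.frame(fx = faces$fx, fy = faces$fy,
             dual_x = faces$fx + 0.5, dual_y = faces$fy + 0.5,
             classification = cls)
}

# status of the 4 bounding unit edges of face (fx, fy):
# "fiber", "self_avoiding" or "plain"
face_edge_status <- function(fx, fy, stat, claimed) {
  segs <- rbind(c(fx, fy, fx + 1, fy), c(fx + 1, fy, fx + 1, fy + 1),
                c(fx, fy + 1, fx + 1, fy + 1), c(fx, fy, fx, fy + 1))
  vapply(seq_len(4), function(i) {
    k <- unit_edge_key(segs[i, 1:2], segs[i, 3:4])
    s <- stat[[k]]
    if (!is.null(s)) return(s)
    # no surviving lattice edge covers this unit edge: interior of a
    # contracted region counts as fiber-covered
    if (is_claimed(segs[i, 1:2], claimed) && is_claimed(segs[i, 3:4], claimed))
      "fiber" else "plain"
  }, character(1))
}

# ---- intermediate lattice ---------------------------------------------------

#' Intermediate-lattice offset for an edge
#'
#' Distance from the fiber endpoint at which the intermediate lattice places
#' a vertex on an edge of length `length` created by `ccount` contractions:
#' `length / (2 * (ccount + 1))`.  On unit edges this is the half-edge
#' distance 0.5; on the axis-aligned contracted edges (lengths 2 and 3) the
#' absolute offset stays at 0.5 lattice units, which leaves a central gap of
#' width `length - 2 * offset` for a future fiber plus its expansion.
#'
#' @param length edge length (lattice units).
#' @param ccount contraction count of the edge.
#' @return offset in lattice units, in (0, length / 2].
#' @examples
#' intermediate_offset(1, 0)        # 0.5
#' intermediate_offset(3, 2)        # 0.5
#' intermediate_offset(sqrt(2), 1)  # sqrt(2) / 4
#' @export
intermediate_offset <- function(length, ccount) {
  stopifnot(all(length > 0), all(ccount >= 0))
  length / (2 * (ccount + 1))
}

#' Build the intermediate lattice of a 2D walk
#'
#' For each surviving lattice edge incident to a fiber vertex and not in the
#' fiber, places a vertex at the intermediate offset from the fiber endpoint
#' (both endpoints when the edge is self-avoiding between two fiber
#' vertices).
#'
#' @param state a 2D `fiber_walk` object.
#' @return data frame with the host edge endpoints (`ax`, `ay`, `bx`, `by`;
#'   the fiber endpoint first), `offset`, and the vertex position (`x`, `y`).
#' @export
build_intermediate_lattice <- function(state) {
  if (state$dimension != 2L)
    stop("unsupported-dimension: the boundary is defined in 2D")
  snap <- walk_snapshot(state, events = FALSE)
  v <- snap$vertices
  e <- snap$edges
  pos <- v$position
  idx <- match(c(e$a, e$b), v$id)
  n <- length(e$a)
  pa <- pos[idx[seq_len(n)], , drop = FALSE]
  pb <- pos[idx[n + seq_len(n)], , drop = FALSE]
  fib_a <- v$in_fiber[match(e$a, v$id)]
  fib_b <- v$in_fiber[match(e$b, v$id)]
  out <- NULL
  for (i in seq_len(n)) {
    if (e$in_fiber[i] || (!fib_a[i] && !fib_b[i])) next
    off <- intermediate_offset(e$length[i], e$contraction_count[i])
    ends <- list()
    if (fib_a[i]) ends <- c(ends, list(list(p = pa[i, ], q = pb[i, ])))
    if (fib_b[i]) ends <- c(ends, list(list(p = pb[i, ], q = pa[i, ])))
    for (en in ends) {
      u <- (en$q - en$p) / e$length[i]
      out <- rbind(out, data.frame(
        ax = en$p[1], ay = en$p[2], bx = en$q[1], by = en$q[2],
        offset = off, x = en$p[1] + off * u[1], y = en$p[2] + off * u[2]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(ax = numeric(0), ay = numeric(0), bx = numeric(0),
                      by = numeric(0), offset = numeric(0),
                      x = numeric(0), y = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# ---- shared geometry --------------------------------------------------------

ckey <- function(x, y) paste0(x, ",", y)

unit_edge_key <- function(p, q) {
  if (p[1] > q[1] || (p[1] == q[1] && p[2] > q[2])) { t <- p; p <- q; q <- t }
  paste0(p[1], ",", p[2], "|", q[1], ",", q[2])
}

is_claimed <- function(p, claimed) !is.null(claimed[[ckey(p[1], p[2])]])

# Collects everything the face traversal needs from a walk state:
#  - claimed: environment mapping "x,y" -> TRUE for fiber + merged positions
#  - offset:  environment mapping "x,y" (fiber vertex) -> named vector of
#             crossing offsets per unit direction ("dx,dy")
#  - edge_status: environment mapping unit edge key -> "fiber" /
#             "self_avoiding" / "plain" for covered unit edges
#  - faces:   data frame of unit faces with >= 1 claimed corner
boundary_geometry <- function(state) {
  if (state$dimension != 2L)
    stop("unsupported-dimension: the boundary is defined in 2D")
  if (n_steps(state) < 1L)
    stop("degenerate-input: the walk has no steps")
  snap <- walk_snapshot(state, events = FALSE)
  v <- snap$vertices
  e <- snap$edges
  pos <- v$position
  fibv <- v$in_fiber

  claimed <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pos))) {
    if (fibv[i]) {
      assign(ckey(pos[i, 1], pos[i, 2]), TRUE, envir = claimed)
      mf <- v$merged_from[[i]]
      if (nrow(mf)) {
        for (r in seq_len(nrow(mf)))
          assign(ckey(mf[r, 1], mf[r, 2]), TRUE, envir = claimed)
      }
    }
  }

  # per fiber vertex: offsets of unit-direction incident edges
  offset <- new.env(parent = emptyenv())
  edge_status <- new.env(parent = emptyenv())
  ia <- match(e$a, v$id)
  ib <- match(e$b, v$id)
  for (i in seq_along(e$a)) {
    pa <- pos[ia[i], ]
    pb <- pos[ib[i], ]
    st <- if (e$in_fiber[i]) "fiber"
          else if (e$self_avoiding[i]) "self_avoiding" else "plain"
    dv <- pb - pa
    if (sum(dv != 0) == 1L) {
      # axis-aligned edge: mark every covered unit sub-edge
      len <- sum(abs(dv))
      u <- sign(dv)
      p <- pa
      for (s in seq_len(len)) {
        assign(unit_edge_key(p, p + u), st, envir = edge_status)
        p <- p + u
      }
    }
    off <- intermediate_offset(e$length[i], e$contraction_count[i])
    for (endp in list(list(fp = pa, fq = pb, fv = fibv[ia[i]]),
                      list(fp = pb, fq = pa, fv = fibv[ib[i]]))) {
      if (!endp$fv) next
      dd <- endp$fq - endp$fp
      if (sum(dd != 0) == 1L && sum(abs(dd)) >= 1L) {
        # the crossing of the first covered unit edge, measured from the
        # fiber endpoint (clamped into that unit edge)
        k <- ckey(endp$fp[1], endp$fp[2])
        cur <- if (exists(k, envir = offset)) get(k, envir = offset) else numeric(0)
        dk <- ckey(sign(dd[1]), sign(dd[2]))
        cur[dk] <- min(off, 0.5)
        assign(k, cur, envir = offset)
      }
    }
  }

  # faces with at least one claimed corner
  ck <- ls(claimed)
  cc <- do.call(rbind, strsplit(ck, ",", fixed = TRUE))
  cc <- matrix(as.integer(cc), ncol = 2)
  faces <- unique(data.frame(
    fx = c(cc[, 1] - 1L, cc[, 1], cc[, 1] - 1L, cc[, 1]),
    fy = c(cc[, 2] - 1L, cc[, 2] - 1L, cc[, 2], cc[, 2])))
  rownames(faces) <- NULL

  list(claimed = claimed, offset = offset, edge_status = edge_status,
       faces = faces, snapshot = snap)
}

# crossing point on the unit edge from claimed corner p to unclaimed corner q
crossing_point <- function(p, q, offset) {
  off <- 0.5
  k <- ckey(p[1], p[2])
  if (exists(k, envir = offset)) {
    ov <- get(k, envir = offset)
    d <- q - p
    dk <- ckey(d[1], d[2])
    if (!is.na(ov[dk])) off <- unname(ov[dk])
  }
  p + off * (q - p)
}

# ---- boundary extraction ----------------------------------------------------

#' Extract the 2D expansion boundary of a walk
#'
#' Builds the closed, simple polyline that separates the space claimed by the
#' fiber (fiber vertices plus all merged-in positions) from the rest of the
#' plane.  The polyline passes through the dual points (centroids) of the
#' fiber-adjacent faces and crosses fiber-incident unit edges at the
#' intermediate-lattice offset.  When the claimed region encloses unclaimed
#' pockets, only the outer loop is returned; pockets are reported separately.
#'
#' @param state a 2D `fiber_walk` object with at least one step taken.
#' @return an object of class `fw_boundary`: list with `points` (closed ring,
#'   first point repeated last), `area` (shoelace area of the outer loop),
#'   `pockets` (list of enclosed inner loops) and `closed = TRUE`.
#' @export
extract_boundary <- function(state) {
  geo <- boundary_geometry(state)
  faces <- geo$faces
  claimed <- geo$claimed
  offset <- geo$offset

  arcs <- list()      # each: list(from = key, to = key, pts = matrix)
  for (i in seq_len(nrow(faces))) {
    fx <- faces$fx[i]; fy <- faces$fy[i]
    corners <- rbind(c(fx, fy), c(fx + 1, fy), c(fx + 1, fy + 1), c(fx, fy + 1))
    cl <- vapply(seq_len(4), function(j) is_claimed(corners[j, ], claimed),
                 logical(1))
    k <- sum(cl)
    if (k == 0L || k == 4L) next
    centroid <- c(fx + 0.5, fy + 0.5)
    # face edges as corner index pairs, cyclic
    ep <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
    cross <- vector("list", 4)
    for (j in seq_len(4)) {
      a <- ep[j, 1]; b <- ep[j, 2]
      if (cl[a] != cl[b]) {
        p <- corners[if (cl[a]) a else b, ]
        q <- corners[if (cl[a]) b else a, ]
        cross[[j]] <- list(key = unit_edge_key(corners[a, ], corners[b, ]),
                           pt = crossing_point(p, q, offset))
      }
    }
    ncr <- sum(!vapply(cross, is.null, logical(1)))
    if (k == 1L || (k == 2L && ncr == 2L)) {
      # single claimed corner, or two adjacent claimed corners: one arc
      # through the dual point
      idx <- which(!vapply(cross, is.null, logical(1)))
      a <- cross[[idx[1]]]; b <- cross[[idx[2]]]
      arcs[[length(arcs) + 1L]] <-
        list(from = a$key, to = b$key, pts = rbind(a$pt, centroid, b$pt))
    } else if (k == 3L) {
      # cut off the unclaimed corner with a straight chord
      idx <- which(!vapply(cross, is.null, logical(1)))
      a <- cross[[idx[1]]]; b <- cross[[idx[2]]]
      arcs[[length(arcs) + 1L]] <-
        list(from = a$key, to = b$key, pts = rbind(a$pt, b$pt))
    } else {
      # saddle: two diagonally claimed corners.  Resolve as connected (the
      # claimed corners belong to one fiber): cut off each unclaimed corner.
      for (uc in which(!cl)) {
        je <- which(ep[, 1] == uc | ep[, 2] == uc)
        a <- cross[[je[1]]]; b <- cross[[je[2]]]
        arcs[[length(arcs) + 1L]] <-
          list(from = a$key, to = b$key, pts = rbind(a$pt, b$pt))
      }
    }
  }

  loops <- glue_arcs(arcs)
  areas <- vapply(loops, shoelace_area, numeric(1))
  outer <- which.max(abs(areas))
  ring <- loops[[outer]]
  if (areas[outer] < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring <- rbind(ring, ring[1, , drop = FALSE])
  colnames(ring) <- c("x", "y")
  pockets <- loops[-outer]
  structure(list(points = ring, area = abs(areas[outer]),
                 pockets = pockets, closed = TRUE),
            class = "fw_boundary")
}

#' @export
print.fw_boundary <- function(x, ...) {
  cat(sprintf("<fw_boundary> closed polyline, %d vertices, area %.2f, %d pocket(s)\n",
              nrow(x$points) - 1L, x$area, length(x$pockets)))
  invisible(x)
}

# joins face arcs at shared crossing keys into closed loops; every crossing
# has exactly two incident arc ends, so the loops are well-defined
glue_arcs <- function(arcs) {
  if (!length(arcs)) stop("degenerate-input: no boundary arcs")
  ends <- data.frame(arc = rep(seq_along(arcs), each = 2),
                     key = unlist(lapply(arcs, function(a) c(a$from, a$to))),
                     side = rep(c(1L, 2L), length(arcs)),
                     stringsAsFactors = FALSE)
  bykey <- split(seq_len(nrow(ends)), ends$key)
  bad <- vapply(bykey, length, integer(1)) != 2L
  if (any(bad)) stop("internal error: boundary crossing with degree != 2")
  used <- logical(length(arcs))
  loops <- list()
  for (start in seq_along(arcs)) {
    if (used[start]) next
    pts <- arcs[[start]]$pts
    used[start] <- TRUE
    cur_key <- arcs[[start]]$to
    first_key <- arcs[[start]]$from
    while (cur_key != first_key) {
      cand <- bykey[[cur_key]]
      nxt <- ends$arc[cand][!used[ends$arc[cand]]]
      if (!length(nxt)) stop("internal error: open boundary chain")
      nxt <- nxt[1]
      a <- arcs[[nxt]]
      seg <- a$pts
      if (a$from != cur_key) {
        seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
        cur_key <- a$from
      } else {
        cur_key <- a$to
      }
      pts <- rbind(pts, seg[-1, , drop = FALSE])
      used[nxt] <- TRUE
    }
    loops[[length(loops) + 1L]] <- pts[-nrow(pts), , drop = FALSE]
  }
  loops
}

shoelace_area <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# ---- boundary checks, smoothing, export ------------------------------------

#' Check right-angle avoidance along the boundary
#'
#' For every right-angle turn of the fiber, verifies that the inner side of
#' the turn is covered: either the boundary contributes a vertex strictly on
#' the inner side, or the inner side lies strictly inside the boundary (the
#' contraction absorbed it, so the boundary does not pass the turn at all).
#' Additionally checks that the two boundary segments meeting at the boundary
#' vertex nearest the turn are not both axis-parallel and mutually
#' perpendicular (which would be a curvature singularity at the turn).
#'
#' @param state a 2D `fiber_walk` object.
#' @param boundary the corresponding `fw_boundary` (computed when missing).
#' @return data frame, one row per turn: turn vertex, whether an inner-side
#'   boundary vertex exists (`inner_vertex`), whether the inner side is
#'   enclosed by the boundary (`inner_enclosed`), and whether the nearest
#'   boundary corner is a plain axis-parallel right angle
#'   (`axis_right_angle`).  Attribute `pass` summarises the check.
#' @export
check_right_angle_avoidance <- function(state, boundary = NULL) {
  if (state$dimension != 2L)
    stop("unsupported-dimension: the boundary is defined in 2D")
  if (is.null(boundary)) boundary <- extract_boundary(state)
  pos <- walk_positions(state)
  pts <- boundary$points[-nrow(boundary$points), , drop = FALSE]
  res <- NULL
  if (nrow(pos) >= 3) {
    for (i in 2:(nrow(pos) - 1)) {
      a <- pos[i, ] - pos[i - 1, ]
      b <- pos[i + 1, ] - pos[i, ]
      if (sum(a * b) != 0) next   # not a right angle
      v <- pos[i, ]
      # inner side of the turn: the quadrant spanned by -a and +b
      ua <- -a / sqrt(sum(a^2)); ub <- b / sqrt(sum(b^2))
      rel <- sweep(pts, 2, v)
      sa <- rel %*% ua; sb <- rel %*% ub
      inner <- which(sa > 1e-9 & sb > 1e-9 &
                     sa < sqrt(sum(a^2)) & sb < sqrt(sum(b^2)))
      has_inner <- length(inner) > 0
      mid <- v + 0.5 * ua + 0.5 * ub
      enclosed <- points_strictly_inside(rbind(mid), boundary$points)
      # nearest boundary vertex to the turn
      dist2 <- rowSums(rel^2)
      ni <- which.min(dist2)
      np <- nrow(pts)
      prev <- pts[if (ni == 1) np else ni - 1, ]
      nxt <- pts[if (ni == np) 1 else ni + 1, ]
      s1 <- pts[ni, ] - prev
      s2 <- nxt - pts[ni, ]
      axis1 <- any(abs(s1) < 1e-9)
      axis2 <- any(abs(s2) < 1e-9)
      perp <- abs(sum(s1 * s2)) < 1e-9
      singular <- axis1 && axis2 && perp
      res <- rbind(res, data.frame(x = v[1], y = v[2],
                                   inner_vertex = has_inner,
                                   inner_enclosed = enclosed,
                                   axis_right_angle = singular))
    }
  }
  if (is.null(res)) {
    res <- data.frame(x = numeric(0), y = numeric(0),
                      inner_vertex = logical(0),
                      inner_enclosed = logical(0),
                      axis_right_angle = logical(0))
  }
  attr(res, "pass") <- all(res$inner_vertex | res$inner_enclosed) &&
    !any(res$axis_right_angle)
  res
}

#' Smooth a boundary by corner-cutting subdivision
#'
#' One iteration replaces every vertex of the closed polyline by the two
#' points at 1/4 and 3/4 of its incident segments (Chaikin's corner cutting,
#' the subdivision scheme of the quadratic B-spline).  Topology is preserved:
#' the result is closed and simple, with twice the vertices per iteration.
#'
#' @param boundary an `fw_boundary` object (closed).
#' @param iterations non-negative integer; 0 returns the input unchanged.
#' @return an `fw_boundary` object.
#' @export
smooth_boundary <- function(boundary, iterations = 1L) {
  if (!inherits(boundary, "fw_boundary") || !isTRUE(boundary$closed))
    stop("invalid-input: smoothing needs a closed boundary polyline")
  if (iterations < 0) stop("invalid-input: iterations must be >= 0")
  ring <- boundary$points[-nrow(boundary$points), , drop = FALSE]
  for (it in seq_len(iterations)) {
    nxt <- ring[c(2:nrow(ring), 1), , drop = FALSE]
    q <- 0.75 * ring + 0.25 * nxt
    r <- 0.25 * ring + 0.75 * nxt
    ring <- matrix(t(cbind(q, r)), ncol = 2, byrow = TRUE)  # interleave q, r
  }
  pts <- rbind(ring, ring[1, , drop = FALSE])
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, area = abs(shoelace_area(ring)),
                 pockets = boundary$pockets, closed = TRUE),
            class = "fw_boundary")
}

#' Write boundary points to CSV
#' @param boundary an `fw_boundary` object.
#' @param path output file.
#' @export
write_boundary_csv <- function(boundary, path) {
  write.csv(as.data.frame(boundary$points), path, row.names = FALSE)
  invisible(path)
}

#' Boundary as a GeoJSON polygon string
#' @param boundary an `fw_boundary` object.
#' @param path optional output file.
#' @export
boundary_to_geojson <- function(boundary, path = NULL) {
  ring <- boundary$points
  obj <- list(type = "Feature",
              geometry = list(type = "Polygon",
                              coordinates = list(unname(ring))),
              properties = list(area = boundary$area))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# ---- small polygon utilities (used by checks and tests) ---------------------

#' Are points strictly inside a closed polygon?
#' @param pts two-column matrix of points.
#' @param ring closed ring matrix (first point repeated last).
#' @return logical vector.
#' @export
points_strictly_inside <- function(pts, ring) {
  open <- ring[-nrow(ring), , drop = FALSE]
  res <- pracma::inpolygon(pts[, 1], pts[, 2], open[, 1], open[, 2],
                           boundary = FALSE)
  as.logical(res)
}

#' Is a closed polyline simple (no self-intersections)?
#' @param ring closed ring matrix (first point repeated last).
#' @return logical scalar.
#' @export
polyline_is_simple <- function(ring) {
  p <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(FALSE)
  if (anyDuplicated(round(p, 9))) return(FALSE)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    js <- seq.int(i + 1, n)
    # skip adjacent segments (shared endpoint)
    js <- js[js != i + 1 & !(i == 1 & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

# vectorised proper/improper segment intersection: segment (p1, p2) against
# rows of (q1, q2)
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2[, 1] - q1[, 1], q2[, 2] - q1[, 2],
               p1[1] - q1[, 1], p1[2] - q1[, 2])
  d2 <- cross2(q2[, 1] - q1[, 1], q2[, 2] - q1[, 2],
               p2[1] - q1[, 1], p2[2] - q1[, 2])
  d3 <- cross2(p2[1] - p1[1], p2[2] - p1[2], q1[, 1] - p1[1], q1[, 2] - p1[2])
  d4 <- cross2(p2[1] - p1[1], p2[2] - p1[2], q2[, 1] - p1[1], q2[, 2] - p1[2])
  eps <- 1e-12
  proper <- (d1 * d2 < -eps) & (d3 * d4 < -eps)
  onseg <- function(px, py, ax, ay, bx, by, d) {
    abs(d) <= eps & px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
      py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
  }
  touch <- onseg(p1[1], p1[2], q1[, 1], q1[, 2], q2[, 1], q2[, 2], d1) |
    onseg(p2[1], p2[2], q1[, 1], q1[, 2], q2[, 1], q2[, 2], d2) |
    onseg(q1[, 1], q1[, 2], p1[1], p1[2], p2[1], p2[2], d3) |
    onseg(q2[, 1], q2[, 2], p1[1], p1[2], p2[1], p2[2], d4)
  proper | touch
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
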