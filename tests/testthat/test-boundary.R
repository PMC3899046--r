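# 2D boundary reconstruction: face classification, intermediate lattice,
# polyline extraction, right-angle behaviour, smoothing, export.

test_that("faces around the fiber receive exactly one of three classes", {
  # 1-step growing SAW: corner faces are plain, edge faces are mixed
  g <- make_forced_walk(rbind(c(1L, 0L)), mode = "growing_saw")
  cf <- classify_faces(g)
  expect_true(all(cf$classification %in%
                  c("self_avoiding", "non_self_avoiding", "mixed")))
  cls <- function(fx, fy) cf$classification[cf$fx == fx & cf$fy == fy]
  expect_equal(cls(-1, 0), "non_self_avoiding")  # shares only the origin corner
  expect_equal(cls(0, 0), "mixed")               # one fiber edge, rest plain
  expect_equal(cf$dual_x, cf$fx + 0.5)

  # U-shaped walk: the enclosed face is bounded by fiber + self-avoiding
  # edges only
  u <- make_forced_walk(rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L)),
                        mode = "growing_saw")
  cfu <- classify_faces(u)
  expect_equal(cfu$classification[cfu$fx == 0 & cfu$fy == 0], "self_avoiding")
})

test_that("intermediate offsets follow length / (2 (c + 1))", {
  expect_equal(intermediate_offset(1, 0), 0.5)
  expect_equal(intermediate_offset(sqrt(2), 1), sqrt(2) / 4)
  expect_equal(intermediate_offset(3, 2), 0.5)
  # a length-3 edge keeps a central gap of width 2 between its two
  # intermediate vertices
  expect_equal(3 - 2 * intermediate_offset(3, 2), 2)
  expect_equal(intermediate_offset(2, 1), 0.5)
})

test_that("the intermediate lattice places vertices on fiber-incident edges", {
  g <- make_forced_walk(rbind(c(1L, 0L)), mode = "growing_saw")
  il <- build_intermediate_lattice(g)
  expect_equal(nrow(il), 6L)           # 6 non-fiber edges touch the fiber
  expect_true(all(il$offset == 0.5))
  expect_setequal(paste(il$x, il$y),
                  c("-0.5 0", "0 0.5", "0 -0.5", "1 0.5", "1 -0.5", "1.5 0"))

  # contracted edges get offset L / (2 (c + 1))
  f <- make_forced_walk(rbind(c(1L, 0L)))
  ilf <- build_intermediate_lattice(f)
  diag <- ilf[abs(ilf$offset - sqrt(2) / 4) < 1e-9, ]
  expect_equal(nrow(diag), 4L)
  long <- ilf[ilf$offset == 0.5 & abs(ilf$bx - ilf$ax) + abs(ilf$by - ilf$ay) == 2, ]
  expect_equal(nrow(long), 2L)         # the two length-2 inherited edges
})

test_that("a 1-step walk yields the dodecagonal loop through duals and midpoints", {
  g <- make_forced_walk(rbind(c(1L, 0L)), mode = "growing_saw")
  b <- extract_boundary(g)
  expect_true(boundary_ok(g, b))
  expect_equal(nrow(b$points), 13L)    # 12 vertices + closing point
  got <- unique(round(b$points, 9))
  duals <- rbind(c(-0.5, 0.5), c(0.5, 0.5), c(1.5, 0.5),
                 c(-0.5, -0.5), c(0.5, -0.5), c(1.5, -0.5))
  mids <- rbind(c(-0.5, 0), c(0, 0.5), c(0, -0.5),
                c(1, 0.5), c(1, -0.5), c(1.5, 0))
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(rbind(duals, mids)[, 1], rbind(duals, mids)[, 2]))
  expect_equal(b$area, 2)
  expect_equal(length(b$pockets), 0L)
})

test_that("the 2-step fiber walk has a single closed loop with the fiber inside", {
  w <- make_forced_walk(rbind(c(1L, 0L), c(2L, 0L)))
  b <- extract_boundary(w)
  expect_true(boundary_ok(w, b))
  expect_equal(length(b$pockets), 0L)
  # merged-in vertices are enclosed as well
  snap <- walk_snapshot(w, events = FALSE)
  absorbed <- do.call(rbind, snap$vertices$merged_from)
  expect_true(all(points_strictly_inside(absorbed, b$points)))
})

test_that("random seeded walks always produce closed simple boundaries", {
  set.seed(41)
  for (i in 1:20) {
    w <- simulate_walk(2, "fiber_walk", max_steps = 40, log_events = FALSE)
    expect_true(boundary_ok(w))
  }
})

test_that("enclosed area is non-decreasing as the walk grows", {
  set.seed(43)
  w <- walk_state(2, "fiber_walk", log_events = FALSE)
  areas <- numeric(0)
  for (k in 1:20) {
    if (is_stopped(w)) break
    take_step(w)
    areas <- c(areas, extract_boundary(w)$area)
  }
  expect_false(is.unsorted(areas))
})

test_that("boundary extraction is reproducible after serialization", {
  set.seed(47)
  w <- simulate_walk(2, "fiber_walk", max_steps = 30)
  w2 <- walk_from_json(walk_to_json(w))
  expect_identical(extract_boundary(w)$points, extract_boundary(w2)$points)
})

test_that("degenerate and unsupported inputs are rejected", {
  w0 <- walk_state(2, "fiber_walk")
  expect_error(extract_boundary(w0), "degenerate-input")
  w3 <- make_forced_walk(rbind(c(1L, 0L, 0L)), dimension = 3)
  expect_error(extract_boundary(w3), "unsupported-dimension")
  expect_error(classify_faces(w3), "unsupported-dimension")
  expect_error(check_right_angle_avoidance(w3), "unsupported-dimension")
})

test_that("right-angle turns contribute an inner boundary vertex", {
  # straight fiber: vacuously passes
  s <- make_forced_walk(rbind(c(1L, 0L), c(2L, 0L)))
  rs <- check_right_angle_avoidance(s)
  expect_equal(nrow(rs), 0L)
  expect_true(attr(rs, "pass"))

  # perpendicular continuation after a contracted step
  t1 <- make_forced_walk(rbind(c(1L, 0L), c(1L, 2L)))
  rt <- check_right_angle_avoidance(t1)
  expect_equal(nrow(rt), 1L)
  expect_true(all(rt$inner_vertex))
  expect_false(any(rt$axis_right_angle))
  expect_true(attr(rt, "pass"))

  # turns in free-running fiber walks keep the property
  set.seed(59)
  for (i in 1:5) {
    w <- simulate_walk(2, "fiber_walk", max_steps = 30, log_events = FALSE)
    expect_true(attr(check_right_angle_avoidance(w), "pass"))
  }
})

test_that("corner-cutting subdivision preserves topology", {
  ring <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  colnames(ring) <- c("x", "y")
  sq <- structure(list(points = ring, area = 1, pockets = list(),
                       closed = TRUE),
                  class = "fw_boundary")
  expect_identical(smooth_boundary(sq, 0)$points, sq$points)
  oct <- smooth_boundary(sq, 1)
  expect_equal(nrow(oct$points) - 1L, 8L)
  expect_true(polyline_is_simple(oct$points))
  # closed-form corner cutting of the unit square
  expect_setequal(paste(oct$points[-9, 1], oct$points[-9, 2]),
                  c("0.25 0", "0.75 0", "1 0.25", "1 0.75",
                    "0.75 1", "0.25 1", "0 0.75", "0 0.25"))
  two <- smooth_boundary(sq, 2)
  expect_equal(nrow(two$points) - 1L, 16L)
  expect_true(polyline_is_simple(two$points))
  open <- sq; open$closed <- FALSE
  expect_error(smooth_boundary(open, 1), "invalid-input")
})

test_that("boundaries export as CSV and GeoJSON", {
  w <- make_forced_walk(rbind(c(1L, 0L)))
  b <- extract_boundary(w)
  csv <- tempfile(fileext = ".csv")
  write_boundary_csv(b, csv)
  back <- read.csv(csv)
  expect_equal(as.matrix(back), b$points, ignore_attr = TRUE)
  gj <- jsonlite::fromJSON(boundary_to_geojson(b))
  expect_equal(gj$geometry$type, "Polygon")
  expect_equal(dim(gj$geometry$coordinates[1, , ]), dim(b$points))
  unlink(csv)
})
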