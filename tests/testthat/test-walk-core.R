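test_that("label entries combine as the sign of their sum", {
  expect_identical(combine_label_entries(1, -1), 0L)
  expect_identical(combine_label_entries(0, 1), 1L)
  # exhaustive 9-case table stays within {-1, 0, 1}
  grid <- expand.grid(a = -1:1, b = -1:1)
  got <- combine_label_entries(grid$a, grid$b)
  expect_true(all(got %in% -1:1))
  expect_identical(got, as.integer(sign(grid$a + grid$b)))
  expect_error(combine_label_entries(2, 0), "invalid-label")
  expect_error(combine_label_entries(0, -3), "invalid-label")
})

test_that("a fresh walk has 2d feasible edges and steps uniformly", {
  w <- walk_state(2, "fiber_walk")
  fe <- feasible_edges(w)
  expect_equal(nrow(fe), 4L)
  expect_true(all(fe$length == 1))
  w3 <- walk_state(3, "fiber_walk")
  expect_equal(nrow(feasible_edges(w3)), 6L)

  # Monte-Carlo frequency of each first step within 3 sigma of 1/4
  set.seed(2024)
  n <- 40000L
  first <- vapply(seq_len(n), function(i) {
    w <- walk_state(2, "growing_saw", log_events = FALSE, record_undo = FALSE)
    take_step(w)
    p <- walk_positions(w)
    paste0(p[2, 1], ",", p[2, 2])
  }, character(1))
  counts <- table(first)
  expect_equal(length(counts), 4L)
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < 3 * sigma))
})

test_that("the first fiber step reproduces the elongation + expansion sequence", {
  # step (0,0) -> (1,0): both side vertices merge into the tip
  w <- make_forced_walk(rbind(c(1L, 0L)))
  expect_identical(merge_counts(w), 2L)
  expect_identical(last_step_label(w), c(1L, 0L))

  snap <- walk_snapshot(w)
  mf <- snap$vertices$merged_from[[which(snap$vertices$id == snap$fiber$vertex_id[2])]]
  expect_equal(mf[order(mf[, 2]), ], rbind(c(1L, -1L), c(1L, 1L)),
               ignore_attr = TRUE)

  # follow-up steps of length 1, sqrt(2) and 2 (7 feasible targets)
  fe <- feasible_edges(w)
  expect_equal(nrow(fe), 7L)
  expect_setequal(round(fe$length^2), c(1, 2, 2, 2, 2, 4, 4))
  tgt <- paste(fe$x1, fe$x2)
  expect_setequal(tgt, c("2 0", "0 1", "0 -1", "2 1", "2 -1", "1 2", "1 -2"))

  # merge events carry the recalculated labels and lengths
  ev <- snap$events$merges
  expect_equal(length(ev), 2L)
  inherited <- do.call(rbind, lapply(ev, function(m)
    cbind(m$inherited_label, m$inherited_length, m$inherited_contraction_count)))
  expect_true(all(inherited[, 1:2] %in% -1:1))
  expect_setequal(round(inherited[, 3]^2), c(2, 2, 4, 2, 2, 4))
  expect_true(all(inherited[, 4] == 1))
})

test_that("lateral selection follows the sign-compatibility rule", {
  # growth label (1,0), both sides free -> labels (0,-1) and (0,1)
  g <- make_forced_walk(rbind(c(1L, 0L)), mode = "growing_saw")
  sel <- select_lateral_edges(g)
  expect_equal(as.matrix(sel[, c("l1", "l2")]), rbind(c(0, -1), c(0, 1)),
               ignore_attr = TRUE)

  # a side neighbour already in the fiber is excluded (self-avoiding edge)
  g2 <- make_forced_walk(rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L)),
                         mode = "growing_saw")
  expect_identical(last_step_label(g2), c(0L, -1L))
  sel2 <- select_lateral_edges(g2)
  expect_equal(nrow(sel2), 1L)
  expect_equal(unlist(sel2[1, c("l1", "l2")]), c(l1 = 1, l2 = 0))

  # 3D, growth label (0,0,1) -> the four perpendicular unit edges
  g3 <- make_forced_walk(rbind(c(0L, 0L, 1L)), mode = "growing_saw",
                         dimension = 3)
  sel3 <- select_lateral_edges(g3)
  expect_equal(nrow(sel3), 4L)
  expect_true(all(sel3$l3 == 0))
  expect_true(all(sel3$length == 1))
  # manual contraction merges exactly those four
  expect_equal(contract_tip(g3), 4L)
})

test_that("contraction performs 0 to 2(d-1) merges per step", {
  # 2D straight step with free sides: exactly 2; 4D free step: 6
  expect_equal(merge_counts(make_forced_walk(rbind(c(1L, 0L)))), 2L)
  w4 <- make_forced_walk(rbind(c(1L, 0L, 0L, 0L)), dimension = 4)
  expect_equal(merge_counts(w4), 6L)

  # corridor: both side vertices already belong to the fiber -> 0 merges
  # (the hook (0,0),(0,-1),(1,-1),(2,-1),(2,0),(2,1),(1,1),(1,0) sandwiches
  # the tip between fiber vertices; it is also a stopping configuration)
  cor <- walk_state(2, "growing_saw")
  for (tgt in list(c(0L, -1L), c(1L, -1L), c(2L, -1L), c(2L, 0L),
                   c(2L, 1L), c(1L, 1L), c(1L, 0L)))
    force_step(cor, tgt)
  expect_identical(last_step_label(cor), c(0L, -1L))
  expect_equal(nrow(select_lateral_edges(cor)), 0L)
  expect_equal(contract_tip(cor), 0L)
  expect_true(is_stopped(cor))

  # property: random fiber walks never exceed the bound
  set.seed(11)
  for (d in 2:4) {
    w <- simulate_walk(d, "fiber_walk", max_steps = 60, log_events = FALSE)
    expect_true(all(merge_counts(w) <= 2 * (d - 1)))
    expect_true(all(cumsum(merge_counts(w)) == sort(cumsum(merge_counts(w)))))
  }
})

test_that("merging is forbidden across self-avoiding edges", {
  # after (0,1),(1,1),(1,0) the edge back to the origin is self-avoiding;
  # the contraction may only absorb the free side
  g <- make_forced_walk(rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L)),
                        mode = "growing_saw")
  snap <- walk_snapshot(g, events = FALSE)
  sa <- snap$edges$self_avoiding & !snap$edges$in_fiber
  expect_equal(sum(sa), 1L)  # the (1,0)-(0,0) edge
  sel <- select_lateral_edges(g)
  expect_equal(nrow(sel), 1L)
  expect_equal(c(sel$x1, sel$x2), c(2, 0))
  expect_equal(contract_tip(g), 1L)
})

test_that("inherited edges reaching fiber vertices become self-avoiding", {
  # turning walks create non-fiber edges between fiber vertices; their
  # lengths stay in the five classes and include contracted ones
  seen <- integer(0)
  for (s in 1:8) {
    w <- simulate_walk(2, "fiber_walk", max_steps = 30, seed = s,
                       log_events = FALSE)
    snap <- walk_snapshot(w, events = FALSE)
    sa <- snap$edges$self_avoiding & !snap$edges$in_fiber
    expect_true(any(sa))
    cls <- round(snap$edges$length[sa]^2)
    expect_true(all(cls %in% c(1, 2, 4, 5, 9)))
    expect_true(all(snap$edges$contraction_count[sa] >= 0))
    seen <- union(seen, cls)
  }
  expect_true(all(c(2, 4, 5) %in% seen))  # contracted classes do occur
})

test_that("stepping a stopped walk is an error and stopping is detected", {
  w <- walk_state(2, "fiber_walk", log_events = FALSE)
  set.seed(4)
  while (!is_stopped(w)) take_step(w)
  expect_equal(nrow(feasible_edges(w)), 0L)
  expect_error(take_step(w), "illegal-state")
})

test_that("seeded runs are bit-reproducible and gsaw never merges", {
  a <- simulate_walk(2, "fiber_walk", max_steps = 80, seed = 123)
  b <- simulate_walk(2, "fiber_walk", max_steps = 80, seed = 123)
  expect_identical(walk_to_json(a), walk_to_json(b))

  g <- simulate_walk(2, "growing_saw", max_steps = 120, seed = 5)
  expect_equal(sum(merge_counts(g)), 0L)
  expect_true(all(step_lengths(g) == 1))
})

test_that("backtracking restarts drive walks to the requested length", {
  set.seed(9)
  w <- simulate_walk(2, "fiber_walk", max_steps = 120, restart = "backtrack")
  expect_equal(n_steps(w), 120L)
  r <- simulate_walk(2, "fiber_walk", max_steps = 120, restart = "rejection",
                     seed = 10)
  expect_equal(n_steps(r), 120L)
})
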