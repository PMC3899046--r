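# Distributional and structural invariants of the walk process.

test_that("growing-SAW configuration frequencies match exhaustive enumeration", {
  # exhaustive path probabilities for all 6-step walks (pure-R oracle),
  # compared with engine Monte-Carlo frequencies by chi-square
  probs <- enumerate_gsaw_configs(6L)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(length(probs), 780L)  # c_6, the 6-step self-avoiding paths

  set.seed(61)
  n <- 30000L
  sig <- mc_gsaw_signatures(n, 6L)
  counts <- table(factor(sig, levels = names(probs)))
  expect_equal(sum(counts), n)  # every signature was enumerated
  ct <- suppressWarnings(stats::chisq.test(as.vector(counts), p = probs))
  expect_gt(ct$p.value, 0.01)
})

test_that("minimum stopping lengths agree with exhaustive enumeration", {
  # growing SAW: pure-R enumeration of all walks up to 8 steps
  expect_equal(enumerate_gsaw_min_stop(8L), 7)
  set.seed(17)
  g <- simulate_ensemble(2, "growing_saw", n_walks = 20000, max_steps = 10)
  stops <- g$stopping_length[g$stopped_naturally]
  expect_gte(min(stops), 7L)
  expect_equal(min(stops), 7L)

  # fiber walk: exhaustive depth-first search over the engine
  expect_equal(fiber_min_stop_exhaustive(5L), 4)
  f <- simulate_ensemble(2, "fiber_walk", n_walks = 5000, max_steps = 10)
  fstops <- f$stopping_length[f$stopped_naturally]
  expect_equal(min(fstops), 4L)
})

test_that("fibers are simple paths with the 2D edge-length classes", {
  set.seed(31)
  for (i in 1:10) {
    w <- simulate_walk(2, "fiber_walk", max_steps = 80, log_events = FALSE)
    p <- walk_positions(w)
    expect_equal(anyDuplicated(p), 0L)                       # Def: all distinct
    expect_true(all(round(step_lengths(w)^2) %in% c(1, 2, 4)))
    snap <- walk_snapshot(w, events = FALSE)
    sa <- snap$edges$self_avoiding & !snap$edges$in_fiber
    expect_true(all(round(snap$edges$length[sa]^2) %in% c(1, 2, 4, 5, 9)))
    # every stored label entry stays in {-1, 0, 1}
    expect_true(all(snap$edges$label %in% -1:1))
    expect_true(all(rowSums(abs(snap$edges$label)) > 0))
    # edge lengths equal endpoint distances
    idx <- match(c(snap$edges$a, snap$edges$b), snap$vertices$id)
    n <- length(snap$edges$a)
    pa <- snap$vertices$position[idx[seq_len(n)], , drop = FALSE]
    pb <- snap$vertices$position[idx[n + seq_len(n)], , drop = FALSE]
    expect_equal(sqrt(rowSums((pa - pb)^2)), snap$edges$length,
                 tolerance = 1e-12)
  }
})

test_that("merged-from sets are disjoint and merges stay within bounds", {
  set.seed(37)
  for (d in 2:4) {
    w <- simulate_walk(d, "fiber_walk", max_steps = 50, log_events = FALSE)
    snap <- walk_snapshot(w, events = FALSE)
    absorbed <- do.call(rbind, snap$vertices$merged_from)
    if (!is.null(absorbed) && nrow(absorbed))
      expect_equal(anyDuplicated(absorbed), 0L)
    expect_true(all(merge_counts(w) <= 2 * (d - 1)))
  }
})

test_that("undo restores the serialized state bit-exactly", {
  set.seed(21)
  w <- walk_state(2, "fiber_walk")
  for (i in 1:10) take_step(w)
  before_json <- walk_to_json(w)
  before_snap <- walk_snapshot(w)
  take_step(w)
  take_step(w)
  expect_true(undo_step(w))
  expect_true(undo_step(w))
  expect_identical(walk_to_json(w), before_json)
  expect_identical(walk_snapshot(w), before_snap)
  # undoing everything returns to the origin, then refuses
  for (i in 1:10) expect_true(undo_step(w))
  expect_false(undo_step(w))
  expect_equal(n_steps(w), 0L)
})

test_that("event-log replay reconstructs the identical state", {
  set.seed(53)
  w <- simulate_walk(2, "fiber_walk", max_steps = 60)
  js <- walk_to_json(w)
  w2 <- walk_from_json(js)
  expect_identical(walk_to_json(w2), js)
  expect_identical(walk_snapshot(w2), walk_snapshot(w))
})

test_that("growing-SAW mode matches the contraction-free distribution", {
  # with contraction disabled the step-length multiset is all ones and the
  # stopping-time distribution differs from the fiber walk's
  set.seed(71)
  g <- simulate_ensemble(2, "growing_saw", 3000, 300, collect = "classes")
  expect_equal(g$fiber_classes$length_sq, 1L)
  expect_equal(nrow(g$sa_classes), 1L)  # unit self-avoiding edges only
  f <- simulate_ensemble(2, "fiber_walk", 3000, 300)
  ks <- two_sample_ks(g$stopping_length, f$stopping_length)
  expect_lt(ks$p.value, 0.05)
})
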