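# Ensemble statistics: stopping times, KS comparison, MSD scaling machinery,
# contraction scaling, edge-class tallies.

test_that("stopping-time ensembles respect max_steps and censoring", {
  s1 <- stopping_time_ensemble(2, "growing_saw", n_walks = 200, max_steps = 1,
                               seed = 1)
  expect_true(all(s1$lengths == 1))      # no walk can stop before its first step
  expect_true(all(s1$censored))
  expect_equal(s1$median, 1L)

  s <- stopping_time_ensemble(2, "fiber_walk", n_walks = 500, max_steps = 300,
                              seed = 2)
  expect_true(all(s$lengths <= 300))
  expect_equal(s$median, cdf_median(s$lengths))
  expect_equal(unname(s$cdf(s$median) >= 0.5), TRUE)
  expect_true(all(diff(s$cdf(sort(unique(s$lengths)))) >= 0))
})

test_that("the KS test behaves on degenerate and real samples", {
  expect_equal(two_sample_ks(1:50, 1:50)$statistic, 0)
  ks <- two_sample_ks(1:50, 101:150)
  expect_equal(ks$statistic, 1)
  expect_lt(ks$p.value, 1e-6)
  expect_error(two_sample_ks(numeric(0), 1:3), "invalid-input")
})

test_that("MSD curves start at 1 and carry per-walk matrices", {
  m <- msd_curve(2, "fiber_walk", n_walks = 100, max_steps = 60, seed = 3)
  expect_equal(m$msd[1], 1)                  # unit first step, exactly
  expect_true(all(m$msd >= 0))
  expect_equal(m$n_contributing, rep(100L, 60))
  expect_equal(dim(m$sq_displacement), c(100L, 60L))
})

test_that("scaling-region detection finds power laws and changepoints", {
  n <- 200
  pure <- list(steps = 1:n, msd = (1:n)^1.17)
  expect_equal(detect_scaling_region(pure), c(lo = 30L, hi = 200L))
  expect_equal(detect_scaling_region(pure, threshold = Inf),
               c(lo = 30L, hi = 200L))

  # transient bump before step 60: the region must start at or after 60
  bump <- list(steps = 1:n,
               msd = (1:n)^1.0 * c(rep(2.5, 59), rep(1, n - 59)))
  reg <- detect_scaling_region(bump)
  expect_gte(reg["lo"], 60L)

  expect_error(detect_scaling_region(list(steps = 1:10, msd = 1:10)),
               "insufficient-data")
})

test_that("exponent fitting recovers closed forms", {
  n <- 200
  curve <- list(steps = 1:n, msd = as.numeric(1:n), sq_displacement = NULL)
  fit <- fit_exponent(curve, region = c(30, 200), n_boot = 0)
  expect_equal(fit$nu, 0.5, tolerance = 1e-12)  # msd = N exactly
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_error(fit_exponent(list(steps = 1:2, msd = c(1, 2)), region = c(1, 2)),
               "insufficient-data")
})

test_that("the simple-random-walk control recovers nu = 1/2", {
  srw <- simulate_simple_walk(2, n_walks = 600, max_steps = 150, seed = 4)
  m <- msd_curve(ensemble = srw)
  expect_equal(m$msd[1], 1)
  fit <- fit_exponent(m, n_boot = 300)
  expect_lt(abs(fit$nu - 0.5), 3 * fit$nu_se)
  expect_lt(abs(fit$nu - 0.5), 0.05)
})

test_that("contraction scaling is 1 for constant merges per step", {
  fake <- list(config = list(mode = "fiber_walk"),
               cum_merges = matrix(rep(2 * (1:150), each = 40), nrow = 40))
  fit <- contraction_scaling(ensemble = fake, n_boot = 0)
  expect_equal(fit$nu, 1, tolerance = 1e-12)

  notf <- list(config = list(mode = "growing_saw"), cum_merges = fake$cum_merges)
  expect_error(contraction_scaling(ensemble = notf), "invalid-mode")
})

test_that("edge-length tallies respect the theoretical classes", {
  h <- edge_length_histogram(2, "fiber_walk", n_walks = 150, max_steps = 100,
                             seed = 5)
  fib <- h[h$edge_set == "fiber", ]
  sa <- h[h$edge_set == "self_avoiding", ]
  expect_true(all(fib$length_sq %in% c(1, 2, 4)))
  expect_true(all(sa$length_sq %in% c(1, 2, 4, 5, 9)))
  expect_equal(fib$length, sqrt(fib$length_sq))

  g <- edge_length_histogram(2, "growing_saw", n_walks = 50, max_steps = 100,
                             seed = 6)
  expect_true(all(g$length == 1))
})

test_that("fiber walks outrun the growing SAW in the transient region", {
  f <- msd_curve(2, "fiber_walk", n_walks = 200, max_steps = 60, seed = 7)
  g <- msd_curve(2, "growing_saw", n_walks = 200, max_steps = 60, seed = 8)
  tr <- 2:29
  expect_true(mean(f$msd[tr] > g$msd[tr]) > 0.9)
})
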