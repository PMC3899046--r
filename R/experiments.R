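# Ensemble statistics: stopping-time distributions, mean-square-displacement
# scaling with scaling-region detection and bootstrap errors, contraction
# scaling, and edge-length class tallies.

#' Stopping-time distribution of an ensemble
#'
#' Runs walks with no restart policy to their natural stopping configuration
#' (or `max_steps`, recorded as censored) and returns the empirical
#' distribution of stopping lengths.  The median is the smallest length at
#' which at least half of the walks have terminated.
#'
#' @inheritParams simulate_ensemble
#' @param ensemble optionally, a precomputed `fw_ensemble` with
#'   `restart = "none"` to reuse.
#' @return an object of class `fw_stopping`: list with `lengths`, `censored`,
#'   `cdf` (a step function), `median` and `config`.
#' @export
stopping_time_ensemble <- function(dimension = 2L,
                                   mode = c("fiber_walk", "growing_saw"),
                                   n_walks = 10000L, max_steps = 300L,
                                   seed = NULL, ensemble = NULL) {
  mode <- match.arg(mode)
  if (is.null(ensemble)) {
    ensemble <- simulate_ensemble(dimension, mode, n_walks, max_steps,
                                  seed = seed, restart = "none")
  } else if (!identical(ensemble$config$restart, "none")) {
    stop("invalid-input: stopping times need an ensemble without restarts")
  }
  lengths <- ensemble$stopping_length
  structure(list(lengths = lengths,
                 censored = !ensemble$stopped_naturally,
                 cdf = stats::ecdf(lengths),
                 median = cdf_median(lengths),
                 config = ensemble$config),
            class = "fw_stopping")
}

# smallest length L with empirical CDF(L) >= 1/2
cdf_median <- function(lengths) {
  s <- sort(lengths)
  s[ceiling(length(s) / 2)]
}

#' @export
print.fw_stopping <- function(x, ...) {
  cat(sprintf("<fw_stopping> %d walks (%s, d = %d): median stopping length %d, %d censored\n",
              length(x$lengths), x$config$mode, x$config$dimension,
              x$median, sum(x$censored)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS statistic and asymptotic p-value, used to compare
#' stopping-length distributions.
#'
#' @param a,b numeric samples (or `fw_stopping` objects).
#' @return list with `statistic` (D) and `p.value`.
#' @export
two_sample_ks <- function(a, b) {
  if (inherits(a, "fw_stopping")) a <- a$lengths
  if (inherits(b, "fw_stopping")) b <- b$lengths
  if (!length(a) || !length(b)) stop("invalid-input: empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Mean-square-displacement curve of an ensemble
#'
#' Average squared Euclidean distance from the origin position to the tip
#' position as a function of the step count.  By default walks are driven to
#' the full `max_steps` with backtracking restarts so every step has the full
#' ensemble behind it.
#'
#' @inheritParams simulate_ensemble
#' @param restart `"backtrack"` (default) or `"rejection"`; the restart
#'   policy overrides natural stopping configurations.
#' @param ensemble optionally a precomputed `fw_ensemble` with a
#'   `sq_displacement` matrix (e.g. from [simulate_simple_walk()]).
#' @return an object of class `fw_msd`: list with `steps`, `msd`,
#'   `n_contributing`, the per-walk matrix `sq_displacement` and `config`.
#' @export
msd_curve <- function(dimension = 2L, mode = c("fiber_walk", "growing_saw"),
                      n_walks = 1000L, max_steps = 200L, seed = NULL,
                      restart = c("backtrack", "rejection"),
                      ensemble = NULL) {
  if (is.null(ensemble)) {
    mode <- match.arg(mode)
    restart <- match.arg(restart)
    ensemble <- simulate_ensemble(dimension, mode, n_walks, max_steps,
                                  seed = seed, restart = restart,
                                  collect = "displacement")
  }
  sq <- ensemble$sq_displacement
  if (is.null(sq)) stop("invalid-input: ensemble lacks displacement data")
  msd <- colMeans(sq, na.rm = TRUE)
  structure(list(steps = seq_len(ncol(sq)), msd = msd,
                 n_contributing = colSums(!is.na(sq)),
                 sq_displacement = sq,
                 config = ensemble$config),
            class = "fw_msd")
}

#' @export
print.fw_msd <- function(x, ...) {
  cat(sprintf("<fw_msd> %s, d = %d: %d steps, msd(1) = %.3f, msd(max) = %.1f\n",
              x$config$mode, x$config$dimension, length(x$steps),
              x$msd[1], x$msd[length(x$msd)]))
  invisible(x)
}

#' Detect the scaling region of an MSD curve
#'
#' Local log-log slopes are estimated by least squares over a sliding window
#' of sample points; the scaling region is the maximal suffix, starting no
#' earlier than `start`, over which the local slope deviates from the
#' terminal slope by less than `threshold`.  Sample points are log-spaced so
#' that the windows have comparable extent in `log(steps)` everywhere (with
#' linear spacing the window extent shrinks like 1/s and the local slope of a
#' Monte-Carlo curve degenerates into noise at large step counts).
#'
#' @param curve an `fw_msd` object (or any list with `steps` and `msd`).
#' @param threshold allowed slope deviation (default 0.1).
#' @param start earliest admissible region start in steps (default 30).
#' @param window window width in sample points for the local slope
#'   (default 5).
#' @param n_samples number of log-spaced sample points (default 25).
#' @return integer vector `c(lo, hi)` in steps.
#' @export
detect_scaling_region <- function(curve, threshold = 0.1, start = 30L,
                                  window = 5L, n_samples = 25L) {
  steps <- curve$steps
  msd <- curve$msd
  n <- length(steps)
  if (n < start) stop("insufficient-data: curve shorter than the region start")
  smp <- unique(round(exp(seq(log(steps[1]), log(steps[n]),
                              length.out = n_samples))))
  smp <- smp[smp >= steps[1] & smp <= steps[n]]
  idx <- match(smp, steps)
  lx <- log(steps[idx])
  ly <- log(msd[idx])
  m <- length(idx)
  half <- window %/% 2
  if (m < window + 1) stop("insufficient-data: too few sample points")
  centers <- seq.int(1 + half, m - half)
  slopes <- vapply(centers, function(i) {
    j <- (i - half):(i + half)
    x <- lx[j] - mean(lx[j])
    sum(x * ly[j]) / sum(x^2)
  }, numeric(1))
  terminal <- slopes[length(slopes)]
  dev_ok <- abs(slopes - terminal) < threshold
  # maximal suffix of windows within the threshold; the region starts at the
  # left edge of the first window of that suffix
  first <- length(centers)
  for (i in rev(seq_along(centers))) {
    if (!dev_ok[i]) break
    first <- i
  }
  lo <- max(as.integer(start), as.integer(smp[centers[first] - half]))
  c(lo = lo, hi = as.integer(steps[n]))
}

#' Fit the MSD scaling exponent
#'
#' Least-squares line on (log steps, log msd) within the scaling region; the
#' scaling exponent is `nu = slope / 2` (so the ordinary diffusive random
#' walk has `nu = 1/2`).  The standard error of `nu` is estimated by
#' bootstrap over walks.
#'
#' @param curve an `fw_msd` object.
#' @param region integer `c(lo, hi)`; detected with default settings when
#'   missing.
#' @param n_boot bootstrap replicates (resampling walks, default 1000); 0
#'   skips the bootstrap.
#' @return an object of class `fw_scaling_fit`: `nu`, `slope`, `region`,
#'   `nu_se`, `slope_se`, `n_walks`.
#' @export
fit_exponent <- function(curve, region = NULL, n_boot = 1000L) {
  if (is.null(region)) region <- detect_scaling_region(curve)
  idx <- which(curve$steps >= region[1] & curve$steps <= region[2])
  if (length(idx) < 3) stop("insufficient-data: fewer than 3 points in region")
  lx <- log(curve$steps[idx])
  slope <- loglog_slope(lx, curve$msd[idx])
  se <- NA_real_
  sq <- curve$sq_displacement
  if (!is.null(sq) && n_boot > 0) {
    sqr <- sq[, idx, drop = FALSE]
    nw <- nrow(sqr)
    bs <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(nw, nw, replace = TRUE)
      loglog_slope(lx, colMeans(sqr[rows, , drop = FALSE], na.rm = TRUE))
    }, numeric(1))
    se <- stats::sd(bs)
  }
  structure(list(nu = slope / 2, slope = slope,
                 region = region, nu_se = se / 2, slope_se = se,
                 n_walks = if (is.null(sq)) NA_integer_ else nrow(sq)),
            class = "fw_scaling_fit")
}

loglog_slope <- function(lx, y) {
  ly <- log(y)
  x <- lx - mean(lx)
  sum(x * ly) / sum(x^2)
}

#' @export
print.fw_scaling_fit <- function(x, ...) {
  cat(sprintf("<fw_scaling_fit> slope %.3f (nu = %.3f +/- %s) on steps [%d, %d]\n",
              x$slope, x$nu,
              if (is.na(x$nu_se)) "NA" else sprintf("%.3f", x$nu_se),
              x$region[1], x$region[2]))
  invisible(x)
}

#' Scaling of the cumulative contraction count
#'
#' Log-log slope of the mean cumulative merge count against the step count
#' for fiber walks, using the same scaling-region rule and walk bootstrap as
#' [fit_exponent()]; the slope is reported directly (not halved), so a
#' constant merges-per-step process has exponent 1.
#'
#' @inheritParams msd_curve
#' @param ensemble optionally a precomputed fiber-walk `fw_ensemble` with a
#'   `cum_merges` matrix.
#' @param n_boot bootstrap replicates.
#' @return an `fw_scaling_fit` whose `slope` is the contraction exponent.
#' @export
contraction_scaling <- function(dimension = 2L, n_walks = 1000L,
                                max_steps = 200L, seed = NULL,
                                restart = c("backtrack", "rejection"),
                                ensemble = NULL, n_boot = 1000L) {
  if (is.null(ensemble)) {
    restart <- match.arg(restart)
    ensemble <- simulate_ensemble(dimension, "fiber_walk", n_walks, max_steps,
                                  seed = seed, restart = restart,
                                  collect = "merges")
  }
  if (!identical(ensemble$config$mode, "fiber_walk"))
    stop("invalid-mode: contraction scaling is defined for fiber walks")
  cm <- ensemble$cum_merges
  if (is.null(cm)) stop("invalid-input: ensemble lacks merge counts")
  curve <- list(steps = seq_len(ncol(cm)), msd = colMeans(cm, na.rm = TRUE),
                sq_displacement = cm)
  region <- detect_scaling_region(curve)
  fit <- fit_exponent(curve, region, n_boot = n_boot)
  fit$nu <- fit$slope        # report the raw slope as the exponent
  fit$nu_se <- fit$slope_se
  fit
}

#' Edge-length class histogram of an ensemble
#'
#' Tallies the exact length classes of fiber edges and self-avoiding edges
#' pooled over a fiber-walk ensemble.  In 2D the fiber classes are a subset
#' of \{1, sqrt(2), 2\} and the self-avoiding classes a subset of
#' \{1, sqrt(2), 2, sqrt(5), 3\}.
#'
#' @inheritParams simulate_ensemble
#' @param ensemble optionally a precomputed `fw_ensemble` with class tallies.
#' @return data frame with `edge_set` (`fiber` / `self_avoiding`),
#'   `length_sq`, `length` and `count`.
#' @export
edge_length_histogram <- function(dimension = 2L,
                                  mode = c("fiber_walk", "growing_saw"),
                                  n_walks = 1000L, max_steps = 200L,
                                  seed = NULL,
                                  restart = c("none", "backtrack", "rejection"),
                                  ensemble = NULL) {
  if (is.null(ensemble)) {
    mode <- match.arg(mode)
    restart <- match.arg(restart)
    ensemble <- simulate_ensemble(dimension, mode, n_walks, max_steps,
                                  seed = seed, restart = restart,
                                  collect = "classes")
  }
  if (is.null(ensemble$fiber_classes))
    stop("invalid-input: ensemble lacks edge class tallies")
  fib <- ensemble$fiber_classes
  sa <- ensemble$sa_classes
  out <- rbind(
    data.frame(edge_set = rep("fiber", nrow(fib)), fib),
    data.frame(edge_set = rep("self_avoiding", nrow(sa)), sa))
  rownames(out) <- NULL
  out
}
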