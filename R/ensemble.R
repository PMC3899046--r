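# Ensemble driver: many independent walks, aggregated statistics collected in
# compiled code.  One R RNG stream feeds the whole ensemble, so a single seed
# reproduces it exactly.

#' Simulate an ensemble of walks
#'
#' Runs `n_walks` independent walks with a shared configuration and collects
#' per-walk stopping lengths plus, optionally, per-step squared displacement
#' from the origin, per-step cumulative merge counts, and edge-length class
#' tallies pooled over the ensemble.
#'
#' @inheritParams simulate_walk
#' @param n_walks number of walks.
#' @param collect character vector, any of `"displacement"`, `"merges"`,
#'   `"classes"`.
#' @return an object of class `fw_ensemble`: a list with `stopping_length`,
#'   `stopped_naturally`, optional matrices `sq_displacement` and
#'   `cum_merges` (walks x steps, `NA`-padded after natural stops), optional
#'   tallies `fiber_classes` / `sa_classes`, and the `config` used.
#' @examples
#' ens <- simulate_ensemble(2, "growing_saw", n_walks = 50, max_steps = 50,
#'                          seed = 1)
#' median(ens$stopping_length)
#' @export
simulate_ensemble <- function(dimension = 2L,
                              mode = c("fiber_walk", "growing_saw"),
                              n_walks = 1000L, max_steps = 300L, seed = NULL,
                              restart = c("none", "backtrack", "rejection"),
                              collect = character(0), max_backtracks = 2e4) {
  mode <- match.arg(mode)
  restart <- match.arg(restart)
  if (length(collect))
    collect <- match.arg(collect, c("displacement", "merges", "classes"),
                         several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  res <- fw_ensemble(as.integer(dimension), mode == "fiber_walk",
                     as.integer(n_walks), as.integer(max_steps),
                     restart_code(restart), max_backtracks,
                     "displacement" %in% collect,
                     "merges" %in% collect,
                     "classes" %in% collect)
  if (!is.null(res$fiber_classes)) {
    cls <- reshape_classes(res$fiber_classes, res$sa_classes)
    res$fiber_classes <- cls$fiber
    res$sa_classes <- cls$self_avoiding
  }
  res$config <- list(dimension = as.integer(dimension), mode = mode,
                     n_walks = as.integer(n_walks),
                     max_steps = as.integer(max_steps),
                     restart = restart, seed = seed)
  class(res) <- "fw_ensemble"
  res
}

#' @export
print.fw_ensemble <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<fw_ensemble> %d %s walks, d = %d, max %d steps, restart = %s\n",
              cf$n_walks, cf$mode, cf$dimension, cf$max_steps, cf$restart))
  cat(sprintf("  stopping length: median %s, %.1f%% stopped naturally\n",
              median(x$stopping_length),
              100 * mean(x$stopped_naturally)))
  invisible(x)
}

#' Simple (non-avoiding) random walk control
#'
#' Ordinary nearest-neighbour random walk on the same lattice, used as the
#' diffusive control for the mean-square-displacement scaling (its exponent
#' is 1/2 in the step count by the classical closed form <R^2> = N).
#'
#' @param dimension lattice dimension.
#' @param n_walks number of walks.
#' @param max_steps walk length.
#' @param seed optional integer seed.
#' @return `fw_ensemble`-like list with a `sq_displacement` matrix.
#' @export
simulate_simple_walk <- function(dimension = 2L, n_walks = 1000L,
                                 max_steps = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- as.integer(dimension)
  sq <- matrix(0, n_walks, max_steps)
  for (w in seq_len(n_walks)) {
    ax <- sample.int(d, max_steps, replace = TRUE)
    sgn <- sample(c(-1L, 1L), max_steps, replace = TRUE)
    pos <- matrix(0L, max_steps, d)
    pos[cbind(seq_len(max_steps), ax)] <- sgn
    pos <- apply(pos, 2L, cumsum)
    sq[w, ] <- rowSums(pos^2)
  }
  structure(list(stopping_length = rep(max_steps, n_walks),
                 stopped_naturally = rep(FALSE, n_walks),
                 sq_displacement = sq,
                 config = list(dimension = d, mode = "simple_walk",
                               n_walks = as.integer(n_walks),
                               max_steps = as.integer(max_steps),
                               restart = "none", seed = seed)),
            class = "fw_ensemble")
}
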