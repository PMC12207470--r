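#' Simulate piecewise-constant migration trajectories
#'
#' Builds replicate trajectory files of the kind produced by
#' isolation-with-migration post-processing: contiguous segments of
#' constant per-generation migration rate `m`. Replicate pairs optionally
#' perturb `m` by a lognormal factor (mimicking between-pair estimation
#' noise) so that pair aggregation can be tested against a known truth.
#' Truth threshold-crossing times of the noise-free trajectory are
#' recorded twice: by the closed-form inversion ([threshold_times()]) and
#' by independent fine-grid integration ([integrate_M_grid()]).
#'
#' @param segments data.frame (or 2-column matrix) with columns
#'   `duration` (generations, > 0) and `m` (per-generation rate, >= 0).
#' @param pairs number of replicate pair trajectories to generate.
#' @param noise_sd SD of the lognormal log-factor applied to `m` per
#'   replicate (0 = identical replicates).
#' @param thresholds truth crossing thresholds.
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, one TSV per pair is written there
#'   (mutation-scaled boundaries when `mu` is supplied).
#' @param mu mutation rate used when writing scaled files; `NULL` writes
#'   generation units.
#' @param pair_prefix label prefix for replicate pairs.
#' @return list with `trajectories` (list of [migration_trajectory()]),
#'   `truth` (data.frame of closed-form and grid-integrated crossing
#'   times per threshold), and `files` (paths or `NULL`).
#' @export
simulate_migration_trajectory <- function(segments, pairs = 1L,
                                          noise_sd = 0,
                                          thresholds = c(0.50, 0.95, 0.99),
                                          seed = 1L, out_dir = NULL,
                                          mu = NULL,
                                          pair_prefix = "pair") {
  segments <- as.data.frame(segments)
  if (!all(c("duration", "m") %in% names(segments)))
    stop("segments needs columns 'duration' and 'm'")
  if (any(segments$duration <= 0)) stop("durations must be positive")
  if (any(segments$m < 0)) stop("negative migration rate")
  set.seed(seed)

  right <- cumsum(segments$duration)
  left <- c(0, right[-length(right)])
  base <- migration_trajectory(left, right, segments$m, pair = "truth")

  closed <- threshold_times(base, thresholds)
  grid_t <- vapply(seq_along(thresholds), function(k) {
    if (!closed$reached[k]) return(NA_real_)
    ## bisection on the grid-integrated M, independent of the closed form
    f <- function(t) integrate_M_grid(base, t) - thresholds[k]
    lo <- 0; hi <- right[length(right)]
    if (f(hi) < 0) return(NA_real_)
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  truth <- data.frame(threshold = thresholds,
                      time_gen_closed = closed$time_gen,
                      time_gen_grid = grid_t,
                      reached = closed$reached)

  trajs <- lapply(seq_len(pairs), function(i) {
    fac <- if (noise_sd > 0) exp(rnorm(1, 0, noise_sd)) else 1
    migration_trajectory(left, right, segments$m * fac,
                         pair = sprintf("%s_%02d", pair_prefix, i))
  })
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- vapply(trajs, function(tr) {
      f <- file.path(out_dir, paste0(tr$pair, ".migration.tsv"))
      write_trajectory_tsv(tr, f, mu = mu)
      f
    }, character(1))
  }
  list(trajectories = trajs, truth = truth, files = files)
}
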