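#' Piecewise-constant migration-rate trajectory
#'
#' Output of an isolation-with-migration analysis for one pair of
#' individuals: contiguous time segments with a symmetric per-generation
#' migration rate `m`, optionally with a published cumulative migration
#' probability column `M`.
#'
#' @param left,right numeric segment boundaries in generations,
#'   non-decreasing and contiguous (`right[i] == left[i + 1]`).
#' @param m per-generation migration rate per segment, `>= 0`.
#' @param M optional published cumulative migration probability at the
#'   right boundary of each segment.
#' @param pair label for the individual/population pair.
#' @return A `migration_trajectory`.
#' @export
migration_trajectory <- function(left, right, m, M = NULL, pair = NA) {
  stopifnot(length(left) == length(right), length(m) == length(left))
  if (any(m < 0)) stop("negative migration rate")
  if (any(right < left)) stop("segment boundaries must be non-decreasing")
  if (length(left) > 1L &&
      any(abs(left[-1L] - right[-length(right)]) > 1e-9 * pmax(1, right[-length(right)])))
    stop("segments must be contiguous")
  if (!is.null(M) && (any(diff(M) < -1e-12) || any(M < 0 | M > 1)))
    stop("published M must be non-decreasing in [0, 1]")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 m = as.numeric(m), M = M, pair = pair),
            class = "migration_trajectory")
}

#' @export
print.migration_trajectory <- function(x, ...) {
  cat("migration_trajectory (", x$pair, "): ", length(x$m),
      " segments over [", x$left[1], ", ", x$right[length(x$right)],
      "] generations\n", sep = "")
  invisible(x)
}

#' Read a migration trajectory from TSV
#'
#' Accepts the tab-separated dialect with header columns
#' `left_time_boundary`, `right_time_boundary`, `m` and optionally `M`
#' (extra columns are ignored). Time units are auto-detected: boundary
#' values below `1e-2` are treated as mutation-scaled (`t * mu`) and
#' converted to generations by dividing by `mu`; larger values are taken
#' as generations. `m` is always interpreted per generation.
#'
#' @param path TSV file path.
#' @param mu mutation rate per site per generation used for unscaling.
#' @param time_units `"auto"`, `"generations"`, or `"scaled"` to override
#'   detection.
#' @param pair pair label attached to the trajectory.
#' @return A [migration_trajectory()] in generation units.
#' @export
read_trajectory_tsv <- function(path, mu = 1.826e-8,
                                time_units = c("auto", "generations",
                                               "scaled"),
                                pair = basename(path)) {
  time_units <- match.arg(time_units)
  d <- read.delim(path, check.names = FALSE)
  need <- c("left_time_boundary", "right_time_boundary", "m")
  if (!all(need %in% names(d)))
    stop("trajectory TSV must have columns: ", paste(need, collapse = ", "))
  left <- d$left_time_boundary; right <- d$right_time_boundary
  scaled <- switch(time_units,
                   auto = max(right) < 1e-2,
                   scaled = TRUE,
                   generations = FALSE)
  if (scaled) { left <- left / mu; right <- right / mu }
  migration_trajectory(left, right, d$m,
                       M = if ("M" %in% names(d)) d$M else NULL,
                       pair = pair)
}

#' Write a migration trajectory as TSV
#'
#' @param traj a [migration_trajectory()] (generation units).
#' @param path output path.
#' @param mu if non-`NULL`, boundaries are written mutation-scaled
#'   (`t * mu`); otherwise in generations.
#' @param with_M include the cumulative probability column computed by
#'   [cumulative_migration()].
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path, mu = NULL, with_M = TRUE) {
  d <- data.frame(left_time_boundary = traj$left,
                  right_time_boundary = traj$right,
                  m = traj$m)
  if (with_M) d$M <- cumulative_migration(traj)$M_right
  if (!is.null(mu)) {
    d$left_time_boundary <- d$left_time_boundary * mu
    d$right_time_boundary <- d$right_time_boundary * mu
  }
  write.table(format(d, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative migration probability M(t)
#'
#' Under an isolation-with-migration model with symmetric piecewise
#' constant rate `m(t)`, the probability that the ancestral lineages of
#' the pair have exchanged by time `t` is
#' `M(t) = 1 - exp(-integral_0^t 2 m(u) du)`. Within segment `i` starting
#' at `(t_i, M_i)` this is `M(t) = 1 - (1 - M_i) * exp(-2 m_i (t - t_i))`.
#'
#' @param traj a [migration_trajectory()].
#' @return list with `segments` (data.frame `left`, `right`, `m`,
#'   `M_left`, `M_right`), `M_fun` (vectorized function evaluating M(t);
#'   constant beyond the last boundary), and `published_deviation` (max
#'   absolute difference from a published `M` column, or `NA`).
#' @export
cumulative_migration <- function(traj) {
  if (any(traj$m < 0)) stop("negative migration rate")
  dur <- traj$right - traj$left
  cumint <- cumsum(2 * traj$m * dur)          # 2 * integral of m
  M_right <- 1 - exp(-cumint)
  M_left <- c(0, M_right[-length(M_right)])
  segs <- data.frame(left = traj$left, right = traj$right, m = traj$m,
                     M_left = M_left, M_right = M_right)
  M_fun <- function(t) {
    vapply(t, function(tt) {
      if (tt <= traj$left[1]) return(0)
      i <- findInterval(tt, traj$left)
      tt <- min(tt, traj$right[length(traj$right)])
      1 - (1 - M_left[i]) * exp(-2 * traj$m[i] * (tt - traj$left[i]))
    }, numeric(1))
  }
  dev <- if (is.null(traj$M)) NA_real_ else max(abs(traj$M - M_right))
  list(segments = segs, M_right = M_right, M_fun = M_fun,
       published_deviation = dev)
}

#' Grid-integration evaluation of M(t)
#'
#' Independent numerical check of [cumulative_migration()]: integrates
#' `2 m(u)` on a fine regular grid (step `<=` 1 generation by default)
#' with the midpoint rule, which is exact for piecewise-constant rates up
#' to grid alignment.
#'
#' @param traj a [migration_trajectory()].
#' @param t times (generations) at which to evaluate M.
#' @param step grid step in generations.
#' @return numeric vector of M values.
#' @export
integrate_M_grid <- function(traj, t, step = 1) {
  m_of <- function(u) {
    i <- findInterval(u, traj$left)
    ifelse(i < 1 | u > traj$right[length(traj$right)], 0, traj$m[pmax(i, 1)])
  }
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    ## integrate exactly over segment pieces, subdividing long ones
    brk <- sort(unique(c(0, traj$left, traj$right, tt)))
    brk <- brk[brk <= tt]
    if (max(brk) < tt) brk <- c(brk, tt)
    total <- 0
    for (k in seq_len(length(brk) - 1L)) {
      a <- brk[k]; b <- brk[k + 1L]
      ns <- max(1L, ceiling((b - a) / step))
      mids <- a + (seq_len(ns) - 0.5) * (b - a) / ns
      total <- total + sum(m_of(mids)) * (b - a) / ns
    }
    1 - exp(-2 * total)
  }, numeric(1))
}

#' Threshold-crossing times of M(t)
#'
#' Exact within-segment inversion: for the first segment where `M`
#' crosses the threshold `theta`,
#' `t* = t_i + ln((1 - M_i) / (1 - theta)) / (2 m_i)`. Thresholds never
#' reached are flagged, never extrapolated.
#'
#' @param traj a [migration_trajectory()].
#' @param thresholds numeric in (0, 1), default `c(0.50, 0.95, 0.99)`.
#' @param gen_time generation time in years; if non-`NULL` a
#'   `time_years` column is added (`generations * gen_time`).
#' @return data.frame `pair`, `threshold`, `time_gen`, `reached`
#'   (and `time_years` when `gen_time` given).
#' @export
threshold_times <- function(traj, thresholds = c(0.50, 0.95, 0.99),
                            gen_time = NULL) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  cm <- cumulative_migration(traj)
  segs <- cm$segments
  t_star <- vapply(thresholds, function(theta) {
    i <- which(segs$M_right >= theta)[1]
    if (is.na(i)) return(NA_real_)
    segs$left[i] + log((1 - segs$M_left[i]) / (1 - theta)) /
      (2 * segs$m[i])
  }, numeric(1))
  out <- data.frame(pair = traj$pair, threshold = thresholds,
                    time_gen = t_star, reached = !is.na(t_star))
  if (!is.null(gen_time)) out$time_years <- out$time_gen * gen_time
  out
}

#' Truncate a trajectory where M(t) reaches a cutoff
#'
#' Segments beyond the crossing of `cutoff` are removed and the crossing
#' segment is cut at the crossing time. A trajectory that never reaches
#' the cutoff is returned unchanged.
#'
#' @param traj a [migration_trajectory()].
#' @param cutoff cumulative probability in (0, 1), default 0.999.
#' @return A [migration_trajectory()].
#' @export
truncate_trajectory <- function(traj, cutoff = 0.999) {
  if (cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly inside (0, 1)")
  tt <- threshold_times(traj, cutoff)
  if (!tt$reached) return(traj)
  t_star <- tt$time_gen
  keep <- traj$left < t_star
  migration_trajectory(traj$left[keep], pmin(traj$right[keep], t_star),
                       traj$m[keep], pair = traj$pair)
}

#' Convert a mutation-scaled time to years
#'
#' `generations = t_scaled / mu`; `years = generations * gen_time`.
#'
#' @param t_scaled non-negative mutation-scaled time(s) (`t * mu`).
#' @param mu mutation rate per site per generation (default 1.826e-8).
#' @param gen_time generation time in years (default 10).
#' @return time(s) in years.
#' @export
scale_to_years <- function(t_scaled, mu = 1.826e-8, gen_time = 10) {
  if (mu <= 0 || gen_time <= 0) stop("mu and gen_time must be positive")
  if (any(t_scaled < 0)) stop("t_scaled must be non-negative")
  t_scaled / mu * gen_time
}

#' Aggregate threshold times over individual-pair replicates
#'
#' Arithmetic mean and sample SD (n - 1 denominator) per population pair
#' and threshold. Replicates that never reached a threshold are excluded
#' from that threshold's aggregate, with the exclusion count reported.
#'
#' @param reports data.frame as returned by [threshold_times()]
#'   (rows from several replicate trajectories bound together); the
#'   column `time_years` is used when present, else `time_gen`.
#' @return data.frame `pair`, `threshold`, `mean`, `sd`, `n`,
#'   `n_not_reached`, `empty`.
#' @export
aggregate_pairs <- function(reports) {
  val <- if ("time_years" %in% names(reports)) reports$time_years
         else reports$time_gen
  key <- interaction(reports$pair, reports$threshold, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    v <- val[sel][reports$reached[sel]]
    data.frame(pair = reports$pair[sel][1],
               threshold = reports$threshold[sel][1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               n = length(v),
               n_not_reached = sum(!reports$reached[sel]),
               empty = length(v) == 0L)
  })
  out <- do.call(rbind, rows)
  out[order(out$pair, out$threshold), , drop = FALSE]
}
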