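TEETH <- c("P2", "P3", "P4", "M1")

#' Load and subset a tooth-measurement table
#'
#' Reads specimen-level postcanine measurements and applies the
#' completeness rule: for each measure family (length, height, top-cusp
#' angle, cusp count), a specimen enters that analysis only if the
#' measure is present for all four right postcanines P2, P3, P4, M1.
#' Specimens flagged with dental anomalies are excluded entirely. Rows
#' for other sides (a `side` column not equal to `"R"`) are ignored with
#' a log note.
#'
#' @param x CSV path or data.frame with columns `specimen_id`,
#'   `population`, `sex`, `tooth`, `length_mm`, `height_mm`,
#'   `top_cusp_angle_deg`, `cusp_count`; optional `anomaly` (logical)
#'   and `side`.
#' @return A `tooth_table`: list with `data` (retained rows),
#'   `complete` (per measure family, the specimen ids passing the
#'   completeness rule), and `log` (exclusion counts).
#' @export
load_tooth_table <- function(x) {
  d <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("specimen_id", "population", "tooth")
  if (!all(need %in% names(d)))
    stop("tooth table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(d$tooth), TEETH)
  if (length(bad)) stop("unknown tooth label: ", paste(bad, collapse = ", "))
  lg <- character(0)
  if ("side" %in% names(d)) {
    n_off <- sum(d$side != "R")
    if (n_off) lg <- c(lg, sprintf("%d non-right-side rows ignored", n_off))
    d <- d[d$side == "R", , drop = FALSE]
  }
  if ("anomaly" %in% names(d)) {
    anom <- unique(d$specimen_id[isTRUE_vec(d$anomaly)])
    if (length(anom))
      lg <- c(lg, sprintf("%d specimens excluded for dental anomalies",
                          length(anom)))
    d <- d[!d$specimen_id %in% anom, , drop = FALSE]
  }
  measures <- intersect(c("length_mm", "height_mm", "top_cusp_angle_deg",
                          "cusp_count"), names(d))
  complete <- lapply(measures, function(m) {
    ok <- !is.na(d[[m]])
    tab <- table(d$specimen_id[ok], d$tooth[ok])
    ids <- rownames(tab)[rowSums(tab[, intersect(TEETH, colnames(tab)),
                                     drop = FALSE] > 0) == length(TEETH) &
                           ncol(tab) >= 1]
    if (!all(TEETH %in% colnames(tab))) ids <- character(0)
    ids
  })
  names(complete) <- measures
  for (m in measures)
    lg <- c(lg, sprintf("%s: %d of %d specimens complete", m,
                        length(complete[[m]]),
                        length(unique(d$specimen_id))))
  structure(list(data = d, complete = complete, log = lg),
            class = "tooth_table")
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' Summary statistics of a tooth table
#'
#' Population-by-tooth means (length, height, height/length ratio,
#' top-cusp angle) over analysis-ready specimens, per-specimen M1/P4
#' length ratios, and the cusp-count tabulation per population.
#'
#' @param tt a [load_tooth_table()] result.
#' @return list with `by_tooth` (data.frame of group means and n),
#'   `ratios` (per-specimen M1/P4 length ratio with population), and
#'   `cusp_counts` (population x cusp-count table).
#' @export
summarize_teeth <- function(tt) {
  d <- tt$data
  len_ids <- tt$complete$length_mm
  dl <- d[d$specimen_id %in% len_ids, , drop = FALSE]

  grp <- function(sub, value) {
    ag <- aggregate(list(mean = value),
                    by = list(population = sub$population,
                              tooth = sub$tooth), FUN = mean)
    nn <- aggregate(list(n = value),
                    by = list(population = sub$population,
                              tooth = sub$tooth), FUN = length)
    merge(ag, nn)
  }
  by_tooth <- grp(dl, dl$length_mm)
  names(by_tooth)[names(by_tooth) == "mean"] <- "mean_length"
  if ("height_mm" %in% names(d)) {
    dh <- d[d$specimen_id %in% tt$complete$height_mm, , drop = FALSE]
    h <- grp(dh, dh$height_mm)[, 1:3]
    names(h)[3] <- "mean_height"
    r <- grp(dh[!is.na(dh$length_mm), , drop = FALSE],
             with(dh[!is.na(dh$length_mm), ], height_mm / length_mm))[, 1:3]
    names(r)[3] <- "mean_height_length"
    by_tooth <- merge(merge(by_tooth, h, all = TRUE), r, all = TRUE)
  }
  if ("top_cusp_angle_deg" %in% names(d)) {
    da <- d[d$specimen_id %in% tt$complete$top_cusp_angle_deg, ,
            drop = FALSE]
    a <- grp(da, da$top_cusp_angle_deg)[, 1:3]
    names(a)[3] <- "mean_angle"
    by_tooth <- merge(by_tooth, a, all = TRUE)
  }

  m1 <- dl[dl$tooth == "M1", c("specimen_id", "population", "length_mm")]
  p4 <- dl[dl$tooth == "P4", c("specimen_id", "length_mm")]
  ratios <- merge(m1, p4, by = "specimen_id",
                  suffixes = c("_M1", "_P4"))
  ratios$ratio <- ratios$length_mm_M1 / ratios$length_mm_P4
  ratios <- ratios[, c("specimen_id", "population", "ratio")]

  cusp_counts <- NULL
  if ("cusp_count" %in% names(d)) {
    dc <- d[d$specimen_id %in% tt$complete$cusp_count, , drop = FALSE]
    cusp_counts <- table(population = dc$population,
                         cusps = factor(dc$cusp_count, levels = 3:5))
  }
  list(by_tooth = by_tooth, ratios = ratios, cusp_counts = cusp_counts)
}

#' One-tailed permutation test for a difference in group means
#'
#' The statistic is `mean(b) - mean(a)`. When the number of label
#' arrangements `choose(nA + nB, nA)` is at most `exact_limit`, the null
#' distribution is enumerated exactly and
#' `p = #\{stat_perm extreme\} / total` with ties counted as extreme;
#' otherwise a seeded Monte Carlo estimate with the +1 correction
#' `p = (1 + #extreme) / (1 + B)` is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param B Monte Carlo permutation count (default 10000).
#' @param alternative `"greater"` (mean of `b` exceeds mean of `a`) or
#'   `"less"`.
#' @param seed integer seed (Monte Carlo branch only).
#' @param exact_limit arrangement count below which enumeration is exact.
#' @return A `perm_result`: list with `observed`, `p`, `exact`,
#'   `n_perm`, `alternative`, `seed`.
#' @export
permutation_test <- function(a, b, B = 10000L,
                             alternative = c("greater", "less"),
                             seed = 1L, exact_limit = 20000) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  obs <- mean(b) - mean(a)
  extreme <- function(stat) {
    if (alternative == "greater") stat >= obs - 1e-12 * max(1, abs(obs))
    else stat <= obs + 1e-12 * max(1, abs(obs))
  }
  total <- choose(na + nb, na)
  if (total <= exact_limit) {
    idx <- combn(na + nb, na)
    stats <- apply(idx, 2L, function(ia)
      mean(pool[-ia]) - mean(pool[ia]))
    p <- sum(extreme(stats)) / total
    return(structure(list(observed = obs, p = p, exact = TRUE,
                          n_perm = total, alternative = alternative,
                          seed = NA_integer_), class = "perm_result"))
  }
  set.seed(seed)
  stats <- replicate(B, {
    ia <- sample.int(na + nb, na)
    mean(pool[-ia]) - mean(pool[ia])
  })
  p <- (1 + sum(extreme(stats))) / (1 + B)
  structure(list(observed = obs, p = p, exact = FALSE, n_perm = B,
                 alternative = alternative, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test (%s, %s): observed %.4g, p = %.4g (%s)\n",
              x$alternative,
              if (x$exact) "exact" else paste0(x$n_perm, " permutations"),
              x$observed, x$p,
              if (x$exact) "enumeration" else paste("seed", x$seed)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' With `smaller_is_positive = TRUE` scores are negated before analysis
#' so that larger oriented scores always indicate the positive class.
#' The AUC is the Mann-Whitney concordance probability with ties counted
#' one half. The curve enumerates all distinct oriented scores as
#' thresholds (predict positive iff oriented score >= threshold), plus
#' the two trivial endpoints.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) vector, `TRUE` = positive class.
#' @param smaller_is_positive do smaller raw scores indicate positives
#'   (tooth lengths, top-cusp angles)?
#' @return A `roc_result`: list with `auc`, `curve` (data.frame
#'   `threshold` on the original score scale, `tpr`, `fpr`),
#'   `smaller_is_positive`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, smaller_is_positive = FALSE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  s <- if (smaller_is_positive) -scores else scores
  np <- sum(labels); nn <- sum(!labels)
  r <- rank(s)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s[labels] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!labels] >= t) / nn, numeric(1))
  curve <- data.frame(
    threshold_oriented = c(Inf, thr, -Inf),
    threshold = if (smaller_is_positive) -c(Inf, thr, -Inf)
                else c(Inf, thr, -Inf),
    tpr = c(0, tpr, 1), fpr = c(0, fpr, 1))
  structure(list(auc = auc, curve = curve,
                 smaller_is_positive = smaller_is_positive,
                 n_pos = np, n_neg = nn, oriented_scores = s,
                 labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives%s)\n", x$auc,
              x$n_pos, x$n_neg,
              if (x$smaller_is_positive) ", smaller-is-positive" else ""))
  invisible(x)
}

#' Youden-J diagnostic cutoff from a ROC curve
#'
#' Chooses the threshold maximizing `J = TPR - FPR` (ties broken toward
#' the threshold with higher TPR) and reports the midpoint between that
#' oriented threshold and the next lower distinct observed score, mapped
#' back to the original score scale. With `smaller_is_positive` scores,
#' classification is then "positive iff score <= cutoff".
#'
#' @param roc a [roc_curve()] result.
#' @return list with `cutoff` (original scale), `J`, `tpr`, `fpr`,
#'   `rule = "youden"`.
#' @export
diagnostic_cutoff <- function(roc) {
  cv <- roc$curve
  finite <- is.finite(cv$threshold_oriented)
  cc <- cv[finite, , drop = FALSE]
  J <- cc$tpr - cc$fpr
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(cc$tpr[best])]
  t_or <- cc$threshold_oriented[best]
  lower <- sort(unique(roc$oriented_scores))
  below <- lower[lower < t_or]
  mid_or <- if (length(below)) (t_or + max(below)) / 2 else t_or
  cutoff <- if (roc$smaller_is_positive) -mid_or else mid_or
  list(cutoff = cutoff, J = J[best], tpr = cc$tpr[best],
       fpr = cc$fpr[best], rule = "youden")
}

#' Classify a tooth-length ratio against a diagnostic cutoff
#'
#' Boundary inclusive: a ratio exactly at the cutoff is positive.
#'
#' @param ratio positive M1/P4 length ratio(s).
#' @param cutoff diagnostic boundary (default 0.88).
#' @return character vector, `"positive"` or `"other"`.
#' @export
classify_ratio <- function(ratio, cutoff = 0.88) {
  if (any(ratio <= 0)) stop("ratios must be positive")
  ifelse(ratio <= cutoff, "positive", "other")
}

#' Crown outline profile
#'
#' An ordered 2-D polyline over a tooth crown from one end of the crown
#' base to the other.
#'
#' @param x,y numeric coordinates of the ordered outline points (>= 3);
#'   the first and last points are the crown-base endpoints.
#' @param apices optional indices of cusp apex points; by default apices
#'   are the strict local maxima of height above the base chord.
#' @return A `crown_profile`.
#' @export
crown_profile <- function(x, y, apices = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(x = as.numeric(x), y = as.numeric(y), apices = apices),
            class = "crown_profile")
}

#' Crown relief, top-cusp angle and cusp index
#'
#' * relief: outline arc length between base endpoints divided by the
#'   base chord length (1.0 for a flat crown);
#' * top-cusp angle: the angle at the highest apex subtended by the
#'   apices of its two neighbouring cusps (requires >= 3 apices, else
#'   `NA`);
#' * cusp index: relief divided by the relative crown height
#'   (max perpendicular height / base chord length) -- a documented
#'   placeholder standardization.
#'
#' All metrics are invariant to rigid motion and uniform scaling.
#'
#' @param profile a [crown_profile()] (or data.frame with `x`, `y`).
#' @return list with `relief`, `top_cusp_angle`, `cusp_index`,
#'   `max_height`, `base_length`, `n_apices`.
#' @export
crown_metrics <- function(profile) {
  if (is.data.frame(profile))
    profile <- crown_profile(profile$x, profile$y)
  x <- profile$x; y <- profile$y
  n <- length(x)
  b0 <- c(x[1], y[1]); b1 <- c(x[n], y[n])
  chord <- sqrt(sum((b1 - b0)^2))
  if (chord <= 0) stop("degenerate crown base")
  ## base-aligned frame: u along chord, v perpendicular height
  e1 <- (b1 - b0) / chord
  e2 <- c(-e1[2], e1[1])
  u <- (x - b0[1]) * e1[1] + (y - b0[2]) * e1[2]
  v <- (x - b0[1]) * e2[1] + (y - b0[2]) * e2[2]
  if (mean(v) < 0) v <- -v       # crown on the positive side
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  relief <- arc / chord

  ap <- profile$apices
  if (is.null(ap)) {
    interior <- 2:(n - 1)
    ap <- interior[v[interior] > v[interior - 1] &
                     v[interior] > v[interior + 1]]
  }
  angle <- NA_real_
  if (length(ap) >= 3) {
    ap <- ap[order(u[ap])]
    k <- which.max(v[ap])
    if (k > 1 && k < length(ap)) {
      main <- c(u[ap[k]], v[ap[k]])
      left <- c(u[ap[k - 1]], v[ap[k - 1]])
      right <- c(u[ap[k + 1]], v[ap[k + 1]])
      v1 <- left - main; v2 <- right - main
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
  }
  hmax <- max(v)
  list(relief = relief, top_cusp_angle = angle,
       cusp_index = if (hmax > 0) relief / (hmax / chord) else NA_real_,
       max_height = hmax, base_length = chord, n_apices = length(ap))
}

## segment intersection helper (proper crossings only)
segs_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Relative tongue-width profile in ten-percent bins
#'
#' Given a simple tongue outline polygon with identified tip and
#' posterior-body-end landmarks (or 10 pre-binned widths), measures the
#' width perpendicular to the tip-to-posterior axis at the stations
#' 10%, 20%, ..., 100% of the axis length, normalized by the maximum
#' measured width. The `broad_tip` flag is set when the relative width
#' at the 20% station is at least 0.70 (the suction-feeder-like shape).
#'
#' @param outline data.frame with columns `x`, `y`: vertices of a
#'   simple (non-self-intersecting) polygon, or `NULL` when `widths` is
#'   given.
#' @param tip,posterior length-2 numeric landmarks (required with an
#'   outline).
#' @param widths optional numeric vector of 10 pre-binned widths.
#' @param specimen_id,population optional labels carried through.
#' @return A `tongue_profile`: list with `rel_widths` (length 10,
#'   max = 1), `stations` (0.1..1.0), `broad_tip`, labels.
#' @export
tongue_profile <- function(outline = NULL, tip = NULL, posterior = NULL,
                           widths = NULL, specimen_id = NA,
                           population = NA) {
  if (is.null(widths)) {
    stopifnot(!is.null(outline), !is.null(tip), !is.null(posterior))
    px <- outline$x; py <- outline$y
    n <- length(px)
    if (n < 3) stop("outline needs at least 3 vertices")
    ## self-intersection check over non-adjacent edge pairs
    P <- cbind(c(px, px[1]), c(py, py[1]))
    for (i in seq_len(n - 2)) {
      jmax <- if (i == 1) n - 1 else n
      for (j in (i + 2):jmax) {
        if (segs_cross(P[i, ], P[i + 1, ], P[j, ], P[j + 1, ]))
          stop("self-intersecting outline")
      }
    }
    axis <- c(posterior[1] - tip[1], posterior[2] - tip[2])
    L <- sqrt(sum(axis^2))
    if (L <= 0) stop("tip and posterior landmarks coincide")
    e1 <- axis / L
    e2 <- c(-e1[2], e1[1])
    qx <- (px - tip[1]) * e1[1] + (py - tip[2]) * e1[2]
    qy <- (px - tip[1]) * e2[1] + (py - tip[2]) * e2[2]
    stations <- seq(0.1, 1.0, by = 0.1)
    widths <- vapply(stations, function(s) {
      x0 <- min(s, 1 - 1e-9) * L
      ys <- numeric(0)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        x1 <- qx[i]; x2 <- qx[j]
        if ((x1 - x0) * (x2 - x0) <= 0 && x1 != x2) {
          t <- (x0 - x1) / (x2 - x1)
          ys <- c(ys, qy[i] + t * (qy[j] - qy[i]))
        }
      }
      if (length(ys) < 2) 0 else max(ys) - min(ys)
    }, numeric(1))
  } else {
    if (length(widths) != 10) stop("exactly 10 width bins required")
  }
  if (max(widths) <= 0) stop("degenerate outline: zero widths")
  rel <- widths / max(widths)
  structure(list(rel_widths = rel, stations = seq(0.1, 1.0, by = 0.1),
                 broad_tip = rel[2] >= 0.70,
                 specimen_id = specimen_id, population = population),
            class = "tongue_profile")
}
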