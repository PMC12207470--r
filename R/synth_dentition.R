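#' Per-population dentition generator presets
#'
#' Stand-in parameter sets for five ringed seal style populations. The
#' focal population (`saimaa`) follows the qualitative pattern of the
#' real material: a distinctly short M1 (hence a low M1/P4 length
#' ratio), tall anterior postcanines (high height/length), small
#' top-cusp angles, and a zero probability of five-cusped teeth, while
#' P4 length overlaps the other populations. All values are in mm and
#' degrees and are nominal, not measurements.
#'
#' @return named list of per-population parameter lists with elements
#'   `length`, `height`, `angle` (named by tooth P2, P3, P4, M1),
#'   `sd_length`, `sd_height`, `sd_angle`, `size_sd` (SD of the shared
#'   per-specimen size factor, which cancels in within-specimen ratios),
#'   and `cusp_probs` (probabilities of 3/4/5 cusps).
#' @export
dentition_presets <- function() {
  base <- function(len, hei, ang, cusp)
    list(length = len, height = hei, angle = ang,
         sd_length = 0.30, sd_height = 0.35, sd_angle = 6,
         size_sd = 0.06, cusp_probs = cusp)
  tooth <- function(p2, p3, p4, m1) c(P2 = p2, P3 = p3, P4 = p4, M1 = m1)
  other_cusps <- c(`3` = 0.15, `4` = 0.75, `5` = 0.10)
  list(
    saimaa  = base(tooth(7.4, 7.7, 7.8, 6.3),
                   tooth(6.5, 6.6, 6.4, 5.0),
                   tooth(55, 55, 56, 58),
                   c(`3` = 0.25, `4` = 0.75, `5` = 0)),
    baltic  = base(tooth(7.9, 8.2, 8.1, 7.7),
                   tooth(5.9, 6.0, 5.9, 5.4),
                   tooth(70, 70, 71, 72), other_cusps),
    ladoga  = base(tooth(7.8, 8.1, 8.0, 7.6),
                   tooth(5.8, 5.9, 5.8, 5.3),
                   tooth(69, 70, 70, 71), other_cusps),
    arctic  = base(tooth(7.8, 8.1, 8.0, 7.6),
                   tooth(5.8, 5.9, 5.8, 5.3),
                   tooth(70, 71, 71, 72), other_cusps),
    okhotsk = base(tooth(7.0, 7.3, 7.2, 6.9),
                   tooth(5.2, 5.3, 5.2, 4.8),
                   tooth(68, 69, 69, 70), other_cusps))
}

## Gaussian truncated at zero by redrawing (means here are many SDs
## above zero, so redraws are essentially never needed).
rnorm_pos <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep_len(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate a specimen-level tooth table
#'
#' Draws, per specimen, a shared size factor `N(1, size_sd)` applied to
#' lengths and heights (so within-specimen ratios are less noisy than
#' single measures, as in real material), then per tooth adds
#' independent Gaussian noise, truncating all measures at zero. Cusp
#' counts are drawn from the per-population probability vector.
#'
#' @param pop_params named list of per-population parameter lists (see
#'   [dentition_presets()]).
#' @param n_per_pop specimens per population (scalar or named).
#' @param seed integer seed.
#' @return list with `teeth` (data.frame in the tooth-table layout:
#'   `specimen_id`, `population`, `sex`, `tooth`, `length_mm`,
#'   `height_mm`, `top_cusp_angle_deg`, `cusp_count`) and `truth`
#'   (the parameters and per-specimen size factors).
#' @export
simulate_dentition <- function(pop_params = dentition_presets(),
                               n_per_pop = 50L, seed = 1L) {
  for (pl in names(pop_params)) {
    pp <- pop_params[[pl]]
    if (any(c(pp$sd_length, pp$sd_height, pp$sd_angle, pp$size_sd) < 0))
      stop("SDs must be non-negative")
    if (abs(sum(pp$cusp_probs) - 1) > 1e-9 || any(pp$cusp_probs < 0))
      stop("cusp probabilities must be non-negative and sum to 1")
  }
  set.seed(seed)
  if (is.null(names(n_per_pop)))
    n_per_pop <- setNames(rep(n_per_pop[1], length(pop_params)),
                          names(pop_params))
  rows <- list()
  sizes <- list()
  for (pl in names(pop_params)) {
    pp <- pop_params[[pl]]
    for (i in seq_len(n_per_pop[[pl]])) {
      sid <- sprintf("%s_%03d", pl, i)
      sf <- if (pp$size_sd > 0) rnorm_pos(1, 1, pp$size_sd) else 1
      sizes[[sid]] <- sf
      sex <- sample(c("F", "M"), 1)
      for (tth in TEETH) {
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sid, population = pl, sex = sex, tooth = tth,
          length_mm = rnorm_pos(1, sf * pp$length[[tth]], pp$sd_length),
          height_mm = rnorm_pos(1, sf * pp$height[[tth]], pp$sd_height),
          top_cusp_angle_deg = rnorm_pos(1, pp$angle[[tth]],
                                         pp$sd_angle),
          cusp_count = as.integer(sample(names(pp$cusp_probs), 1,
                                         prob = pp$cusp_probs)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(teeth = do.call(rbind, rows),
       truth = list(pop_params = pop_params,
                    size_factor = unlist(sizes), seed = seed))
}

#' Build a synthetic crown outline of triangular cusps
#'
#' Adjoined isoceles-triangle cusps on a flat base running from `(0, 0)`
#' to `(L, 0)` with `L` the sum of base widths. The exact perimeter is
#' `sum(2 * sqrt((w/2)^2 + h^2))`, so the cusp relief has a closed form
#' recorded in the result.
#'
#' @param cusp_heights non-negative cusp heights (one per cusp).
#' @param cusp_base_widths positive base widths, same length.
#' @return A [crown_profile()] with attribute `relief_truth`.
#' @export
simulate_crown_profile <- function(cusp_heights, cusp_base_widths) {
  stopifnot(length(cusp_heights) == length(cusp_base_widths))
  if (!length(cusp_heights)) stop("at least one cusp required")
  if (any(cusp_base_widths <= 0)) stop("base widths must be positive")
  if (any(cusp_heights < 0)) stop("cusp heights must be non-negative")
  x <- 0; y <- 0; cx <- 0
  apices <- integer(0)
  for (i in seq_along(cusp_heights)) {
    w <- cusp_base_widths[i]; h <- cusp_heights[i]
    x <- c(x, cx + w / 2, cx + w)
    y <- c(y, h, 0)
    apices <- c(apices, length(x) - 1L)
    cx <- cx + w
  }
  pr <- crown_profile(x, y, apices = apices)
  attr(pr, "relief_truth") <-
    sum(2 * sqrt((cusp_base_widths / 2)^2 + cusp_heights^2)) /
    sum(cusp_base_widths)
  pr
}

#' Build a synthetic tongue outline polygon
#'
#' Symmetric polygon around the tip-to-posterior axis whose half-width
#' follows `w(s) = s^shape_exp` of the maximum half-width: a small
#' exponent gives the blunt, broad-tipped outline of a suction feeder
#' (width at the 20% station already above 70% of the maximum), an
#' exponent of 1 gives an acute triangular outline.
#'
#' @param shape `"broad"` (exponent 0.15) or `"acute"` (exponent 1), or
#'   a numeric exponent.
#' @param length_mm axis length.
#' @param max_width_mm maximum total width.
#' @param n_points vertices per side.
#' @return list with `outline` (data.frame `x_mm`, `y_mm`), `tip`,
#'   `posterior` landmarks.
#' @export
simulate_tongue_outline <- function(shape = c("broad", "acute"),
                                    length_mm = 80, max_width_mm = 40,
                                    n_points = 60) {
  expo <- if (is.numeric(shape)) shape
          else switch(match.arg(shape), broad = 0.15, acute = 1)
  s <- seq(0, 1, length.out = n_points)[-1]   # tip handled separately
  hw <- (s^expo) * max_width_mm / 2
  outline <- data.frame(
    x_mm = c(0, s * length_mm, rev(s) * length_mm),
    y_mm = c(0, hw, -rev(hw)))
  list(outline = outline, tip = c(0, 0), posterior = c(length_mm, 0))
}
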