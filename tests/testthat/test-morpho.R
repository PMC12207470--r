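tooth_rows <- function(id, pop, lens, heights = lens * 0.8,
                       angles = rep(70, 4), cusps = rep(4L, 4),
                       sex = "F") {
  data.frame(specimen_id = id, population = pop, sex = sex,
             tooth = c("P2", "P3", "P4", "M1"), length_mm = lens,
             height_mm = heights, top_cusp_angle_deg = angles,
             cusp_count = cusps, stringsAsFactors = FALSE)
}

test_that("completeness rule keeps only fully measured specimens", {
  d <- rbind(tooth_rows("s1", "saimaa", c(7, 8, 8, 6)),
             tooth_rows("s2", "saimaa", c(7, NA, 8, 6), heights = c(5, 6, 6, 5)),
             tooth_rows("s3", "baltic", c(8, 8, 8, 8)),
             tooth_rows("s4", "baltic", c(8, 8, 8, 7.5)),
             tooth_rows("s5", "baltic", c(8, 8, 8, 7.6)))
  tt <- load_tooth_table(d)
  expect_setequal(tt$complete$length_mm, c("s1", "s3", "s4", "s5"))
  ## s2 still complete for heights
  expect_true("s2" %in% tt$complete$height_mm)
  ## anomaly exclusion
  d$anomaly <- d$specimen_id == "s3"
  tt2 <- load_tooth_table(d)
  expect_false("s3" %in% tt2$complete$length_mm)
  expect_match(paste(tt2$log, collapse = " "), "anomalies")
  d$tooth[1] <- "M2"
  expect_error(load_tooth_table(d), "unknown tooth")
})

test_that("summaries compute M1/P4 ratios and cusp tabulations", {
  d <- rbind(tooth_rows("s1", "a", c(7, 8, 4, 3)),
             tooth_rows("s2", "a", c(7, 8, 4, 4)))
  s <- summarize_teeth(load_tooth_table(d))
  expect_equal(sort(s$ratios$ratio), c(0.75, 1.0))
  expect_equal(mean(s$ratios$ratio), 0.875)
  bt <- s$by_tooth
  expect_equal(bt$mean_length[bt$tooth == "M1"], 3.5)
  expect_equal(bt$n[bt$tooth == "M1"], 2)
  ## focal synthetic preset tabulates zero five-cusp teeth
  den <- simulate_dentition(n_per_pop = 40, seed = 2)
  cc <- summarize_teeth(load_tooth_table(den$teeth))$cusp_counts
  expect_equal(unname(cc["saimaa", "5"]), 0L)
  expect_gt(sum(cc[rownames(cc) != "saimaa", "5"]), 0L)
})

test_that("permutation test enumerates exactly and is symmetric", {
  r <- permutation_test(c(1, 2), c(3, 4), alternative = "greater")
  expect_true(r$exact)
  expect_equal(r$p, 1 / 6)
  expect_equal(r$observed, 2)
  ## identical constant groups
  r0 <- permutation_test(rep(1, 3), rep(1, 3))
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1.0)
  ## swap groups + flip alternative: identical p
  set.seed(2)
  a <- rnorm(5); b <- rnorm(6) + 0.5
  expect_equal(permutation_test(a, b, alternative = "greater")$p,
               permutation_test(b, a, alternative = "less")$p)
  expect_error(permutation_test(a, b, alternative = "two.sided"))
  expect_error(permutation_test(numeric(0), b), "non-empty")
})

test_that("exact and Monte Carlo permutation p agree within 3 MC SDs", {
  set.seed(8)
  for (r in 1:5) {
    a <- rnorm(6); b <- rnorm(6) + 1
    pe <- permutation_test(a, b, alternative = "greater")$p
    pm <- permutation_test(a, b, B = 4000, alternative = "greater",
                           seed = r, exact_limit = 1)$p
    expect_lt(abs(pe - pm), 3 * sqrt(pe * (1 - pe) / 4000) + 1e-3)
  }
})

test_that("AUC equals pairwise concordance and handles orientation", {
  r <- roc_curve(c(0.80, 0.86, 0.84, 0.95),
                 c(TRUE, TRUE, FALSE, FALSE),
                 smaller_is_positive = TRUE)
  expect_equal(r$auc, 0.75)
  ## perfect separation
  expect_equal(roc_curve(c(1, 2, 9, 10), c(F, F, T, T))$auc, 1.0)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  ## brute-force oracle on random inputs with ties, n <= 30
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, TRUE)
    lb <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(lb) || all(lb)) next
    sip <- sample(c(TRUE, FALSE), 1)
    expect_equal(roc_curve(sc, lb, sip)$auc, oracle_auc(sc, lb, sip))
  }
  ## TPR/FPR non-decreasing along the curve
  cv <- roc_curve(rnorm(50), rep(c(TRUE, FALSE), 25))$curve
  expect_true(all(diff(cv$tpr) >= 0))
  expect_true(all(diff(cv$fpr) >= 0))
})

test_that("null AUC concentrates around 0.5", {
  set.seed(3)
  aucs <- vapply(1:50, function(i) {
    roc_curve(rnorm(200), sample(rep(c(TRUE, FALSE), 100)))$auc
  }, numeric(1))
  expect_gte(sum(abs(aucs - 0.5) <= 0.12), 47)
})

test_that("Youden cutoff reports the midpoint between classes", {
  r <- roc_curve(c(0.70, 0.80, 0.90, 1.00), c(TRUE, TRUE, FALSE, FALSE),
                 smaller_is_positive = TRUE)
  cut <- diagnostic_cutoff(r)
  expect_equal(cut$cutoff, 0.85)
  expect_equal(cut$J, 1)
  expect_equal(cut$rule, "youden")
  ## degenerate flat curve: J = 0 everywhere, deterministic result
  rflat <- roc_curve(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE))
  cflat <- diagnostic_cutoff(rflat)
  expect_equal(cflat$J, 0)
})

test_that("ratio classification is boundary-inclusive at 0.88", {
  expect_equal(classify_ratio(0.83), "positive")   # lectotype, both sides
  expect_equal(classify_ratio(0.88), "positive")   # inclusive boundary
  expect_equal(classify_ratio(0.92), "other")
  expect_error(classify_ratio(-1), "positive")
})

test_that("crown metrics match closed-form geometry", {
  flat <- crown_profile(c(0, 1, 2), c(0, 0, 0))
  expect_equal(crown_metrics(flat)$relief, 1.0)
  one <- simulate_crown_profile(1, 2)
  expect_equal(crown_metrics(one)$relief, sqrt(2), tolerance = 1e-12)
  ## apices at (-0.5, 0.5), (0, 1), (0.5, 0.5): 90 degrees at the top
  pr <- crown_profile(c(-1, -0.5, -0.25, 0, 0.25, 0.5, 1),
                      c(0, 0.5, 0.3, 1, 0.3, 0.5, 0))
  cm <- crown_metrics(pr)
  expect_equal(cm$top_cusp_angle, 90)
  ## fewer than 3 apices: angle absent
  expect_true(is.na(crown_metrics(one)$top_cusp_angle))
  expect_error(crown_metrics(crown_profile(c(0, 0, 0), c(0, 1, 0))),
               "degenerate")
})

test_that("relief is invariant to rigid motion and uniform scaling", {
  pr <- simulate_crown_profile(c(0.4, 0.6, 0.5), c(0.5, 0.6, 0.5))
  base <- crown_metrics(pr)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (s in c(0.5, 3)) {
    xy <- s * cbind(pr$x, pr$y) %*% t(R)
    tf <- crown_profile(xy[, 1] + 5, xy[, 2] - 2, apices = pr$apices)
    m <- crown_metrics(tf)
    expect_equal(m$relief, base$relief, tolerance = 1e-10)
    expect_equal(m$top_cusp_angle, base$top_cusp_angle,
                 tolerance = 1e-8)
    expect_equal(m$cusp_index, base$cusp_index, tolerance = 1e-8)
  }
})

test_that("top-cusp angle decreases as lateral apices drop", {
  hs <- seq(0.9, 0.1, by = -0.2)
  angles <- vapply(hs, function(h) {
    pr <- simulate_crown_profile(c(h, 1, h), c(1, 1, 1))
    crown_metrics(pr)$top_cusp_angle
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
})

test_that("tongue profiles bin widths and flag broad tips", {
  ## rectangle: all widths equal
  rect <- data.frame(x = c(0, 10, 10, 0), y = c(-2, -2, 2, 2))
  tp <- tongue_profile(rect, tip = c(0, 0), posterior = c(10, 0))
  expect_equal(tp$rel_widths, rep(1, 10))
  expect_true(tp$broad_tip)
  ## triangle with apex at the tip: widths grow linearly
  tri <- data.frame(x = c(0, 10, 10), y = c(0, -3, 3))
  tp2 <- tongue_profile(tri, tip = c(0, 0), posterior = c(10, 0))
  expect_equal(tp2$rel_widths, seq(0.1, 1, by = 0.1), tolerance = 1e-6)
  expect_false(tp2$broad_tip)
  ## pre-binned widths: 0.75 at the 20% station flags broad
  w <- c(0.5, 0.75, 0.85, 0.9, 0.95, 1, 1, 1, 1, 0.9)
  tp3 <- tongue_profile(widths = w)
  expect_true(tp3$broad_tip)
  expect_equal(max(tp3$rel_widths), 1.0)
  expect_error(tongue_profile(widths = w[1:5]), "10 width bins")
  ## self-intersecting bow-tie outline
  bow <- data.frame(x = c(0, 10, 0, 10), y = c(0, 2, 2, 0))
  expect_error(tongue_profile(bow, c(0, 0), c(10, 1)),
               "self-intersecting")
  ## generator shapes land on the intended sides of the flag
  g1 <- simulate_tongue_outline("broad")
  p1 <- tongue_profile(setNames(g1$outline, c("x", "y")), g1$tip,
                       g1$posterior)
  expect_true(p1$broad_tip)
  g2 <- simulate_tongue_outline("acute")
  p2 <- tongue_profile(setNames(g2$outline, c("x", "y")), g2$tip,
                       g2$posterior)
  expect_false(p2$broad_tip)
})
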