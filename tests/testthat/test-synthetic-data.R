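test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(500, 3, missing_rate = 0.05, seed = 99)
  s1 <- simulate_genotypes(seal_model(), cfg)
  s2 <- simulate_genotypes(seal_model(), cfg)
  expect_identical(s1$variants$dosage, s2$variants$dosage)
  expect_identical(s1$variants$pos, s2$variants$pos)
  expect_identical(s1$truth$freq, s2$truth$freq)
  d1 <- simulate_dentition(n_per_pop = 5, seed = 4)
  d2 <- simulate_dentition(n_per_pop = 5, seed = 4)
  expect_identical(d1$teeth, d2$teeth)
})

test_that("Balding-Nichols branch transitions have the analytic moments", {
  set.seed(1)
  for (F in c(0.05, 0.3, 0.6)) {
    p <- 0.3
    q <- phocidist:::bn_draw(rep(p, 40000), F)
    expect_equal(mean(q), p, tolerance = 0.01)
    expect_equal(var(q), F * p * (1 - p), tolerance = 0.05)
  }
  expect_identical(phocidist:::bn_draw(0.4, 0), 0.4)
})

test_that("zero drift gives statistically equal private proportions", {
  br <- data.frame(parent = "ROOT", child = c("out", "A", "B", "C"),
                   F = 0)
  m <- pop_model(br, outgroup = "out")
  sim <- simulate_genotypes(m, sim_config(4000, 4, seed = 13))
  vt <- polarize(sim$variants, grep("^out", colnames(sim$variants$dosage),
                                    value = TRUE))
  ## every ingroup population has the same expected frequency: truth
  expect_equal(sim$truth$freq[, "A"], sim$truth$freq[, "B"])
  pp <- private_proportions(vt, n_range = 2, replicates = 20, seed = 5)
  spread <- max(pp$mean) - min(pp$mean)
  expect_lt(spread, 3 * max(pp$sd) / sqrt(20) * 3 + 0.01)
})

test_that("sample frequencies converge to truth at n = 200", {
  br <- data.frame(parent = "ROOT", child = c("out", "A", "B"),
                   F = c(0, 0.2, 0.05))
  m <- pop_model(br, outgroup = "out")
  sim <- simulate_genotypes(m, sim_config(2000, c(out = 2, A = 200,
                                                  B = 200), seed = 8))
  vt <- polarize(sim$variants, c("out_1", "out_2"))
  for (pl in c("A", "B")) {
    cols <- names(vt$populations)[vt$populations == pl]
    n <- length(cols)
    obs <- rowMeans(vt$dosage[, cols]) / 2
    tr <- sim$truth$freq[, pl]
    bound <- 4 * sqrt(pmax(tr * (1 - tr), 1e-6) / (2 * n))
    expect_gte(mean(abs(obs - tr) < bound), 0.95)
  }
})

test_that("outgroup is homozygous ancestral and never missing", {
  sim <- simulate_genotypes(seal_model(),
                            sim_config(300, 3, missing_rate = 0.3,
                                       seed = 2))
  vt <- sim$variants
  og <- grep("^spotted", colnames(vt$dosage), value = TRUE)
  expect_false(anyNA(vt$dosage[, og]))
  ## outgroup ALT dosage is 0 where REF is ancestral, 2 otherwise
  expect_equal(unname(vt$dosage[, og[1]]),
               ifelse(sim$truth$ref_is_anc, 0L, 2L))
  ## ingroup missingness near the configured rate
  ing <- setdiff(colnames(vt$dosage), og)
  expect_equal(mean(is.na(vt$dosage[, ing])), 0.3, tolerance = 0.05)
})

test_that("genotype generator validates inputs", {
  expect_error(sim_config(0, 5), "n_sites")
  expect_error(sim_config(10, 0), "n_per_pop")
  br <- data.frame(parent = "ROOT", child = c("o", "A"), F = c(0, 0.2))
  expect_error(pop_model(br, outgroup = "x"), "outgroup")
  expect_error(pop_model(data.frame(parent = "ROOT", child = c("o", "A"),
                                    F = c(0, 1.0)), outgroup = "o"),
               "F must lie")
  expect_error(
    pop_model(br, outgroup = "o",
              pulses = list(list(from = "A", to = "o", intensity = 0.5,
                                 t0 = 0, t1 = 5))),
    "outside tree depth")
})

test_that("migration pulses mix tip frequencies linearly", {
  br <- data.frame(parent = "ROOT", child = c("out", "A", "B"),
                   F = c(0, 0.3, 0.3))
  m0 <- pop_model(br, outgroup = "out")
  m1 <- pop_model(br, outgroup = "out",
                  pulses = list(list(from = "A", to = "B",
                                     intensity = 1, t0 = 0.5, t1 = 0.6)))
  cfg <- sim_config(500, 2, seed = 3)
  s0 <- simulate_genotypes(m0, cfg)
  s1 <- simulate_genotypes(m1, cfg)
  ## intensity 1 replaces the recipient frequency entirely
  expect_equal(s1$truth$freq[, "B"], s1$truth$freq[, "A"])
  expect_equal(s0$truth$freq[, "A"], s1$truth$freq[, "A"])
})

test_that("trajectory generator truth agrees with the integration oracle", {
  seg <- data.frame(duration = c(1000, 4000, 50000),
                    m = c(0, 2e-4, 5e-5))
  out <- simulate_migration_trajectory(seg, pairs = 2, seed = 6)
  tr <- out$truth
  expect_true(all(tr$reached))
  expect_equal(tr$time_gen_closed, tr$time_gen_grid, tolerance = 1e-6)
  ## single segment m = 1e-4: M50 at ln(2)/(2e-4)
  one <- simulate_migration_trajectory(
    data.frame(duration = 1e5, m = 1e-4), thresholds = 0.5)
  expect_equal(one$truth$time_gen_closed, log(2) / 2e-4,
               tolerance = 1e-9)
  ## m = 0 throughout: nothing reached
  zero <- simulate_migration_trajectory(data.frame(duration = 1e4, m = 0))
  expect_false(any(zero$truth$reached))
  ## pulse of migration: M constant after the pulse ends
  pulse <- migration_trajectory(c(0, 1000, 2000), c(1000, 2000, 50000),
                                c(0, 3e-4, 0))
  Mf <- cumulative_migration(pulse)$M_fun
  expect_equal(Mf(2000), Mf(40000))
  expect_gt(Mf(2000), 0)
  expect_error(
    simulate_migration_trajectory(data.frame(duration = 10, m = -1)),
    "negative")
})

test_that("dentition generator honours presets and degenerate SDs", {
  pp <- dentition_presets()
  ## SD = 0 everywhere: records equal their population means
  p0 <- lapply(pp, function(x) {
    x$sd_length <- x$sd_height <- x$sd_angle <- x$size_sd <- 0
    x$cusp_probs <- c(`3` = 0, `4` = 1, `5` = 0)
    x
  })
  d0 <- simulate_dentition(p0, n_per_pop = 2, seed = 1)
  m1 <- d0$teeth[d0$teeth$population == "saimaa" &
                   d0$teeth$tooth == "M1", ]
  expect_true(all(m1$length_mm == pp$saimaa$length[["M1"]]))
  expect_true(all(d0$teeth$cusp_count == 4L))
  ## focal preset: no five-cusped teeth; sample mean close to truth
  den <- simulate_dentition(n_per_pop = 50, seed = 10)
  sai <- den$teeth[den$teeth$population == "saimaa", ]
  expect_equal(sum(sai$cusp_count == 5L), 0L)
  m1len <- sai$length_mm[sai$tooth == "M1"]
  se <- sqrt(pp$saimaa$sd_length^2 +
               (pp$saimaa$size_sd * pp$saimaa$length[["M1"]])^2) /
    sqrt(length(m1len))
  expect_lt(abs(mean(m1len) - pp$saimaa$length[["M1"]]), 3 * se)
  ## invalid probability vector
  bad <- pp
  bad$saimaa$cusp_probs <- c(`3` = 0.5, `4` = 0.2, `5` = 0.2)
  expect_error(simulate_dentition(bad, 2), "sum to 1")
})

test_that("crown profile generator matches the closed-form relief", {
  flat <- simulate_crown_profile(0, 2)
  expect_equal(crown_metrics(flat)$relief, 1.0)
  one <- simulate_crown_profile(1, 2)
  expect_equal(attr(one, "relief_truth"), sqrt(2))
  expect_equal(crown_metrics(one)$relief, sqrt(2), tolerance = 1e-12)
  four <- simulate_crown_profile(rep(0.5, 4), rep(0.5, 4))
  expect_equal(crown_metrics(four)$relief, 8 * sqrt(0.25^2 + 0.5^2) / 2,
               tolerance = 1e-12)
  expect_equal(crown_metrics(four)$relief, attr(four, "relief_truth"))
  expect_error(simulate_crown_profile(numeric(0), numeric(0)), "cusp")
})

test_that("seeded generator outputs are byte-identical on disk", {
  td <- withr::local_tempdir()
  cfg <- sim_config(200, 2, missing_rate = 0.1, seed = 5)
  f1 <- file.path(td, "a.vcf"); f2 <- file.path(td, "b.vcf")
  write_variant_vcf(simulate_genotypes(seal_model(), cfg)$variants, f1)
  write_variant_vcf(simulate_genotypes(seal_model(), cfg)$variants, f2)
  expect_identical(readLines(f1), readLines(f2))
  seg <- data.frame(duration = c(500, 2000), m = c(1e-5, 2e-4))
  t1 <- simulate_migration_trajectory(seg, pairs = 3, noise_sd = 0.1,
                                      seed = 2, out_dir = file.path(td, "x"))
  t2 <- simulate_migration_trajectory(seg, pairs = 3, noise_sd = 0.1,
                                      seed = 2, out_dir = file.path(td, "y"))
  expect_identical(readLines(t1$files[2]), readLines(t2$files[2]))
})
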