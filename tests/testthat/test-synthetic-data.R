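test_that("colonization simulator respects exposure bounds and saturates", {
  p_sat <- colonization_params(
    species = c("a", "b"), host_class = c("historical", "novel"),
    stage_intercepts = matrix(20, 2, 3), sd_tree = 1, sd_unit = 1)
  for (st in c("bark", "phloem", "brood")) {
    tr <- simulate_colonization(p_sat, st, seed = 7)
    expect_true(all(tr$n_success == tr$n_exposed))
    expect_true(all(tr$n_success >= 0))
    expect_true(is.integer(tr$n_success))
  }
})

test_that("null intercepts with no random effects recover p = 0.5", {
  p <- colonization_params(
    species = "a", host_class = "novel",
    stage_intercepts = matrix(0, 1, 3),
    sd_tree = 0, sd_unit = 0, phloem_slope = 0,
    design = flat_design(units = 200L, per = 50L))  # N = 10,000
  tr <- simulate_colonization(p, "bark", seed = 11)
  N <- sum(tr$n_exposed)
  expect_equal(N, 10000)
  frac <- sum(tr$n_success) / N
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / N))
})

test_that("default stage calibration recovers the pooled stage rates", {
  truth <- c(bark = 0.633, phloem = 0.847, brood = 0.702)
  p <- colonization_params(sd_tree = 0, sd_unit = 0, phloem_slope = 0,
                           design = flat_design(units = 100L, per = 50L))
  for (st in names(truth)) {
    tr <- simulate_colonization(p, st, seed = 5)
    N <- sum(tr$n_exposed)
    frac <- sum(tr$n_success) / N
    expect_lt(abs(frac - truth[[st]]),
              3 * sqrt(truth[[st]] * (1 - truth[[st]]) / N))
  }
})

test_that("all generators are seed-deterministic", {
  pc <- colonization_params()
  expect_identical(simulate_colonization(pc, "bark", seed = 3),
                   simulate_colonization(pc, "bark", seed = 3))
  expect_false(identical(simulate_colonization(pc, "bark", seed = 3),
                         simulate_colonization(pc, "bark", seed = 4)))
  pt <- trap_params()
  expect_identical(simulate_traps(pt, seed = 3), simulate_traps(pt, seed = 3))
  px <- chem_params()
  expect_identical(simulate_chemistry(px, seed = 3),
                   simulate_chemistry(px, seed = 3))
})

test_that("raising a stage intercept never decreases success counts (CRN)", {
  set.seed(202)
  for (rep in 1:20) {
    b0 <- rnorm(1, 0, 1.5)
    base <- colonization_params(
      species = "a", host_class = "novel",
      stage_intercepts = matrix(b0, 1, 3),
      sd_tree = runif(1, 0, 1), sd_unit = runif(1, 0, 0.5),
      design = flat_design(units = 10L, per = 10L))
    up <- base
    up$stage_intercepts[] <- b0 + runif(1, 0.1, 2)
    seed <- sample.int(1e6, 1)
    lo <- simulate_colonization(base, "bark", seed = seed)
    hi <- simulate_colonization(up, "bark", seed = seed)
    expect_true(all(hi$n_success >= lo$n_success))
  }
})

test_that("trap simulator matches its stated mean and handles edge designs", {
  p <- trap_params(log_means = c(only = log(4), pad = log(4)),
                   sd_site = 0, sd_week = 0, dispersion = 0.5,
                   n_sites = 400L, n_weeks = 2L)
  tr <- simulate_traps(p, seed = 9)
  y <- tr$count[tr$treatment == "only"]
  # Var = lambda + phi lambda^2 = 4 + 0.5*16 = 12
  expect_lt(abs(mean(y) - 4), 3 * sqrt(12 / length(y)))
  expect_gt(var(y), mean(y))  # overdispersed beyond Poisson

  empty <- simulate_traps(trap_params(n_sites = 0L), seed = 1)
  expect_s3_class(empty, "data.frame")
  expect_identical(nrow(empty), 0L)

  expect_error(trap_params(dispersion = 0), "dispersion")
  expect_error(trap_params(log_means = c(a = 1)), "two treatments")
})

test_that("chemistry simulator: zero-variance limit, ratios, totals", {
  p0 <- chem_params(species = c("s1", "s2"), log_means = log(2), log_sds = 0,
                    trees_per_species = 3L)
  ch <- simulate_chemistry(p0, seed = 1)
  expect_true(all(ch$mg_per_g == 2))

  # species log-means differing by ln 6 at zero SD: total ratio exactly 6
  lm_ <- matrix(log(1), 2, length(COMPOUNDS),
                dimnames = list(c("s1", "s2"), COMPOUNDS))
  lm_["s2", ] <- lm_["s2", ] + log(6)
  p6 <- chem_params(species = c("s1", "s2"), log_means = lm_, log_sds = 0,
                    trees_per_species = 2L)
  tot <- total_monoterpenes(simulate_chemistry(p6, seed = 1))
  m1 <- mean(tot$total_mono_mg_per_g[tot$species == "s1"])
  m2 <- mean(tot$total_mono_mg_per_g[tot$species == "s2"])
  expect_equal(m2 / m1, 6)

  # totals are the sum of the seven monoterpenes, excluding 4-allylanisole
  ch6 <- simulate_chemistry(p6, seed = 1)
  one <- ch6[ch6$tree_id == ch6$tree_id[1], ]
  expect_equal(tot$total_mono_mg_per_g[tot$tree_id == one$tree_id[1]],
               sum(one$mg_per_g[one$compound != "4-allylanisole"]))
  expect_false("4-allylanisole" %in% MONOTERPENES)
})

test_that("packaged fixture tables match their printed sources digit for digit", {
  fx <- fixture_tables()
  expect_identical(fx$pooled$exp1_pooled$successes, 532L)
  expect_identical(fx$pooled$exp1_pooled$total, 840L)
  expect_identical(fx$pooled$exp2_pooled$percent, 84.7)
  expect_identical(fx$pooled$exp2_pooled$total, 1123L)
  expect_identical(fx$pooled$exp3_pooled$percent, 70.2)

  t1 <- fx$table1
  expect_equal(t1$dbh_mean[t1$year == 2013 & t1$species == "ponderosa"],
               25.76)
  expect_equal(t1$phloem_se[t1$year == 2014 & t1$species == "scots"], 0.07)
  expect_true(all(t1$n == 4))

  t2 <- fx$table2
  row <- t2[t2$species == "ponderosa" & t2$hours == 72, ]
  expect_equal(unlist(row[, c("mean_pct", "ci_lo", "ci_hi")],
                      use.names = FALSE), c(74.8, 66.5, 81.7))
  f13 <- fx$table1_footer
  expect_equal(f13$F[f13$year == 2013 & f13$column == "dbh"], 1.46)
  expect_equal(f13$F[f13$year == 2014 & f13$column == "dbh"], 0.83)
})

test_that("parameter validation rejects malformed designs", {
  expect_error(colonization_params(sd_tree = -1), "SDs")
  expect_error(colonization_params(stage_intercepts = matrix(Inf, 6, 3)),
               "finite")
  expect_error(simulate_colonization(colonization_params(), "larva", 1),
               "stage")
  expect_error(chem_params(log_sds = -0.1), "log_sds")
})
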