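test_that("transform registry covers every analysed response", {
  expect_equal(apply_transform(4, "sqrt"), 2)
  expect_equal(apply_transform(0, "log1p"), 0)
  expect_equal(apply_transform(9, "log1p"), log(10))
  expect_error(apply_transform(-1, "sqrt"), "negative")
  expect_error(apply_transform(-1, "log1p"), "negative")

  reg <- transform_registry()
  expect_identical(unname(reg["trap_count"]), "sqrt")
  expect_identical(unname(reg["alpha-pinene"]), "identity")
  expect_identical(unname(reg["4-allylanisole"]), "sqrt")
  for (cmp in c("beta-pinene", "3-carene", "myrcene", "limonene",
                "beta-phellandrene", "camphene"))
    expect_identical(unname(reg[cmp]), "log1p")
})

test_that("one-way ANOVA matches hand decomposition", {
  a <- oneway_anova(list(lo = c(1, 2, 3), hi = c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_identical(c(a$df_num, a$df_den), c(1L, 4L))
  expect_equal(a$ms_between, 13.5)  # SSB = 13.5, MSW = 1
  expect_equal(a$ms_within, 1)
  expect_equal(a$F, a$ms_between / a$ms_within)

  flat <- oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3) + 1e-15))
  expect_lt(flat$F, 1e-12)
})

test_that("summary-statistics ANOVA reconstructs published omnibus F values", {
  fx <- fixture_tables()
  for (yr in c(2013, 2014)) {
    t1 <- fx$table1[fx$table1$year == yr, ]
    a <- anova_from_summary(t1$dbh_mean, t1$dbh_se, n = 4,
                            names = t1$species)
    ref <- fx$table1_footer
    expect_equal(round(a$F, 2), ref$F[ref$year == yr & ref$column == "dbh"])
    expect_identical(c(a$df_num, a$df_den), c(5L, 18L))
  }
  same <- anova_from_summary(rep(3, 4), c(0.2, 0.4, 0.1, 0.3), n = 5)
  expect_equal(same$F, 0)
  expect_error(anova_from_summary(1:3, c(1, 1), 4), "equal length")
  expect_error(anova_from_summary(1:3, rep(1, 3), 1), "n >= 2")
})

test_that("summary-vs-raw equivalence holds on random balanced data", {
  set.seed(88)
  for (rep in 1:50) {
    k <- sample(2:6, 1); n <- sample(3:9, 1)
    groups <- replicate(k, rnorm(n, mean = runif(1, -2, 2),
                                 sd = runif(1, 0.2, 3)), simplify = FALSE)
    names(groups) <- paste0("g", 1:k)
    raw <- oneway_anova(groups)
    summ <- anova_from_summary(vapply(groups, mean, 0),
                               vapply(groups, function(g) sd(g) / sqrt(n), 0),
                               n = n)
    expect_equal(summ$F, raw$F, tolerance = 1e-10)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-10)
  }
})

test_that("blocked ANOVA reduces to one-way without blocks and matches a
           least-squares oracle with them", {
  set.seed(9)
  d <- expand.grid(site = paste0("s", 1:4), week = c("w1", "w2"),
                   treatment = paste0("t", 1:3), stringsAsFactors = FALSE)
  d$count <- rpois(nrow(d), 5)

  ab <- blocked_anova(d, "count", "treatment", blocks = character())
  ao <- oneway_anova(split(d$count, d$treatment))
  expect_equal(ab$F, ao$F, tolerance = 1e-12)
  expect_equal(ab$df_den, ao$df_den)

  # RCB with real block effects: treatment F from explicit normal equations
  d$count <- d$count + rep(c(0, 3, 6), each = 8)
  full <- stats::model.matrix(~ factor(site) + factor(week) +
                                factor(treatment), d)
  red <- stats::model.matrix(~ factor(site) + factor(week), d)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$count)
    sum((d$count - X %*% beta)^2)
  }
  df1 <- ncol(full) - ncol(red)
  df2 <- nrow(d) - ncol(full)
  f_oracle <- ((rss(red) - rss(full)) / df1) / (rss(full) / df2)
  ab2 <- blocked_anova(d, "count", "treatment", blocks = c("site", "week"))
  expect_equal(ab2$F, f_oracle, tolerance = 1e-10)
  expect_identical(c(ab2$df_num, ab2$df_den), c(df1, df2))

  # relabeling block levels must not move the treatment test
  d2 <- d; d2$site <- paste0("z", match(d$site, unique(d$site)))
  ab3 <- blocked_anova(d2, "count", "treatment", blocks = c("site", "week"))
  expect_equal(ab3$F, ab2$F, tolerance = 1e-12)
})

test_that("compact letter display handles none/all/chain significance", {
  gn <- c("A", "B", "C")
  none <- matrix(FALSE, 3, 3, dimnames = list(gn, gn))
  expect_true(all(compact_letter_display(none) == "a"))

  all_sig <- matrix(TRUE, 3, 3, dimnames = list(gn, gn)); diag(all_sig) <- FALSE
  expect_equal(sort(unname(compact_letter_display(all_sig))),
               c("a", "b", "c"))

  chain <- none; chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(compact_letter_display(chain),
               c(A = "a", B = "ab", C = "b"))

  asym <- none; asym["A", "B"] <- TRUE
  expect_error(compact_letter_display(asym), "asymmetric")
})

test_that("protected LSD separates means only after a significant omnibus", {
  # {1,2,3} vs {4,5,6}: F = 13.5 significant; LSD = 2.776*sqrt(2/3) < 3
  a <- oneway_anova(list(lo = c(1, 2, 3), hi = c(4, 5, 6)))
  l <- protected_lsd(a)
  expect_true(l$omnibus_significant)
  expect_equal(unname(l$lsd["hi", "lo"]), qt(0.975, 4) * sqrt(2 / 3),
               tolerance = 1e-10)
  expect_false(l$letters[["hi"]] == l$letters[["lo"]])

  # non-significant omnibus: one shared letter, zero significant pairs
  ns <- anova_from_summary(c(24.22, 23.61, 22.93, 23.10, 24.13, 23.56),
                           c(0.21, 0.48, 0.55, 0.36, 0.63, 0.93), n = 4,
                           names = paste0("s", 1:6))
  expect_gt(ns$p_value, 0.05)
  lns <- protected_lsd(ns)
  expect_false(lns$omnibus_significant)
  expect_identical(lns$n_significant_pairs, 0L)
  expect_true(all(lns$letters == lns$letters[1]))

  # overlap chain: A != C but A = B and B = C
  g <- list(A = c(-1, -0.5, 0, 0.5, 1),
            B = c(-1, -0.5, 0, 0.5, 1) + 1,
            C = c(-1, -0.5, 0, 0.5, 1) + 2)
  ac <- oneway_anova(g)
  lc <- protected_lsd(ac)
  expect_true(lc$omnibus_significant)
  expect_equal(unname(lc$letters[c("C", "B", "A")]), c("a", "ab", "b"))
})

test_that("Bonferroni indicator scan flags a planted outlier and matches a
           deleted-residual oracle", {
  set.seed(4)
  d <- data.frame(y = rnorm(20))
  d <- rbind(d, data.frame(y = 10))  # ~10 SDs out
  rep_ <- bonferroni_outlier_scan(d, y ~ 1, candidates = 21L)
  expect_identical(rep_$flagged, 21L)
  expect_lt(rep_$p_values[["21"]], 0.05 / 21)
  expect_equal(rep_$thresholds[["21"]], 0.05 / 21)

  # oracle: indicator t-test in y ~ 1 equals the externally-deleted t test
  yi <- d$y[21]; rest <- d$y[-21]
  tt <- (yi - mean(rest)) / (sd(rest) * sqrt(1 + 1 / length(rest)))
  p_oracle <- 2 * pt(-abs(tt), df = length(rest) - 1)
  expect_equal(rep_$p_values[["21"]], p_oracle, tolerance = 1e-10)

  expect_identical(length(bonferroni_outlier_scan(d, y ~ 1,
                                                  integer(0))$flagged), 0L)

  # homogeneous data: scanning every point flags nothing
  set.seed(10)
  h <- data.frame(y = rnorm(20))
  all_scan <- bonferroni_outlier_scan(h, y ~ 1, candidates = 1:20)
  expect_identical(all_scan$flagged, integer(0))
  # brute-force check that no deleted-residual p crosses the Bonferroni cut
  p_all <- vapply(1:20, function(i) {
    tt <- (h$y[i] - mean(h$y[-i])) /
      (sd(h$y[-i]) * sqrt(1 + 1 / 19))
    2 * pt(-abs(tt), 18)
  }, 0)
  expect_true(min(p_all) >= 0.05 / 20)
})
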