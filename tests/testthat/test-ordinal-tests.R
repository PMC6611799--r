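test_that("ridit scores follow the cumulative-midpoint formula", {
  expect_equal(ridit_scores(c(10, 10, 20)), c(0.125, 0.375, 0.75))
  expect_equal(ridit_scores(57), 0.5)   # single category: whole-distribution midpoint
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:200, sample(2:8, 1), replace = TRUE)
    r <- ridit_scores(n)
    expect_true(all(r > 0 & r < 1))
    expect_true(all(diff(r) >= 0))
    expect_equal(sum(n * r) / sum(n), 0.5)   # combined mean ridit identity
  }
  expect_error(ridit_scores(c(0, 0)), "zero")
})

test_that("ridit test matches the expanded rank-sum oracle on fixed tables", {
  res <- ridit_test(c(9, 0), c(0, 9))
  expect_equal(res$mean_ridits[["ref"]], 0.25)
  expect_equal(res$mean_ridits[["alt"]], 0.75)
  expect_equal(res$statistic, oracle_ranksum_z(c(9, 0), c(0, 9)))
  expect_equal(abs(res$statistic), 4.1231, tolerance = 1e-4)

  # unrelated variant: equal allele ratios in all three bulks
  null <- ridit_test(c(50, 50, 50), c(50, 50, 50))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
})

test_that("ridit z equals the brute-force oracle on random tables", {
  set.seed(42)
  checked <- 0
  while (checked < 300) {
    tab <- random_grade_table()
    if (is_degenerate_table(tab$ref, tab$alt)) next
    z <- ridit_test(tab$ref, tab$alt)$statistic
    z_oracle <- oracle_ranksum_z(tab$ref, tab$alt)
    if (abs(z_oracle) < 1e-10) {
      expect_equal(z, z_oracle, tolerance = 1e-10)
    } else {
      expect_equal(z, z_oracle, tolerance = 1e-12)
    }
    checked <- checked + 1
  }
})

test_that("swapping allele rows negates z and preserves p", {
  set.seed(7)
  for (i in 1:25) {
    tab <- random_grade_table()
    if (is_degenerate_table(tab$ref, tab$alt)) next
    a <- ridit_test(tab$ref, tab$alt)
    b <- ridit_test(tab$alt, tab$ref)
    expect_equal(a$statistic, -b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("ridit p agrees with wilcox.test on the expanded observations", {
  for (tab in list(list(ref = c(30, 50, 70), alt = c(70, 50, 30)),
                   list(ref = c(12, 0, 7, 20), alt = c(3, 9, 9, 1)))) {
    vals <- rep(seq_along(tab$ref), tab$ref + tab$alt)
    grp <- unlist(lapply(seq_along(tab$ref), function(j) {
      rep(c(1, 2), c(tab$ref[j], tab$alt[j]))
    }))
    w <- suppressWarnings(
      stats::wilcox.test(vals[grp == 1], vals[grp == 2], correct = FALSE)
    )
    expect_equal(ridit_test(tab$ref, tab$alt)$p_value, w$p.value,
                 tolerance = 1e-10)
  }
})

test_that("the Bross variance option gives the classical approximation", {
  # same mean-ridit difference, variance (1/12)(1/n1 + 1/n2)
  res <- ridit_test(c(30, 70), c(70, 30), variance = "bross")
  d <- res$mean_ridits[["ref"]] - res$mean_ridits[["alt"]]
  expect_equal(res$statistic, d / sqrt((1 / 100 + 1 / 100) / 12))
  # ignoring the tie reduction overstates the variance on a 2-category table
  expect_lt(abs(res$statistic), abs(ridit_test(c(30, 70), c(70, 30))$statistic))
})

test_that("degenerate tables return the p = 1 convention", {
  empty_group <- ridit_test(c(0, 0, 0), c(10, 20, 30))
  expect_equal(empty_group$p_value, 1)
  expect_true(empty_group$degenerate)
  one_grade <- ridit_test(c(40, 0), c(60, 0))   # all mass in one grade
  expect_equal(one_grade$p_value, 1)
  expect_equal(one_grade$statistic, 0)
})

test_that("Kruskal-Wallis H matches kruskal.test and the k = 2 identity", {
  null <- kruskal_wallis_test(c(50, 50, 50), c(50, 50, 50))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  # z^2 = H for two grades (both tie-corrected)
  z <- ridit_test(c(30, 70), c(70, 30))$statistic
  h <- kruskal_wallis_test(c(30, 70), c(70, 30))$statistic
  expect_equal(z^2, h, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:10) {
    tab <- random_grade_table(k = sample(3:5, 1), max_count = 30)
    if (is_degenerate_table(tab$ref, tab$alt)) next
    vals <- c(rep(0, sum(tab$ref)), rep(1, sum(tab$alt)))
    grades <- c(rep(seq_along(tab$ref), tab$ref),
                rep(seq_along(tab$alt), tab$alt))
    keep <- grades %in% which(tab$ref + tab$alt > 0)
    kt <- stats::kruskal.test(vals[keep], factor(grades[keep]))
    mine <- kruskal_wallis_test(tab$ref, tab$alt)
    expect_equal(mine$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, kt$p.value, tolerance = 1e-10)
  }

  one_grade <- kruskal_wallis_test(c(40, 0), c(60, 0))
  expect_equal(one_grade$p_value, 1)
})

test_that("chi-square matches hand computation and handles zero columns", {
  null <- chisq_test(c(50, 50, 50), c(50, 50, 50))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  res <- chisq_test(c(90, 10), c(10, 90))
  expect_equal(res$statistic, 128)
  expect_equal(res$df, 1L)

  withzero <- chisq_test(c(40, 0, 20), c(20, 0, 40))
  expect_equal(withzero$df, 1L)

  expect_error(chisq_test(c(0, 0), c(10, 20)), "empty")

  # vectorised track path agrees with stats::chisq.test
  set.seed(9)
  for (i in 1:10) {
    tab <- random_grade_table(k = 4, max_count = 50)
    if (is_degenerate_table(tab$ref, tab$alt)) next
    rows <- gradedpool:::chisq_rows(matrix(tab$ref, 1), matrix(tab$alt, 1))
    ref <- chisq_test(tab$ref, tab$alt)
    expect_equal(rows$statistic, ref$statistic, tolerance = 1e-12)
    expect_equal(rows$p_value, ref$p_value, tolerance = 1e-12)
  }
})

test_that("null binomial read counts give uniform p-values", {
  set.seed(1234)
  m <- 4000
  depth <- 100
  ref <- matrix(rbinom(3 * m, depth, 0.5), m, 3)
  t <- make_variants(ref, depth - ref)
  for (method in c("ridit", "kw", "chisq")) {
    pv <- test_track(t, method = method)
    frac <- mean(pv$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / m)
    expect_lt(abs(frac - 0.05), 3 * se + 1e-12)
    expect_true(all(pv$p_value >= 0 & pv$p_value <= 1))
    expect_true(all(is.finite(pv$neg_ln_p)))
  }
  # tail calibration at the thresholds the scan uses; a whole-range
  # Kolmogorov-Smirnov check is not applicable because the midrank z on
  # heavily tied tables has a discrete (lumpy) null distribution
  pv <- test_track(t)
  for (a in c(0.001, 0.01, 0.1)) {
    se_a <- sqrt(a * (1 - a) / m)
    expect_lt(abs(mean(pv$p_value < a) - a), 4 * se_a + 2e-4)
  }
})

test_that("a monotone QTL-like gradient yields tiny p-values", {
  set.seed(99)
  m <- 200
  depth <- 100
  f <- c(0.3, 0.5, 0.7)
  alt <- sapply(f, function(p) rbinom(m, depth, p))
  t <- make_variants(depth - alt, alt)
  pv <- test_track(t)
  expect_lt(median(pv$p_value), 1e-3)
})

test_that("steeper allele-frequency gradients never raise the mean ridit p", {
  set.seed(17)
  depth <- 100
  reps <- 400
  mean_p <- sapply(c(0.02, 0.06, 0.12, 0.20), function(delta) {
    f <- c(0.5 - delta, 0.5, 0.5 + delta)
    alt <- sapply(f, function(p) rbinom(reps, depth, p))
    t <- make_variants(depth - alt, alt)
    mean(test_track(t)$p_value)
  })
  expect_true(all(diff(mean_p) <= 0))
})

test_that("empty tables give empty tracks and scaling stays in bounds", {
  t <- make_variants(matrix(0L, 0, 3), matrix(0L, 0, 3))
  expect_equal(nrow(test_track(t)), 0L)
  t2 <- make_variants(rbind(c(30, 50, 70)), rbind(c(70, 50, 30)))
  full <- test_track(t2)
  scaled <- test_track(t2, effective_size = 0.5)
  expect_gt(scaled$p_value, full$p_value)   # shrunken evidence
  expect_error(test_track(t2, effective_size = 1.5))
})
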