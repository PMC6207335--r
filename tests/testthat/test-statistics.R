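test_that("Mann-Whitney U reproduces small exact cases and degenerate input", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(5, 5, 5), c(5, 5))
  expect_equal(same$p_value, 1)

  # identical multisets with distinct values: maximal p
  x <- c(1, 3, 7)
  expect_gt(mann_whitney_u(x, x)$p_value, 0.99)
})

test_that("the exact branch agrees with enumeration on tie-free samples", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)  # distinct values
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_mwu_exact(x, y), tolerance = 1e-9)
  }
})

test_that("a 2-sigma location shift at n = 50 is essentially always detected", {
  set.seed(77)
  hits <- vapply(1:100, function(i) {
    mann_whitney_u(rnorm(50), rnorm(50, mean = 2))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("Dunn's test reduces to a rank-sum z-test for two groups", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(18)
  d <- dunn_bonferroni(list(x, y))
  expect_equal(nrow(d), 1)
  # closed form: z from mean rank difference with no tie correction
  r <- rank(c(x, y))
  rb1 <- mean(r[seq_along(x)]); rb2 <- mean(r[-seq_along(x)])
  N <- 33
  z <- (rb1 - rb2) / sqrt(N * (N + 1) / 12 * (1 / 15 + 1 / 18))
  expect_equal(d$z, z, tolerance = 1e-9)
  expect_equal(d$p_value, min(1, 2 * pnorm(-abs(z))), tolerance = 1e-9)

  ident <- dunn_bonferroni(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$p_value, 1)
})

test_that("Dunn flags only the shifted group among three", {
  set.seed(123)
  ok <- vapply(1:200, function(i) {
    g <- list(a = rnorm(40), b = rnorm(40), c = rnorm(40, mean = 3))
    d <- dunn_bonferroni(g)
    shifted <- d$p_value[d$group_i == "c" | d$group_j == "c"]
    null_pair <- d$p_value[d$group_i == "a" & d$group_j == "b"]
    all(shifted < 0.025) && null_pair >= 0.025
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  expect_error(dunn_bonferroni(list(1:3, numeric(0))), "non-empty")
})

test_that("feature comparison finds a planted effect in the buried subset", {
  set.seed(9)
  n <- 120
  early <- rep(c(TRUE, FALSE), c(40, 80))
  tab <- data.frame(
    folding_class = ifelse(early, "EARLY", "LATE"),
    functional = FALSE,
    buried = runif(n) < 0.5,
    energy = ifelse(early, rnorm(n, -10), rnorm(n, -5)))
  cmp <- compare_feature(tab, "energy", "folding_class")
  expect_true(cmp$significant)
  expect_lt(cmp$groups$mean[cmp$groups$group == "EARLY"],
            cmp$groups$mean[cmp$groups$group == "LATE"])
  expect_equal(cmp$test, "mann_whitney")

  # identical distributions: insignificant
  tab$flat <- rep(1:10, 12)
  cmp2 <- compare_feature(tab, "flat", "folding_class")
  expect_false(cmp2$significant)
  expect_gt(cmp2$p_buried, 0.5)

  # a grouping without both levels is an error naming the issue
  tab$folding_class <- "LATE"
  expect_error(compare_feature(tab, "energy", "folding_class"), "empty group")
})

test_that("count features route to Dunn with its stricter alpha", {
  set.seed(10)
  tab <- data.frame(
    folding_class = rep(c("EARLY", "LATE"), c(40, 60)),
    functional = FALSE, buried = TRUE,
    n_hbond = rpois(100, 3))
  cmp <- compare_feature(tab, "n_hbond", "folding_class")
  expect_equal(cmp$test, "dunn")
  expect_equal(cmp$alpha, 0.025)
})

test_that("overlap shift is observed minus expected joint percentage", {
  ov <- overlap_shift(0, 16, 4, 82)
  expect_equal(round(ov$shift_pct, 2), -0.95)
  ov2 <- overlap_shift(1, 16, 13, 82)
  expect_equal(round(ov2$shift_pct, 2), -1.87)
  expect_equal(ov2$shift_pct, ov2$observed_pct - ov2$expected_pct)

  certain <- overlap_shift(10, 10, 10, 10)
  expect_equal(certain$shift_pct, 0)

  expect_error(overlap_shift(5, 4, 10, 20))  # n_obs > min(n_A, n_B)
  expect_error(overlap_shift(0, 1, 1, 0), "positive")
})

test_that("the contingency summary reproduces its printed worked example", {
  cs <- contingency_summary(list(early_functional = 22,
                                 early_nonfunctional = 324,
                                 late_functional = 130,
                                 late_nonfunctional = 2014))
  expect_equal(cs$total, 2490)
  expect_equal(round(cs$observed_pct, 1), 0.9)
  expect_equal(round(cs$expected_pct, 1), 0.8)

  all_both <- data.frame(folding_class = rep("EARLY", 10),
                         functional = TRUE)
  cs2 <- contingency_summary(all_both)
  expect_equal(cs2$observed_pct, 100)
  expect_equal(cs2$expected_pct, 100)
})

test_that("independent labels give matching observed and expected rates", {
  set.seed(2024)
  N <- 1e5
  tab <- data.frame(folding_class = ifelse(runif(N) < 0.15, "EARLY", "LATE"),
                    functional = runif(N) < 0.06)
  cs <- contingency_summary(tab)
  expect_lt(abs(cs$observed_pct - cs$expected_pct), 0.2)
})

test_that("notch bounds follow the 1.57 IQR / sqrt(n) convention", {
  flat <- notch_bounds(rep(3, 10))
  expect_equal(flat$lower, flat$upper)

  nb <- notch_bounds(1:100)
  expect_equal(nb$median, 50.5)
  expect_equal(nb$upper - nb$median, 1.57 * 49.5 / 10, tolerance = 1e-12)

  # quadrupling n roughly halves the notch width
  x <- rnorm(100)
  w1 <- diff(unlist(notch_bounds(x)[c("lower", "upper")]))
  w4 <- diff(unlist(notch_bounds(rep(x, 4))[c("lower", "upper")]))
  expect_equal(unname(w4 / w1), 0.5, tolerance = 0.05)
})
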