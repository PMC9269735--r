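test_that("extreme-outlier rule removes only values above Q3 + 3 IQR", {
  same <- exclude_extreme_outliers(rep(5, 10))
  expect_length(same$removed, 0)
  expect_equal(same$kept, rep(5, 10))

  # rule is upper-side only: a symmetric low outlier stays
  low <- c(-1000, 1, 2, 3, 4, 5, 6, 7, 8)
  r <- exclude_extreme_outliers(low)
  expect_true(-1000 %in% r$kept)
  expect_length(r$removed, 0)

  x <- c(1:8, 1000)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  cut <- q[2] + 3 * (q[2] - q[1])
  rx <- exclude_extreme_outliers(x)
  expect_equal(rx$removed, x[x > cut])
  expect_equal(rx$cutoff, cut)

  expect_warning(exclude_extreme_outliers(1:3), "fewer than 4")
})

test_that("outlier exclusion matches a brute-force quantile oracle on random samples", {
  set.seed(19)
  for (i in 1:50) {
    x <- c(rnorm(sample(10:40, 1)), if (runif(1) < 0.5) runif(1, 5, 50))
    q1 <- as.numeric(quantile(x, 0.25, type = 7))
    q3 <- as.numeric(quantile(x, 0.75, type = 7))
    expect_equal(sort(exclude_extreme_outliers(x)$removed),
                 sort(x[x > q3 + 3 * (q3 - q1)]))
  }
})

test_that("outlier exclusion is idempotent on typical samples", {
  set.seed(23)
  for (i in 1:30) {
    x <- c(rnorm(25), if (runif(1) < 0.5) runif(1, 8, 60))
    once <- exclude_extreme_outliers(x)$kept
    twice <- exclude_extreme_outliers(once)$kept
    expect_equal(sort(twice), sort(once))
  }
})

test_that("normality check accepts normal quantiles and rejects skew and constants", {
  q <- qnorm(ppoints(21))
  nc <- normality_check(q)
  expect_true(nc$is_normal)
  expect_equal(nc$p, shapiro.test(q)$p.value)

  # Shapiro-Wilk power against exp(1) at n = 21 is ~86% (estimated by
  # simulation), so well over three quarters of skewed samples must fail
  # the check.
  set.seed(3)
  rejected <- sum(sapply(1:100, function(i) {
    !normality_check(rexp(21))$is_normal
  }))
  expect_gte(rejected, 80)

  cst <- normality_check(rep(2, 10))
  expect_true(cst$degenerate)
  expect_false(cst$is_normal)
  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("Bonferroni thresholds reproduce the printed reporting forms", {
  b4 <- bonferroni_alpha(0.05, 4)
  expect_equal(b4$threshold, 0.0125)
  expect_equal(b4$reported, 0.013)
  b3 <- bonferroni_alpha(0.05, 3)
  expect_equal(b3$threshold, 0.05 / 3)
  expect_equal(b3$reported, 0.017)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("paired test gates on normality and handles identical visits", {
  x <- rnorm(21)
  same <- paired_change_test(x, x, m_comparisons = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  expect_equal(same$test, "paired-t")

  set.seed(9)
  t1 <- rnorm(21, 10, 1)
  t2 <- t1 + rnorm(21, 1, 0.5)      # normal differences
  r <- paired_change_test(t1, t2, m_comparisons = 3)
  expect_equal(r$test, "paired-t")
  expect_true(r$significant)
  expect_equal(r$alpha_corrected, 0.05 / 3)
  expect_equal(r$alpha_reported, 0.017)

  t2s <- t1 + rexp(21, 0.5)^3       # heavily skewed differences
  rs <- paired_change_test(t1, t2s, m_comparisons = 3)
  expect_equal(rs$test, "wilcoxon")
  expect_false(normality_check(t2s - t1)$is_normal)

  expect_error(paired_change_test(1:2, 2:3), "3 complete pairs")
})

test_that("significance flag is consistent with the corrected level", {
  set.seed(12)
  for (i in 1:20) {
    t1 <- rnorm(15)
    t2 <- t1 + rnorm(15, sd = 0.5) + runif(1, 0, 0.6)
    r <- paired_change_test(t1, t2, m_comparisons = sample(1:5, 1))
    expect_identical(r$significant, r$p < r$alpha_corrected)
  }
})

test_that("Pearson agreement matches the textbook formula and strength classes", {
  x <- 1:10
  perfect <- pearson_agreement(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$strength, "strong")

  set.seed(8)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  ag <- pearson_agreement(a, b)
  r_brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_stat <- r_brute * sqrt(18 / (1 - r_brute^2))
  p_brute <- 2 * pt(-abs(t_stat), 18)
  expect_lt(abs(ag$r - r_brute), 1e-12)
  expect_lt(abs(ag$p - p_brute), 1e-12)

  expect_error(pearson_agreement(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_agreement(1:2, 2:3), "3 complete pairs")
})

test_that("strength classification partitions [0, 1] at 0.10/0.40/0.70", {
  cls <- function(r) gaitsense:::classify_strength(r)
  expect_equal(cls(0), "negligible")
  expect_equal(cls(0.0999), "negligible")
  expect_equal(cls(0.10), "weak")
  expect_equal(cls(0.39), "weak")
  expect_equal(cls(0.40), "moderate")
  expect_equal(cls(0.69), "moderate")
  expect_equal(cls(0.70), "strong")
  expect_equal(cls(1), "strong")
  expect_equal(cls(-0.5), "moderate")  # |r| is classified
  # no gaps: every |r| in [0,1] gets exactly one label
  rs <- seq(0, 1, by = 0.001)
  labs <- sapply(rs, cls)
  expect_true(all(labs %in% c("negligible", "weak", "moderate", "strong")))
})

test_that("agreement is invariant to positive affine transforms", {
  set.seed(21)
  x <- rnorm(24); y <- 0.8 * x + rnorm(24, sd = 0.4)
  base <- pearson_agreement(x, y)
  tr <- pearson_agreement(3 * x + 7, 0.2 * y - 11)
  expect_lt(abs(tr$r - base$r), 1e-12)
})

test_that("agreement tables pair systems per variable and omit absent variables", {
  set.seed(14)
  n <- 24
  cad <- rnorm(n, 1.7, 0.1)
  feats <- rbind(
    data.frame(subject = 1:n, system = "mocap", task = "normal",
               variable = "cadence", value = cad),
    data.frame(subject = 1:n, system = "smartphone", task = "normal",
               variable = "cadence", value = cad),
    data.frame(subject = 1:n, system = "mocap", task = "normal",
               variable = "step_width", value = rnorm(n, 0.11, 0.02)))
  tb <- build_agreement_tables(feats)
  cad_row <- tb[tb$variable == "cadence", ]
  expect_equal(cad_row$r, 1)
  # step width exists only in one system: no cell at all
  expect_false("step_width" %in% tb$variable)
})

test_that("agreement tables recover a configured correlation", {
  set.seed(30)
  hits <- sum(sapply(1:100, function(i) {
    n <- 24
    true <- rnorm(n, 1.7, 0.1)
    phone <- true + rnorm(n, 0, sd(true) * sqrt(1 / 0.9^2 - 1))
    feats <- rbind(
      data.frame(subject = 1:n, system = "mocap", task = "normal",
                 variable = "cadence", value = true),
      data.frame(subject = 1:n, system = "smartphone", task = "normal",
                 variable = "cadence", value = phone))
    tb <- build_agreement_tables(feats)
    abs(tb$r - 0.9) <= 0.15
  }))
  expect_gte(hits, 90)
})
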