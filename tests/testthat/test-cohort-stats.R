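test_that("summary ANOVA equals raw-data ANOVA on random datasets", {
  # brute-force oracle on 50 random small datasets
  set.seed(2024)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(j)
      rnorm(sample(3:12, 1), mean = runif(1, -2, 2),
            sd = runif(1, 0.3, 2)))
    tri <- lapply(samples, function(x)
      c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x)))
    f_sum <- anova_from_summary(tri)
    x <- unlist(samples)
    g <- factor(rep(seq_len(k), vapply(samples, length, integer(1))))
    f_raw <- anova(lm(x ~ g))
    expect_equal(f_sum$statistic, f_raw[1, "F value"], tolerance = 1e-9)
    expect_equal(f_sum$p_value, f_raw[1, "Pr(>F)"], tolerance = 1e-9)
    expect_equal(f_sum$df, c(k - 1, length(x) - k))
  }
})

test_that("summary ANOVA reproduces the published group statistics", {
  s <- table1_summaries()
  n <- vapply(s, `[[`, integer(1), "n")
  f_of <- function(var) anova_from_summary(lapply(seq_along(s), function(i)
    c(s[[i]]$variables[[var]], n = unname(n[i]))))$statistic
  published <- c(D1_AOA = 1.168, D2_AOA = 0.440, D4_AOA = 3.155,
                 D5_AOA = 4.725, AAO_DAO = 7.321, weight = 2.754)
  for (v in names(published))
    expect_lt(abs(f_of(v) - published[[v]]) / published[[v]], 0.01)
})

test_that("summary ANOVA is degenerate and affine-invariant as expected", {
  eq <- anova_from_summary(list(c(mean = 1, sem = 0.2, n = 10),
                                c(mean = 1, sem = 0.1, n = 12)))
  expect_equal(eq$statistic, 0)
  base <- list(c(mean = 0.4, sem = 0.05, n = 9),
               c(mean = 0.9, sem = 0.07, n = 14),
               c(mean = 0.6, sem = 0.06, n = 11))
  f0 <- anova_from_summary(base)$statistic
  shifted <- lapply(base, function(g)
    c(mean = 3 + 2 * g[["mean"]], sem = 2 * g[["sem"]], n = g[["n"]]))
  expect_equal(anova_from_summary(shifted)$statistic, f0, tolerance = 1e-12)
  expect_error(anova_from_summary(list(c(mean = 1, sem = 1, n = 1),
                                       c(mean = 2, sem = 1, n = 5))),
               "n >= 2")
})

test_that("two-group summary F equals the pooled t statistic squared", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(11, 0.5)
    tri <- lapply(list(a, b), function(x)
      c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x)))
    f <- anova_from_summary(tri)$statistic
    # brute-force pooled two-sample t from the same summaries
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_stat <- (mean(a) - mean(b)) /
      sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(f, t_stat^2, tolerance = 1e-9)
  }
})

test_that("chi-square matches the closed forms", {
  # three-group gender table, against the hand-computed Pearson formula
  tab <- matrix(c(12, 15, 17, 8, 25, 18), nrow = 3, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - e)^2 / e)
  got <- chi_square_test(tab)
  expect_equal(got$statistic, oracle, tolerance = 1e-9)
  expect_equal(oracle, 2.99, tolerance = 0.01)
  expect_equal(got$df, 2)
  # 2x2 closed form N (ad - bc)^2 / row/col products
  t22 <- matrix(c(9, 4, 3, 11), 2)
  cf <- sum(t22) * (t22[1, 1] * t22[2, 2] - t22[1, 2] * t22[2, 1])^2 /
    prod(rowSums(t22), colSums(t22))
  expect_equal(chi_square_test(t22)$statistic, cf, tolerance = 1e-9)
  # invariances and degenerate cases
  expect_equal(chi_square_test(t22[2:1, ])$statistic, cf, tolerance = 1e-12)
  expect_equal(chi_square_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  prop <- matrix(c(10, 20, 5, 10), 2)   # proportional rows
  expect_equal(chi_square_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("the raw-data test battery behaves on known inputs", {
  set.seed(12)
  x <- rnorm(40); y <- rnorm(45, 0.3)
  out <- group_tests(list(a = x, b = y))
  expect_named(out, c("ks.a", "ks.b", "levene", "comparison"))
  expect_true(out$comparison$method %in% c("t_student", "t_welch"))
  # identical samples give t = 0
  out0 <- group_tests(list(a = x, b = x))
  expect_equal(out0$comparison$statistic, 0, tolerance = 1e-12)
  # three groups route to an ANOVA
  out3 <- group_tests(list(a = x, b = y, c = rnorm(30)))
  expect_true(out3$comparison$method %in% c("anova_raw", "anova_welch"))
  expect_error(group_tests(list(a = rep(1, 5), b = rnorm(5))), "constant")
  expect_error(group_tests(list(a = 1, b = rnorm(5))), "n >= 2")
})

test_that("t test and Levene test hold their nominal type-I error", {
  set.seed(31)
  n_rep <- 1000
  rej_t <- 0
  for (i in seq_len(n_rep)) {
    p <- group_tests(list(a = rnorm(1000), b = rnorm(1000)))$comparison
    rej_t <- rej_t + (p$p_value < 0.05)
  }
  expect_lt(abs(rej_t / n_rep - 0.05), 0.015)
  n_rep <- 2000
  rej_l <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(60); g <- factor(rep(1:2, each = 30))
    lv <- car::leveneTest(x, g, center = mean)
    rej_l <- rej_l + (lv[1, "Pr(>F)"] < 0.05)
  }
  expect_lt(abs(rej_l / n_rep - 0.05), 0.015)
})

test_that("the cohort table reports counts, percentages and tests", {
  df <- data.frame(group = rep(c("gothic", "crenel", "romanesque"),
                               c(27, 25, 43)),
                   v = rnorm(95), flag = rep(c(TRUE, FALSE), length.out = 95))
  tab <- build_table1(df, "group")
  expect_identical(tab$variable[1], "n")
  expect_match(tab$gothic[1], "27 \\(28.4%\\)")
  expect_match(tab$crenel[1], "25 \\(26.3%\\)")
  expect_match(tab$romanesque[1], "43 \\(45.3%\\)")
  expect_true("v" %in% tab$variable)
  # single group: summaries only, no statistics
  tab1 <- build_table1(df[df$group == "gothic", ], "group")
  expect_true(all(is.na(tab1$statistic)))
  expect_error(build_table1(df[0, ], "group"), "empty")
})
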