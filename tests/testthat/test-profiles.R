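pearson_oracle <- function(tab) {
  # textbook formula, independent of chisq.test
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

test_that("crosstab test equals the textbook Pearson formula on enumerated small tables", {
  for (n11 in 1:4) for (n12 in 1:4) for (n21 in 1:4) for (n22 in 1:4) {
    tab <- matrix(c(n11, n12, n21, n22), 2, byrow = TRUE)
    g <- rep(c("s1", "s2"), rowSums(tab))
    x <- c(rep(c("a", "b"), tab[1L, ]), rep(c("a", "b"), tab[2L, ]))
    ct <- suppressWarnings(crosstab_test(g, x))
    expect_equal(ct$chi_square, pearson_oracle(tab), tolerance = 1e-10)
    expect_equal(ct$df, 1L)
  }
  # a 2 x 3 and a 3 x 2 spot check
  g <- rep(c("s1", "s2"), c(9, 12))
  x <- c(rep(c("a", "b", "c"), c(2, 3, 4)), rep(c("a", "b", "c"), c(5, 3, 4)))
  ct <- suppressWarnings(crosstab_test(g, x))
  expect_equal(ct$chi_square, pearson_oracle(table(g, x)), tolerance = 1e-10)
  expect_equal(ct$df, 2L)
  g3 <- rep(c("s1", "s2", "s3"), each = 40)
  set.seed(1)
  x3 <- sample(c("18-22", "23-35"), 120, replace = TRUE)
  expect_equal(suppressWarnings(crosstab_test(g3, x3))$df, 2L)
})

test_that("identical segment compositions give chi-square zero", {
  g <- rep(c("s1", "s2"), each = 30)
  x <- rep(rep(c("a", "b", "c"), each = 10), 2)
  ct <- crosstab_test(g, x)
  expect_equal(ct$chi_square, 0)
  expect_equal(ct$p_value, 1)
})

test_that("crosstab rejects degenerate tables and warns about sparse cells", {
  expect_error(crosstab_test(rep("s1", 10), rep(c("a", "b"), 5)),
               "at least 2 segments")
  g <- rep(c("s1", "s2"), each = 4)
  x <- c("a", "a", "a", "b", "b", "b", "b", "a")
  expect_warning(crosstab_test(g, x), "expected counts")
})

test_that("Wilks' lambda matches the determinant-ratio oracle", {
  set.seed(42)
  g <- rep(c("g1", "g2", "g3"), each = 25)
  Y <- cbind(y1 = stats::rnorm(75) + (g == "g1"),
             y2 = stats::rnorm(75) - 0.5 * (g == "g3"),
             y3 = stats::rnorm(75))
  mv <- manova_profile(g, as.data.frame(Y))
  # SSCP oracle
  Gm <- rowsum(Y, g) / as.vector(table(g))
  Yc <- Y - Gm[g, ]
  W <- crossprod(Yc)
  Tm <- scale(Y, scale = FALSE)
  Btot <- crossprod(Tm) - W
  lambda <- det(W) / det(W + Btot)
  expect_equal(mv$wilks_lambda, lambda, tolerance = 1e-10)
  expect_true(mv$wilks_lambda > 0 && mv$wilks_lambda <= 1)
})

test_that("lambda is invariant to affine rescaling of a dependent variable", {
  set.seed(10)
  g <- rep(c("g1", "g2"), each = 20)
  Y <- data.frame(y1 = stats::rnorm(40) + (g == "g1"), y2 = stats::rnorm(40))
  l1 <- manova_profile(g, Y)$wilks_lambda
  Y$y2 <- 100 * Y$y2 - 7
  expect_equal(manova_profile(g, Y)$wilks_lambda, l1, tolerance = 1e-10)
})

test_that("two groups, one variable: MANOVA F equals the one-way ANOVA F", {
  set.seed(3)
  g <- rep(c("g1", "g2"), c(18, 22))
  y <- stats::rnorm(40) + 0.8 * (g == "g2")
  mv <- manova_profile(g, data.frame(score = y))
  f_aov <- summary(stats::aov(y ~ factor(g)))[[1L]]["F value"][1L, 1L]
  expect_equal(mv$approx_f, f_aov, tolerance = 1e-10)
})

test_that("equal group means give lambda one and pairwise non-significance", {
  g <- rep(c("g1", "g2", "g3"), each = 10)
  Y <- data.frame(y1 = rep(1:10, 3), y2 = rep(c(2, 5, 3, 8, 1, 9, 4, 7, 6, 0), 3))
  mv <- manova_profile(g, Y)
  expect_equal(mv$wilks_lambda, 1, tolerance = 1e-10)
  expect_lt(mv$approx_f, 1e-8)
  expect_true(all(mv$pairwise$p_adj > 0.99))
  expect_equal(unique(mv$pairwise$mean_diff), 0)
})

test_that("membership model reports exp(B), Wald p, and honors the reference class", {
  set.seed(8)
  n <- 300
  cls <- sample(c("goal", "immersion", "reward"), n, replace = TRUE)
  x <- stats::rnorm(n) + 1.2 * (cls == "goal") - 0.8 * (cls == "immersion")
  age <- factor(sample(c("18-22", "23-35"), n, replace = TRUE),
                levels = c("23-35", "18-22"))
  m <- fit_membership_model(cls, data.frame(drive = x, age = age),
                            reference_class = "reward")
  expect_identical(m$class_labels[1L], "reward")
  expect_identical(rownames(m$coefficients), c("goal", "immersion"))
  expect_equal(m$exp_b, exp(m$coefficients))
  expect_true(all(m$p_value >= 0 & m$p_value <= 1))
  expect_gt(m$coefficients["goal", "drive"], 0)
  expect_lt(m$coefficients["immersion", "drive"], 0)
})

test_that("intercept-only membership model returns the observed shares", {
  cls <- rep(c("a", "b", "c"), c(50, 30, 20))
  m <- fit_membership_model(cls, data.frame(row.names = seq_len(100)),
                            reference_class = "a")
  pr <- predict_membership(m, data.frame(row.names = 1L))
  expect_equal(unname(pr$probabilities[1L, c("a", "b", "c")]),
               c(0.5, 0.3, 0.2), tolerance = 1e-4)
})

test_that("prediction is the softmax of the linear predictors and sums to one", {
  set.seed(12)
  cls <- sample(c("a", "b"), 120, replace = TRUE)
  x <- stats::rnorm(120) + (cls == "b")
  m <- fit_membership_model(cls, data.frame(x = x), reference_class = "a")
  nd <- data.frame(x = c(-1, 0, 2.5))
  pr <- predict_membership(m, nd)
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, 3), tolerance = 1e-12)
  # closed-form two-class check
  b <- m$coefficients[1L, ]
  eta <- b["(Intercept)"] + b["x"] * nd$x
  expect_equal(unname(pr$probabilities[, "b"]),
               unname(1 / (1 + exp(-eta))), tolerance = 1e-10)
  expect_error(predict_membership(m, data.frame(z = 1)), "missing predictor")
})

test_that("declared covariate effects are recovered across seeded replicates", {
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 250
    cls <- sample(c("ref", "s2", "s3"), n, replace = TRUE)
    x1 <- stats::rnorm(n, mean = ifelse(cls == "s2", 0.9, 0))
    x2 <- stats::rnorm(n, mean = ifelse(cls == "s3", -0.9, 0))
    m <- fit_membership_model(cls, data.frame(x1 = x1, x2 = x2),
                              reference_class = "ref")
    ok <- m$coefficients["s2", "x1"] > 0 && m$p_value["s2", "x1"] < 0.05 &&
      m$coefficients["s3", "x2"] < 0 && m$p_value["s3", "x2"] < 0.05
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("rank-deficient predictor sets are rejected naming the columns", {
  cls <- rep(c("a", "b"), each = 20)
  x <- stats::rnorm(40)
  expect_error(fit_membership_model(cls, data.frame(x = x, x2 = 2 * x)),
               "collinear")
})

test_that("membership models survive a JSON round trip for prediction", {
  set.seed(2)
  cls <- sample(c("a", "b", "c"), 200, replace = TRUE)
  x <- stats::rnorm(200) + (cls == "b")
  grp <- factor(sample(c("lo", "hi"), 200, replace = TRUE))
  m <- fit_membership_model(cls, data.frame(x = x, grp = grp),
                            reference_class = "a")
  path <- withr::local_tempfile(fileext = ".json")
  write_membership_model(m, path)
  m2 <- read_membership_model(path)
  nd <- data.frame(x = c(0, 1), grp = factor(c("lo", "hi"), levels = levels(grp)))
  expect_equal(predict_membership(m2, nd)$probabilities,
               predict_membership(m, nd)$probabilities, tolerance = 1e-10)
})
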