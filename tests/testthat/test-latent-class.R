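test_that("one-class latent fit equals the aggregate logit", {
  d <- small_design()
  pop <- homogeneous_pop(d, n = 60, seed = 13)
  obs <- explode_tasks(pop$responses)
  m1 <- fit_latent_class(obs, 1)
  fa <- fit_aggregate(obs)
  expect_equal(m1$loglik, fa$loglik, tolerance = 1e-6)
  expect_equal(unname(m1$class_utilities[, 1L]), unname(fa$utilities),
               tolerance = 1e-6)
  expect_equal(m1$n_params, d$spec$n_items - 1L)
})

test_that("EM recovers a well-separated two-class structure", {
  d <- small_design(K = 6, a = 3, Tn = 8, V = 4)
  u1 <- c(1.5, 1, 0.5, -0.5, -1, -1.5)
  u2 <- rev(u1)
  pop <- simulate_population(
    population_spec(150, c(0.6, 0.4), cbind(u1, u2), sigma = 0.3, seed = 5),
    d)
  obs <- explode_tasks(pop$responses)
  m <- fit_latent_class(obs, 2, n_restarts = 6, seed = 9)
  expect_equal(rowSums(m$posterior), rep(1, 150), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(m$shares), 1, tolerance = 1e-9)
  expect_true(all(diff(m$shares) <= 0))      # ordered by share
  perm <- align_classes(m$class_utilities, cbind(u1, u2))
  expect_true(all(attr(perm, "correlations") > 0.95))
  expect_lt(max(abs(m$shares[perm] - c(0.6, 0.4))), 0.07)
  est <- assign_segments(m)$segment
  expect_gt(mean(est == perm[pop$true_classes]), 0.9)
})

test_that("likelihood is monotone over class counts and posteriors stay proper", {
  d <- small_design(K = 6, a = 3, Tn = 6, V = 4)
  pop <- simulate_population(
    population_spec(80, c(0.5, 0.5),
                    cbind(c(1, .6, .2, -.2, -.6, -1),
                          c(-1, -.6, -.2, .2, .6, 1)),
                    sigma = 0.3, seed = 8),
    d)
  obs <- explode_tasks(pop$responses)
  lls <- vapply(1:3, function(C)
    fit_latent_class(obs, C, n_restarts = 4, seed = 2)$loglik, 0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("metric arithmetic follows the stated formulas", {
  fm <- fit_metrics(-5000, n_classes = 3, n_items = 10, n_respondents = 100,
                    n_tasks = 8, items_per_task = 4)
  k <- 3 * 9 + 2
  N <- 100 * 8 * 2
  ll0 <- -N * log(4)
  expect_equal(fm$n_params, k)
  expect_equal(fm$aic, 10000 + 2 * k)
  expect_equal(fm$bic, 10000 + k * log(N))
  expect_equal(fm$caic, 10000 + k * (log(N) + 1))
  expect_equal(fm$abic, 10000 + k * log((N + 2) / 24))
  expect_equal(fm$chi_square, 2 * (-5000 - ll0))
  expect_equal(fm$relative_chi_square, fm$chi_square / k)
  expect_equal(fm$percentage_certainty, 100 * (1 - 5000 / -ll0))
  # chance-level fit scores zero evidence
  fm0 <- fit_metrics(ll0, 2, 10, 100, 8, 4)
  expect_equal(fm0$chi_square, 0)
  expect_equal(fm0$percentage_certainty, 0)
})

test_that("class scan tabulates one row per class count and chance data show no structure", {
  d <- small_design(K = 6, a = 3, Tn = 6, V = 4)
  pop <- simulate_population(
    population_spec(80, 1, class_utilities = matrix(0, 6), sigma = 0,
                    seed = 17),
    d)
  obs <- explode_tasks(pop$responses)
  sc <- model_scan(obs, n_tasks = 6, class_range = 1:2, n_restarts = 3,
                   seed = 4, restart_iter = 15, max_iter = 60)
  expect_equal(nrow(sc$metrics), 2L)
  # a one-class fit on chance data carries no structure; a two-class EM can
  # chase respondent noise for a small overfitting gain only
  expect_lt(sc$metrics$percentage_certainty[1L], 0.5)
  expect_lt(max(sc$metrics$percentage_certainty), 3)
  expect_equal(sc$sizes[[1L]]$n, 80)
})

test_that("modal assignment breaks ties toward the lower class", {
  m <- structure(list(n_classes = 2L, shares = c(0.5, 0.5),
                      posterior = matrix(c(0.5, 0.7, 0.5, 0.3), 2, 2,
                                         dimnames = list(c("a", "b"), NULL))),
                 class = "maxdiff_lc_model")
  asg <- assign_segments(m)
  expect_identical(asg$segment, c(1L, 1L))
  expect_equal(attr(asg, "sizes")$percent, c(100, 0))
})
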