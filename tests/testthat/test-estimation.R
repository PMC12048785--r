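test_that("uninformative (uniform-choice) data give near-zero utilities and the chance LL", {
  d <- small_design(K = 6, a = 3, Tn = 6, V = 4)
  pop <- simulate_population(
    population_spec(200, 1, class_utilities = matrix(0, 6), sigma = 0,
                    seed = 31),
    d)
  obs <- explode_tasks(pop$responses)
  fit <- fit_aggregate(obs)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$utilities)), 0.12)
  expect_gte(fit$loglik, fit$null_loglik)
  expect_lt(fit$loglik - fit$null_loglik, 30)   # chance-level fit
})

test_that("two-item symmetric-swap tasks give antisymmetric utilities", {
  d <- generate_design(design_spec(2, 2, 2, 1, seed = 1))
  # item 1 chosen best and item 2 worst in every task, for two respondents
  recs <- expand.grid(respondent_id = c("a", "b"), task = 1:2)
  recs$version <- 1L; recs$best <- 1L; recs$worst <- 2L
  rs <- response_set(recs, d)
  fit <- suppressWarnings(fit_aggregate(explode_tasks(rs), ridge = 1e-2))
  expect_equal(unname(fit$utilities[1L]), -unname(fit$utilities[2L]),
               tolerance = 1e-8)
  expect_gt(fit$utilities[1L], 0)
})

test_that("estimates recover known utilities within sampling error", {
  d <- paper_scale_design(V = 30)
  u <- scenario_score_tables()$preference3[, "goal"]
  u <- invert_rescaled(100 * u / sum(u), a = 4)$utilities
  pop <- simulate_population(
    population_spec(378, 1, class_utilities = matrix(u, 16), sigma = 0,
                    seed = 101),
    d)
  fit <- fit_aggregate(explode_tasks(pop$responses))
  z <- abs(fit$utilities - u) / fit$se
  expect_lt(max(z), 3)
  expect_gt(stats::cor(fit$utilities, u), 0.995)
})

test_that("fit is equivariant under item relabeling", {
  d <- small_design(K = 6, a = 3, Tn = 6, V = 3)
  pop <- homogeneous_pop(d, n = 60, seed = 44)
  obs <- explode_tasks(pop$responses)
  fit <- fit_aggregate(obs)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)          # relabel item i -> perm[i]
  obs2 <- obs
  obs2$sets <- matrix(perm[obs$sets], nrow(obs$sets))
  fit2 <- fit_aggregate(obs2)
  expect_equal(unname(fit2$utilities[perm]), unname(fit$utilities),
               tolerance = 1e-6)
})

test_that("complete separation triggers a ridge-stabilized warning fit", {
  d <- generate_design(design_spec(4, 4, 2, 1, seed = 5))
  recs <- data.frame(respondent_id = rep(c("a", "b"), each = 2),
                     version = 1L, task = rep(1:2, 2),
                     best = 1L, worst = 2L)
  rs <- response_set(recs, d)
  expect_warning(fit <- fit_aggregate(explode_tasks(rs)), "separation")
  expect_true(all(is.finite(fit$utilities)))
})

test_that("rescaled scores sum to 100, preserve order, and invert exactly", {
  set.seed(7)
  for (method in c("probability", "softmax")) {
    for (rep in 1:20) {
      u <- stats::rnorm(12, sd = 1.5)
      u <- u - mean(u)
      s <- rescale_scores(u, a = 4, method = method)
      expect_equal(sum(s$scores), 100, tolerance = 1e-9)
      expect_true(all(s$scores > 0))
      expect_identical(order(s$scores), order(u))   # strictly monotone
      u2 <- invert_rescaled(s)
      expect_equal(unname(u2$utilities), unname(u), tolerance = 1e-8)
    }
  }
  # flat utilities spread the budget evenly
  s0 <- rescale_scores(rep(0, 16), a = 4)
  expect_equal(unname(s0$scores), rep(6.25, 16))
  expect_equal(unname(invert_rescaled(s0)$utilities), rep(0, 16),
               tolerance = 1e-8)
})

test_that("degenerate rescaling inputs are rejected", {
  expect_error(rescale_scores(c(0.5, -0.5), a = 1), ">= 2")
  expect_error(invert_rescaled(c(0, 100), a = 4), "positive")
  expect_error(invert_rescaled(c(40, 50), a = 4), "sum to 100")
})

test_that("ranking follows competition convention with ties", {
  expect_identical(rank_items(c(3, 2, 2, 1)), c(1L, 2L, 2L, 4L))
  expect_identical(rank_items(rep(5, 4)), rep(1L, 4))
  s <- rescale_scores(c(1, 0, -1), a = 3)
  expect_identical(unname(rank_items(s)), c(1L, 2L, 3L))
})

test_that("utility tables carry item, score and rank columns consistently", {
  d <- small_design()
  pop <- homogeneous_pop(d, n = 40, seed = 3)
  fit <- fit_aggregate(explode_tasks(pop$responses))
  tab <- utility_table(fit, a = d$spec$items_per_task)
  expect_named(tab, c("item", "utility", "se", "score", "rank"))
  expect_equal(sum(tab$score), 100, tolerance = 1e-9)
  expect_identical(tab$rank[which.max(tab$score)], 1L)
})
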