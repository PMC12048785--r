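test_that("population specs validate shares, utilities, and covariate blocks", {
  expect_error(population_spec(10, c(0.5, 0.6), matrix(0, 4, 2)), "sum to 1")
  expect_error(population_spec(10, 1, matrix(c(1, 1, 1, 1))), "sum to zero")
  expect_error(population_spec(10, 1, matrix(0, 4), sigma = -1), "sigma")
  expect_error(population_spec(10, c(.5, .5), matrix(0, 4, 2),
                               covariates = list(x = list(type = "numeric",
                                                          mean = 1, sd = 1))),
               "one value per class")
  expect_error(population_spec(10, 1, class_scores = matrix(c(0, 40, 60)),
                               items_per_task = 3),
               "positive")
})

test_that("same seed reproduces the population byte for byte", {
  d <- small_design()
  spec <- population_spec(25, c(0.5, 0.5),
                          cbind(c(1, .5, 0, 0, -.5, -1),
                                c(-1, -.5, 0, 0, .5, 1)),
                          sigma = 0.4,
                          covariates = list(
                            score = list(type = "numeric", mean = c(5, 4),
                                         sd = c(1, 1)),
                            band = list(type = "categorical",
                                        levels = c("lo", "hi"),
                                        probs = rbind(c(.7, .3), c(.3, .7)))),
                          seed = 77)
  p1 <- simulate_population(spec, d)
  p2 <- simulate_population(spec, d)
  expect_identical(p1$responses$records, p2$responses$records)
  expect_identical(p1$responses$covariates, p2$responses$covariates)
  expect_identical(p1$true_utilities, p2$true_utilities)
  p3 <- simulate_population(spec, d, seed = 78)
  expect_false(identical(p1$responses$records, p3$responses$records))
})

test_that("simulated records satisfy the response invariants by construction", {
  d <- small_design()
  pop <- homogeneous_pop(d, n = 30, sigma = 0.5, seed = 9)
  rec <- pop$responses$records
  expect_true(all(rec$best != rec$worst))
  expect_equal(nrow(rec), 30 * d$spec$n_tasks)
  # versions assigned round-robin
  expect_identical(unique(rec$version[rec$respondent_id == "r0001"]), 1L)
  expect_identical(unique(rec$version[rec$respondent_id == "r0006"]), 1L)
})

test_that("choice frequencies converge to the exploded-logit expectations", {
  # single task shown many times: empirical best shares vs softmax(u)
  d <- generate_design(design_spec(4, 4, 1, 1, seed = 2))
  u <- c(1, 0.2, -0.4, -0.8); u <- u - mean(u)
  pop <- simulate_population(
    population_spec(5000, 1, class_utilities = matrix(u, 4), sigma = 0,
                    seed = 55),
    d)
  rec <- pop$responses$records
  p_best <- tabulate(rec$best, 4) / nrow(rec)
  expect_lt(max(abs(p_best - exp(u) / sum(exp(u)))), 0.02)
  p_worst <- tabulate(rec$worst, 4) / nrow(rec)
  expect_lt(max(abs(p_worst - exp(-u) / sum(exp(-u)))), 0.02)
  expect_true(all(rec$best != rec$worst))
})

test_that("class-conditional covariates carry the declared group differences", {
  d <- small_design()
  spec <- population_spec(600, c(0.5, 0.5),
                          cbind(c(1, .5, 0, 0, -.5, -1),
                                c(-1, -.5, 0, 0, .5, 1)),
                          sigma = 0,
                          covariates = list(
                            drive = list(type = "numeric", mean = c(5.8, 4.8),
                                         sd = c(0.9, 0.9)),
                            age = list(type = "categorical",
                                       levels = c("18-22", "23-35"),
                                       probs = rbind(c(.7, .3), c(.3, .7)))),
                          seed = 3)
  pop <- simulate_population(spec, d)
  cov <- pop$responses$covariates
  cls <- pop$true_classes
  expect_gt(mean(cov$drive[cls == 1]) - mean(cov$drive[cls == 2]), 0.6)
  expect_gt(mean(cov$age[cls == 1] == "18-22"), 0.6)
  expect_lt(mean(cov$age[cls == 2] == "18-22"), 0.4)
})

test_that("built-in scenarios match their declared shares and score tables", {
  sc <- builtin_scenarios()
  expect_named(sc, c("preference3", "motivation4"))
  expect_equal(sc$preference3$class_shares, c(0.426, 0.299, 0.275))
  expect_equal(sc$motivation4$class_shares, c(0.209, 0.339, 0.169, 0.283))
  tabs <- scenario_score_tables()
  for (nm in names(sc)) {
    spec <- sc[[nm]]
    expect_equal(length(spec$class_shares), ncol(tabs[[nm]]))
    # utilities rescale back to the published-style score columns
    for (c in seq_along(spec$class_shares)) {
      back <- rescale_scores(spec$class_utilities[, c], a = 4)$scores
      expect_equal(unname(back), unname(100 * tabs[[nm]][, c] / sum(tabs[[nm]][, c])),
                   tolerance = 1e-8)
      expect_lt(max(abs(back - tabs[[nm]][, c])), 0.01)
    }
    expect_lt(max(abs(colSums(spec$class_utilities))), 1e-8)
  }
})

test_that("end-to-end recovery: simulate, segment, and re-find covariate effects", {
  d <- paper_scale_design(V = 20)
  sc <- builtin_scenarios(n_respondents = 250, seed = 41)
  pop <- simulate_population(sc$preference3, d)
  obs <- explode_tasks(pop$responses)
  m <- fit_latent_class(obs, 3, n_restarts = 5, seed = 6)
  asg <- assign_segments(m)
  cov <- pop$responses$covariates
  cov <- cov[match(asg$respondent_id, cov$respondent_id), ]
  perm <- align_classes(m$class_utilities, sc$preference3$class_utilities)
  # relabel estimated segments into true-class order before profiling
  seg_true_order <- match(asg$segment, perm)
  mm <- fit_membership_model(factor(seg_true_order),
                             data.frame(achievement = cov$achievement_driven),
                             reference_class = "3")
  # the goal-preferred class (1) has the highest achievement-driven mean
  expect_gt(mm$coefficients["1", "achievement"], 0)
})
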