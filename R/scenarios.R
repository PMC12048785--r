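# Built-in simulation scenarios. Both describe gamification-element
# MaxDiff studies on wearable users: 16 game elements, 4 shown per task,
# 12 tasks per respondent, 378 respondents. Segment-level sum-to-100
# scores are inverted to logit utilities; covariate generators reproduce
# segment differences in 7-point Likert measures (Hexad user types and
# gamification-drive dimensions) and in age structure.

gamification_items <- c(
  "Goals", "Progress", "Feedback", "Overview", "Points", "Levels",
  "Badges", "Leaderboards", "Community", "Sharing", "Cooperation",
  "Competition", "Challenges", "Narrative", "Avatars", "Digital currency")

# segment-level rescaled scores (columns sum to 100 up to print rounding)
preference3_scores <- matrix(c(
  # goal-preferred, immersion-preferred, reward-preferred
   9.529,  6.322,  6.175,
  13.977,  9.324,  9.806,
   7.309,  5.761,  5.053,
   8.447,  5.412,  6.240,
   4.058,  4.283, 11.426,
   6.982,  5.470,  6.572,
   7.307,  6.998,  5.825,
   6.704,  3.545,  5.904,
   2.887,  5.026,  4.654,
   6.408,  4.606,  5.373,
   5.891,  6.264,  4.031,
   5.886,  3.882,  3.800,
   9.471,  6.355,  4.703,
   1.545, 14.840,  2.330,
   2.243,  9.823,  4.123,
   1.356,  2.090, 13.986), nrow = 16L, byrow = TRUE,
  dimnames = list(gamification_items,
                  c("goal", "immersion", "reward")))

motivation4_scores <- matrix(c(
  # goal-, immersion-, reward-, socially-motivated
  13.981,  6.214,  6.983, 10.171,
  15.228,  9.572,  9.754, 13.171,
   6.265,  3.058,  1.787,  2.192,
  11.360,  6.147,  5.569,  9.563,
   7.241,  5.809, 12.106,  3.630,
   9.009,  5.670,  7.141,  4.886,
   9.969,  8.069,  5.163,  4.611,
   2.077,  5.151,  9.086, 11.231,
   1.354,  4.007,  4.408,  1.687,
   1.958,  4.804,  5.256,  8.021,
   3.418,  8.210,  5.913,  9.746,
   1.569,  5.914,  7.101, 11.225,
   9.384,  4.423,  4.363,  6.699,
   0.847, 13.031,  0.658,  0.676,
   2.510,  5.225,  1.605,  1.132,
   3.830,  4.695, 13.108,  1.359), nrow = 16L, byrow = TRUE,
  dimnames = list(gamification_items,
                  c("goal", "immersion", "reward", "social")))

num_cov <- function(mean, sd) list(type = "numeric", mean = mean, sd = sd)
cat_cov <- function(levels, probs) list(type = "categorical", levels = levels,
                                        probs = probs)

# class-conditional 7-point scale means/SDs by segment (order matches the
# score matrix columns); age-group splits chosen to reproduce the reported
# concentration of older users in the reward segments
preference3_covariates <- list(
  philanthropist = num_cov(c(5.23, 4.94, 4.76), c(0.837, 0.936, 0.940)),
  socializer = num_cov(c(4.89, 4.45, 4.63), c(1.031, 1.163, 0.974)),
  free_spirit = num_cov(c(5.64, 5.39, 5.34), c(0.645, 0.795, 0.918)),
  achiever = num_cov(c(5.56, 5.05, 5.01), c(0.691, 0.855, 0.936)),
  goal_driven = num_cov(c(5.93, 5.52, 5.43), c(0.778, 0.892, 1.084)),
  achievement_driven = num_cov(c(5.87, 5.26, 5.19), c(0.826, 0.894, 1.084)),
  socialization_driven = num_cov(c(5.23, 4.89, 4.91), c(1.126, 1.118, 1.218)),
  immersion_driven = num_cov(c(4.89, 5.59, 5.01), c(1.076, 1.110, 1.179)),
  age_group = cat_cov(c("18-22", "23-35"),
                      matrix(c(0.55, 0.45,
                               0.50, 0.50,
                               0.31, 0.69), 3L, byrow = TRUE)))

motivation4_covariates <- list(
  socializer = num_cov(c(4.44, 4.53, 4.92, 4.93), c(0.954, 1.156, 0.873, 1.090)),
  free_spirit = num_cov(c(5.60, 5.34, 5.39, 5.62), c(0.795, 0.788, 0.870, 0.677)),
  achiever = num_cov(c(5.20, 5.03, 5.24, 5.58), c(0.914, 0.839, 0.917, 0.682)),
  goal_driven = num_cov(c(5.79, 5.41, 5.68, 5.89), c(0.949, 0.938, 1.021, 0.774)),
  achievement_driven = num_cov(c(5.58, 5.18, 5.46, 5.85), c(1.020, 0.980, 0.989, 0.796)),
  socialization_driven = num_cov(c(4.90, 4.85, 5.11, 5.33), c(1.197, 1.196, 1.121, 1.055)),
  immersion_driven = num_cov(c(4.92, 5.49, 5.05, 4.91), c(1.321, 1.101, 1.101, 1.012)),
  age_group = cat_cov(c("18-22", "23-35"),
                      matrix(c(0.50, 0.50,
                               0.50, 0.50,
                               0.33, 0.67,
                               0.65, 0.35), 4L, byrow = TRUE)),
  exercise_interest = cat_cov(c("hardly", "general", "enthusiast"),
                              matrix(c(0.30, 0.40, 0.30,
                                       0.50, 0.35, 0.15,
                                       0.35, 0.40, 0.25,
                                       0.20, 0.40, 0.40), 4L, byrow = TRUE)))

#' Built-in simulation scenarios
#'
#' Ready-made [population_spec()]s for gamification MaxDiff studies of
#' wearable-device users (16 game elements, 4 per task, 12 tasks, 378
#' respondents):
#' \describe{
#'   \item{preference3}{three preference segments (goal-, immersion-,
#'     reward-preferred) with shares 42.6/29.9/27.5\% and segment-level
#'     sum-to-100 preference scores; covariates cover the six Hexad user
#'     types, four gamification-drive dimensions (7-point scales) and an
#'     age-group split.}
#'   \item{motivation4}{four motivation segments (goal-, immersion-,
#'     reward-, socially motivated) with shares 20.9/33.9/16.9/28.3\%,
#'     plus an exercise-interest covariate.}
#' }
#' Segment scores are converted to logit utilities by [invert_rescaled()];
#' within-class heterogeneity defaults to \code{sigma = 0.5}.
#'
#' @param n_respondents sample size (default 378).
#' @param sigma within-class utility heterogeneity (default 0.5).
#' @param seed seed stored in the specs.
#' @return named list of \code{maxdiff_population_spec} objects.
#' @examples
#' sc <- builtin_scenarios()
#' sc$preference3$class_shares
#' @export
builtin_scenarios <- function(n_respondents = 378L, sigma = 0.5, seed = 1L) {
  list(
    preference3 = population_spec(
      n_respondents = n_respondents,
      class_shares = c(0.426, 0.299, 0.275),
      class_scores = 100 * sweep(preference3_scores, 2L,
                                 colSums(preference3_scores), `/`),
      items_per_task = 4L, sigma = sigma,
      covariates = preference3_covariates,
      class_names = c("goal-preferred", "immersion-preferred",
                      "reward-preferred"),
      seed = seed),
    motivation4 = population_spec(
      n_respondents = n_respondents,
      class_shares = c(0.209, 0.339, 0.169, 0.283),
      class_scores = 100 * sweep(motivation4_scores, 2L,
                                 colSums(motivation4_scores), `/`),
      items_per_task = 4L, sigma = sigma,
      covariates = motivation4_covariates,
      class_names = c("goal-motivated", "immersion-motivated",
                      "reward-motivated", "socially-motivated"),
      seed = seed))
}

#' Segment-level score tables of the built-in scenarios
#'
#' The raw sum-to-100 score matrices behind [builtin_scenarios()] (one
#' column per segment; columns sum to 100 up to 3-decimal print rounding).
#'
#' @return named list of two matrices, \code{preference3} (16 x 3) and
#'   \code{motivation4} (16 x 4).
#' @export
scenario_score_tables <- function() {
  list(preference3 = preference3_scores, motivation4 = motivation4_scores)
}
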