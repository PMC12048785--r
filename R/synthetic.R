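# Synthetic respondent generator. Emulates the data-generating process the
# whole pipeline assumes: latent classes with fixed shares, class-level
# sum-to-zero utilities, isotropic normal individual heterogeneity on the
# utility scale, exploded-logit best/worst choices, and class-conditional
# covariates. Every pipeline stage can thereby be exercised and validated
# by parameter recovery.

# Joint distribution of (best, worst) with zero diagonal whose margins are
# exactly softmax(u) for the best pick and softmax(-u) for the worst pick,
# by Sinkhorn scaling of the product coupling. Such a coupling always
# exists: p_best_i + p_worst_i <= 1 reduces to
# (sum_{j!=i} e^{u_j})(sum_{j!=i} e^{-u_j}) >= (a-1)^2 >= 1 (Cauchy-Schwarz).
# Sampling the pair from it keeps best != worst in every record while the
# exploded-logit estimator stays exactly unbiased (its score only involves
# the two margins).
bw_coupling <- function(pb, pw, tol = 1e-12, max_iter = 500L) {
  a <- length(pb)
  M <- outer(pb, pw)
  diag(M) <- 0
  for (it in seq_len(max_iter)) {
    M <- M * (pb / rowSums(M))
    M <- t(t(M) * (pw / colSums(M)))
    if (max(abs(rowSums(M) - pb)) < tol) break
  }
  M
}

#' Specify a synthetic respondent population
#'
#' @param n_respondents number of respondents to simulate.
#' @param class_shares class probabilities (length C, summing to 1; a
#'   single 1 gives a homogeneous population).
#' @param class_utilities K x C matrix of sum-to-zero class utilities
#'   (one column per class). Alternatively supply \code{class_scores}.
#' @param class_scores K x C matrix of rescaled scores (columns summing to
#'   100) to be inverted via [invert_rescaled()]; requires
#'   \code{items_per_task}.
#' @param sigma within-class heterogeneity: standard deviation of the
#'   isotropic normal perturbation added to the class utilities on the
#'   logit scale (default 0.5).
#' @param covariates named list of class-conditional covariate generators.
#'   Numeric: \code{list(type = "numeric", mean = <C values>, sd = <C
#'   values>)}. Categorical: \code{list(type = "categorical", levels =
#'   <labels>, probs = <C x L matrix, rows summing to 1>)}.
#' @param items_per_task needed only to invert \code{class_scores}.
#' @param class_names optional class labels.
#' @param seed integer seed used by [simulate_population()].
#' @return an object of class \code{maxdiff_population_spec}.
#' @seealso [simulate_population()], [builtin_scenarios()]
#' @export
population_spec <- function(n_respondents, class_shares, class_utilities = NULL,
                            class_scores = NULL, sigma = 0.5,
                            covariates = list(), items_per_task = NULL,
                            class_names = NULL, seed = 1L) {
  class_shares <- as.numeric(class_shares)
  if (any(class_shares < 0) || abs(sum(class_shares) - 1) > 1e-6)
    stopf("class_shares must be nonnegative and sum to 1")
  C <- length(class_shares)
  if (sigma < 0) stopf("sigma must be >= 0")
  if (is.null(class_utilities)) {
    if (is.null(class_scores)) stopf("supply class_utilities or class_scores")
    class_scores <- as.matrix(class_scores)
    if (ncol(class_scores) != C) stopf("class_scores needs one column per class")
    if (is.null(items_per_task)) stopf("items_per_task is required to invert scores")
    class_utilities <- apply(class_scores, 2L, function(s)
      invert_rescaled(s, a = items_per_task)$utilities)
  }
  class_utilities <- as.matrix(class_utilities)
  if (ncol(class_utilities) != C) stopf("class_utilities needs one column per class")
  if (any(abs(colSums(class_utilities)) > 1e-6))
    stopf("class utility columns must sum to zero")
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!cv$type %in% c("numeric", "categorical"))
      stopf("covariate '%s': type must be numeric or categorical", nm)
    if (cv$type == "numeric" &&
        (length(cv$mean) != C || length(cv$sd) != C))
      stopf("covariate '%s': mean and sd need one value per class", nm)
    if (cv$type == "categorical") {
      pr <- as.matrix(cv$probs)
      if (nrow(pr) != C || ncol(pr) != length(cv$levels) ||
          any(abs(rowSums(pr) - 1) > 1e-6))
        stopf("covariate '%s': probs must be C x n_levels with rows summing to 1", nm)
    }
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 class_shares = class_shares,
                 class_utilities = class_utilities,
                 sigma = sigma, covariates = covariates,
                 class_names = class_names %||% paste0("class", seq_len(C)),
                 seed = as.integer(seed)),
            class = "maxdiff_population_spec")
}

#' Simulate a synthetic respondent population
#'
#' Draws a population from a [population_spec()] against a design:
#' each respondent gets a class from the share distribution, individual
#' utilities \code{beta = u_class + eps} with \code{eps ~ N(0, sigma^2 I)}
#' re-centered to sum to zero, and a questionnaire version assigned
#' round-robin. For every task the (best, worst) pair is drawn from a
#' zero-diagonal coupling whose margins are exactly \code{softmax(beta)}
#' for the best pick and \code{softmax(-beta)} for the worst pick over the
#' shown items: records always satisfy best != worst, yet the
#' exploded-logit estimator remains exactly unbiased because its score
#' depends only on the two margins. Covariates are drawn from the
#' class-conditional generators. Fully reproducible for a fixed seed.
#'
#' @param spec a \code{maxdiff_population_spec}.
#' @param design a \code{maxdiff_design} with matching \code{n_items}.
#' @param seed overrides \code{spec$seed} if given.
#' @return an object of class \code{maxdiff_population}: \code{responses}
#'   (a \code{maxdiff_responses} with any covariates attached),
#'   \code{true_classes} (integer vector), \code{true_utilities} (R x K),
#'   \code{spec}.
#' @export
simulate_population <- function(spec, design, seed = NULL) {
  stopifnot(inherits(spec, "maxdiff_population_spec"),
            inherits(design, "maxdiff_design"))
  sp <- design$spec
  K <- nrow(spec$class_utilities)
  if (K != sp$n_items)
    stopf("spec has %d items but design has %d", K, sp$n_items)
  R <- spec$n_respondents
  C <- length(spec$class_shares)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %||% spec$seed)

  cls <- sample.int(C, R, replace = TRUE, prob = spec$class_shares)
  beta <- t(spec$class_utilities[, cls, drop = FALSE])
  if (spec$sigma > 0) {
    eps <- matrix(stats::rnorm(R * K, sd = spec$sigma), R, K)
    eps <- eps - rowMeans(eps)
    beta <- beta + eps
  }
  ids <- sprintf("r%04d", seq_len(R))
  versions <- ((seq_len(R) - 1L) %% sp$n_versions) + 1L

  nrec <- R * sp$n_tasks
  rec <- data.frame(respondent_id = rep(ids, each = sp$n_tasks),
                    version = rep(versions, each = sp$n_tasks),
                    task = rep(seq_len(sp$n_tasks), R),
                    best = 0L, worst = 0L)
  k <- 0L
  for (r in seq_len(R)) {
    tasks <- design$versions[[versions[r]]]
    b <- beta[r, ]
    for (t in seq_len(sp$n_tasks)) {
      k <- k + 1L
      s <- tasks[t, ]
      a <- length(s)
      M <- bw_coupling(softmax(b[s]), softmax(-b[s]))
      pick <- sample.int(a * a, 1L, prob = as.vector(M))
      rec$best[k] <- s[(pick - 1L) %% a + 1L]
      rec$worst[k] <- s[(pick - 1L) %/% a + 1L]
    }
  }

  cov_df <- NULL
  if (length(spec$covariates)) {
    cov_df <- data.frame(respondent_id = ids)
    for (nm in names(spec$covariates)) {
      cv <- spec$covariates[[nm]]
      if (cv$type == "numeric") {
        cov_df[[nm]] <- stats::rnorm(R, mean = cv$mean[cls], sd = cv$sd[cls])
      } else {
        pr <- as.matrix(cv$probs)
        cov_df[[nm]] <- vapply(cls, function(c)
          sample(cv$levels, 1L, prob = pr[c, ]), character(1))
      }
    }
  }
  rs <- response_set(rec, design, covariates = cov_df)
  dimnames(beta) <- list(ids, sp$items)
  structure(list(responses = rs, true_classes = cls,
                 true_utilities = beta, spec = spec),
            class = "maxdiff_population")
}

#' @export
print.maxdiff_population <- function(x, ...) {
  cat(sprintf("Synthetic MaxDiff population: %d respondents, %d classes (sigma = %g)\n",
              x$spec$n_respondents, length(x$spec$class_shares), x$spec$sigma))
  invisible(x)
}

#' Align estimated classes with true classes
#'
#' Latent-class labels are arbitrary; this finds the permutation of the
#' estimated classes that maximizes the summed correlation between
#' estimated and true class utility vectors (exhaustive over permutations,
#' fine for the small class counts used here).
#'
#' @param est_util K x C matrix of estimated class utilities.
#' @param true_util K x C matrix of true class utilities.
#' @return integer permutation \code{perm} such that estimated class
#'   \code{perm[c]} corresponds to true class \code{c}, with attribute
#'   \code{"correlations"} (per-class Pearson r after alignment).
#' @export
align_classes <- function(est_util, true_util) {
  C <- ncol(true_util)
  stopifnot(ncol(est_util) == C)
  cors <- stats::cor(est_util, true_util)   # est x true
  perms <- all_permutations(C)
  sc <- vapply(seq_len(nrow(perms)), function(i)
    sum(cors[cbind(perms[i, ], seq_len(C))]), 0)
  best <- perms[which.max(sc), ]
  structure(best, correlations = cors[cbind(best, seq_len(C))])
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
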