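# Exploded-logit likelihood machinery.
#
# An observation is (shown set S, chosen item c, sign s): the choice
# probability is exp(s*u_c) / sum_{j in S} exp(s*u_j). Best picks have
# s = +1, worst picks s = -1 (one shared utility vector). The pooled
# log-likelihood is concave in u, and u is identified by sum(u) = 0.

# per-observation log-probabilities under utilities u
exploded_logp <- function(u, obs) {
  eta <- matrix(u[obs$sets], nrow(obs$sets)) * obs$sign
  lse <- row_logsumexp(eta)
  eta[cbind(seq_len(nrow(eta)), obs$choice_col)] - lse
}

# log-likelihood, gradient (length K) and negative Hessian (K x K) with
# observation weights w
exploded_deriv <- function(u, obs, w, hessian = TRUE) {
  n <- nrow(obs$sets); K <- obs$n_items
  eta <- matrix(u[obs$sets], n) * obs$sign
  mx <- do.call(pmax, as.data.frame(eta))
  ex <- exp(eta - mx)
  denom <- rowSums(ex)
  p <- ex / denom
  ll <- sum(w * (eta[cbind(seq_len(n), obs$choice_col)] - (log(denom) + mx)))

  ws <- w * obs$sign
  g <- numeric(K)
  gc <- rowsum(ws, obs$sets[cbind(seq_len(n), obs$choice_col)])
  g[as.integer(rownames(gc))] <- gc
  gs <- rowsum(as.vector(p) * rep(ws, ncol(p)), as.vector(obs$sets))
  g[as.integer(rownames(gs))] <- g[as.integer(rownames(gs))] - gs

  H <- NULL
  if (hessian) {
    # negative Hessian A = sum_i w_i (diag(p_S) - p_S p_S') over the shown set
    d <- numeric(K)
    dd <- rowsum(as.vector(p) * rep(w, ncol(p)), as.vector(obs$sets))
    d[as.integer(rownames(dd))] <- dd
    X <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(p)),
                              j = as.vector(obs$sets),
                              x = as.vector(p) * rep(sqrt(w), ncol(p)),
                              dims = c(n, K))
    H <- diag(d) - as.matrix(Matrix::crossprod(X))
  }
  list(ll = ll, grad = g, neg_hessian = H, prob = p)
}

# detect complete separation: an item that is chosen every time (or never)
# it is shown, pooling best evidence and reversed worst evidence
detect_separation <- function(obs) {
  K <- obs$n_items
  shown_b <- shown_w <- won_b <- won_w <- numeric(K)
  best <- obs$sign > 0
  tb <- tabulate(obs$sets[best, ], nbins = K)
  tw <- tabulate(obs$sets[!best, ], nbins = K)
  cb <- tabulate(obs$sets[cbind(seq_len(nrow(obs$sets)), obs$choice_col)][best], nbins = K)
  cw <- tabulate(obs$sets[cbind(seq_len(nrow(obs$sets)), obs$choice_col)][!best], nbins = K)
  hi <- (tb + tw) > 0 & cb == tb & cw == 0
  lo <- (tb + tw) > 0 & cw == tw & cb == 0
  which(hi | lo)
}

#' Fit the pooled (aggregate) exploded-logit model
#'
#' Maximum-likelihood estimation of one sum-to-zero utility vector from all
#' exploded best-worst observations, by damped Newton iteration on the
#' concave log-likelihood in the K-1 dimensional effects-coded basis.
#' Standard errors come from the observed information.
#'
#' @param obs a \code{maxdiff_choices} object from [explode_tasks()].
#' @param weights optional nonnegative observation weights (used by the
#'   latent-class M-step); default all 1.
#' @param ridge L2 penalty applied when complete separation is detected
#'   (an item always or never chosen when shown); default \code{1e-6}.
#' @param start optional length-K starting utilities.
#' @param tol convergence tolerance on the relative log-likelihood change
#'   (default \code{1e-10}); iteration also stops at gradient norm
#'   \code{< 1e-8}.
#' @param max_iter maximum Newton iterations.
#' @param check_separation set \code{FALSE} to skip the separation scan
#'   (weighted refits).
#' @return an object of class \code{maxdiff_utilities}: \code{utilities}
#'   (named, sum-to-zero), \code{se}, \code{vcov} (K x K, singular by
#'   construction along the constant direction), \code{loglik},
#'   \code{null_loglik}, \code{converged}, \code{n_iter}, \code{n_obs}.
#' @examples
#' spec <- design_spec(6, 3, 4, 5, seed = 2)
#' des <- generate_design(spec)
#' pop <- simulate_population(population_spec(
#'   n_respondents = 50, class_shares = 1,
#'   class_utilities = matrix(c(1, .5, 0, 0, -.5, -1)), sigma = 0, seed = 3), des)
#' fit <- fit_aggregate(explode_tasks(pop$responses))
#' round(fit$utilities, 2)
#' @export
fit_aggregate <- function(obs, weights = NULL, ridge = 1e-6, start = NULL,
                          tol = 1e-10, max_iter = 100L,
                          check_separation = TRUE) {
  stopifnot(inherits(obs, "maxdiff_choices"))
  n <- nrow(obs$sets)
  if (n < 1L) stopf("no observations to fit")
  K <- obs$n_items
  shown <- tabulate(obs$sets, nbins = K)
  if (any(shown == 0L))
    stopf("item(s) never shown in any choice set: %s",
          paste(obs$items[shown == 0L], collapse = ", "))
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0))
    as.numeric(weights)
  }
  pen <- 0
  if (check_separation) {
    sep <- detect_separation(obs)
    if (length(sep)) {
      warnf("complete separation for item(s) %s; applying ridge %g",
            paste(obs$items[sep], collapse = ", "), ridge)
      pen <- ridge
    }
  }
  Z <- effects_basis(K)
  theta <- if (is.null(start)) numeric(K - 1L) else {
    stopifnot(length(start) == K)
    start[-K] - mean(start)
  }
  u <- as.vector(Z %*% theta)
  dv <- exploded_deriv(u, obs, w)
  ll <- dv$ll - pen * sum(u^2) / 2
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gz <- crossprod(Z, dv$grad - pen * u)
    Az <- crossprod(Z, (dv$neg_hessian + diag(pen, K)) %*% Z)
    step <- tryCatch(solve(Az, gz),
                     error = function(e) solve(Az + diag(1e-8, K - 1L), gz))
    lam <- 1
    repeat {
      theta_new <- theta + lam * as.vector(step)
      u_new <- as.vector(Z %*% theta_new)
      dv_new <- exploded_deriv(u_new, obs, w)
      ll_new <- dv_new$ll - pen * sum(u_new^2) / 2
      if (ll_new >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1)
    theta <- theta_new; u <- u_new; dv <- dv_new; ll <- ll_new
    if (sqrt(sum(crossprod(Z, dv$grad - pen * u)^2)) < 1e-8 || rel < tol) {
      converged <- TRUE
      break
    }
  }
  Az <- crossprod(Z, (dv$neg_hessian + diag(pen, K)) %*% Z)
  Vz <- tryCatch(solve(Az), error = function(e) matrix(NA_real_, K - 1L, K - 1L))
  V <- Z %*% Vz %*% t(Z)
  names(u) <- obs$items
  structure(list(utilities = u,
                 se = sqrt(pmax(diag(V), 0)),
                 vcov = V,
                 loglik = dv$ll,
                 null_loglik = -n * log(obs$items_per_task),
                 converged = converged, n_iter = iter, n_obs = n,
                 ridge = pen),
            class = "maxdiff_utilities")
}

#' @export
print.maxdiff_utilities <- function(x, digits = 3, ...) {
  cat(sprintf("Exploded-logit utilities (%d items, LL = %.2f%s)\n",
              length(x$utilities), x$loglik,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$utilities, digits))
  invisible(x)
}

#' Rescale utilities to preference scores summing to 100
#'
#' Transforms logit-scale utilities into nonnegative, ratio-interpretable
#' preference scores that sum to 100 across items. The default
#' "probability" method uses the choice-probability transform
#' \code{q_i = exp(u_i) / (exp(u_i) + a - 1)} (the probability that item i
#' beats a - 1 average items in a task) before normalizing; "softmax"
#' normalizes \code{exp(u_i)} directly. Both are strictly increasing in
#' \code{u_i}, so rankings are method-invariant.
#'
#' @param u a \code{maxdiff_utilities} object or bare numeric utility vector.
#' @param a number of items shown per task (required by the probability
#'   method); taken from the fit when available.
#' @param method "probability" (default) or "softmax".
#' @return an object of class \code{maxdiff_scores}: \code{scores} (named,
#'   summing to 100), \code{items_per_task}, \code{method}.
#' @export
rescale_scores <- function(u, a = NULL, method = c("probability", "softmax")) {
  method <- match.arg(method)
  uv <- if (inherits(u, "maxdiff_utilities")) u$utilities else u
  stopifnot(is.numeric(uv), all(is.finite(uv)))
  if (is.null(a)) stopf("items_per_task 'a' is required")
  if (a < 2) stopf("items_per_task must be >= 2")
  q <- switch(method,
              probability = exp(uv) / (exp(uv) + (a - 1)),
              softmax = exp(uv - max(uv)))
  s <- 100 * q / sum(q)
  names(s) <- names(uv)
  structure(list(scores = s, items_per_task = a, method = method),
            class = "maxdiff_scores")
}

#' @export
print.maxdiff_scores <- function(x, digits = 3, ...) {
  cat(sprintf("Rescaled preference scores (sum 100, method '%s')\n", x$method))
  print(round(x$scores, digits))
  invisible(x)
}

#' Recover utilities from rescaled scores
#'
#' Inverse of [rescale_scores()]: finds the sum-to-zero utility vector whose
#' rescaled scores equal the given ones, under the same method. For the
#' probability method the overall scale of the pre-normalization
#' probabilities is pinned down by root-finding on the sum-to-zero
#' constraint. Lets published score tables be used as simulation inputs.
#'
#' @param scores a \code{maxdiff_scores} object, or a positive numeric
#'   vector summing to 100.
#' @param a items per task (probability method).
#' @param method rescaling method the scores were produced with.
#' @return a \code{maxdiff_utilities} object (no standard errors).
#' @export
invert_rescaled <- function(scores, a = NULL,
                            method = c("probability", "softmax")) {
  if (inherits(scores, "maxdiff_scores")) {
    a <- a %||% scores$items_per_task
    method <- scores$method
    scores <- scores$scores
  } else method <- match.arg(method)
  stopifnot(is.numeric(scores))
  if (any(scores <= 0))
    stopf("scores must be strictly positive to invert (zero score found)")
  if (abs(sum(scores) - 100) > 1e-6)
    stopf("scores must sum to 100 (got %.6f)", sum(scores))
  if (method == "softmax") {
    u <- log(scores)
    u <- u - mean(u)
  } else {
    if (is.null(a)) stopf("items_per_task 'a' is required")
    # q_i = t * scores_i must lie in (0, 1); solve sum(u(t)) = 0 for t
    su <- function(t) sum(log((a - 1) * t * scores / (1 - t * scores)))
    hi <- 1 / max(scores)
    r <- stats::uniroot(su, lower = hi * 1e-12, upper = hi * (1 - 1e-12),
                        tol = .Machine$double.eps^0.75)
    q <- r$root * scores
    u <- log((a - 1) * q / (1 - q))
    u <- u - mean(u)   # residual float error only
  }
  names(u) <- names(scores)
  structure(list(utilities = u, se = NULL, vcov = NULL,
                 loglik = NA_real_, null_loglik = NA_real_,
                 converged = TRUE, n_iter = 0L, n_obs = 0L, ridge = 0),
            class = "maxdiff_utilities")
}

#' Rank items by score
#'
#' Competition ranking: rank 1 is the highest score, tied items share the
#' smallest applicable rank and the following rank is skipped, e.g. scores
#' (3, 2, 2, 1) rank as (1, 2, 2, 4).
#'
#' @param scores a \code{maxdiff_scores} object or numeric vector.
#' @return integer ranks, named like the scores.
#' @export
rank_items <- function(scores) {
  s <- if (inherits(scores, "maxdiff_scores")) scores$scores else scores
  r <- rank(-s, ties.method = "min")
  storage.mode(r) <- "integer"
  r
}

#' Export utilities and scores as a tidy table
#'
#' @param u a \code{maxdiff_utilities} object.
#' @param a items per task for the rescaling.
#' @param method rescaling method.
#' @return data frame with columns \code{item,utility,se,score,rank}.
#' @export
utility_table <- function(u, a, method = c("probability", "softmax")) {
  stopifnot(inherits(u, "maxdiff_utilities"))
  s <- rescale_scores(u, a = a, method = method)
  data.frame(item = names(u$utilities),
             utility = unname(u$utilities),
             se = if (is.null(u$se)) NA_real_ else unname(u$se),
             score = unname(s$scores),
             rank = unname(rank_items(s)),
             row.names = NULL)
}
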