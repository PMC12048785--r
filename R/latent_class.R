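# Latent-class multinomial logit: a finite mixture of exploded-logit choice
# models over respondents. Respondent r in class c contributes
# prod_{obs of r} P(choice | u_c); class shares pi live on the simplex.
# Fitted by EM with multiple random restarts.

# R x C matrix of per-respondent log-likelihoods under each class's utilities
class_loglik_matrix <- function(obs, util_mat) {
  C <- ncol(util_mat)
  R <- length(obs$respondent_ids)
  L <- matrix(0, R, C)
  for (c in seq_len(C)) {
    lp <- exploded_logp(util_mat[, c], obs)
    L[, c] <- rowsum(lp, obs$resp)[, 1L]
  }
  L
}

em_once <- function(obs, C, post, tol, max_iter, ridge = 1e-8) {
  K <- obs$n_items
  n <- nrow(obs$sets)
  util <- matrix(0, K, C)
  ll_old <- -Inf
  ll <- -Inf
  iter <- 0L
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    # M-step: weighted exploded-logit refit per class, warm-started
    pi_c <- pmax(colMeans(post), 1e-12)
    pi_c <- pi_c / sum(pi_c)
    for (c in seq_len(C)) {
      w <- post[obs$resp, c]
      fit <- fit_aggregate(obs, weights = w, ridge = ridge,
                           start = util[, c], tol = 1e-9, max_iter = 25L,
                           check_separation = FALSE)
      util[, c] <- fit$utilities
    }
    # E-step
    L <- class_loglik_matrix(obs, util)
    A <- sweep(L, 2L, log(pi_c), `+`)
    lse <- row_logsumexp(A)
    ll <- sum(lse)
    post <- exp(A - lse)
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-6)
      warnf("EM log-likelihood decreased by %.2g at iteration %d", ll_old - ll, iter)
    if (iter >= max_iter || abs(ll - ll_old) / (abs(ll) + 1) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, shares = pi_c, utilities = util, posterior = post,
       n_iter = iter, trace = trace)
}

#' Fit a latent-class exploded-logit model
#'
#' Segments respondents by EM on the mixture likelihood: the E-step computes
#' posterior class-membership probabilities from per-respondent class
#' likelihoods, the M-step refits each class's exploded logit with posterior
#' weights and sets the shares to the mean posterior. Several random
#' restarts (posterior initializations drawn from a symmetric Dirichlet) are
#' run briefly and the best is polished to full tolerance; the EM
#' log-likelihood is non-decreasing within a run.
#'
#' @param obs a \code{maxdiff_choices} object grouped by respondent.
#' @param n_classes number of classes C (>= 1).
#' @param n_restarts random initializations (default 20).
#' @param seed integer seed for the initializations.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per run (default 500).
#' @param restart_iter short-run iteration cap used to triage restarts
#'   before polishing the best one.
#' @return an object of class \code{maxdiff_lc_model}: \code{n_classes},
#'   \code{shares} (descending), \code{class_utilities} (K x C matrix, one
#'   sum-to-zero column per class), \code{posterior} (R x C, rows sum to 1,
#'   rownames are respondent ids), \code{loglik}, \code{null_loglik},
#'   \code{n_params} (= C*(K-1) + C-1), \code{convergence}.
#' @details Classes are relabeled in order of decreasing share; with
#'   \code{n_classes = 1} the fit coincides with [fit_aggregate()]. A class
#'   whose share collapses below 1e-6 is retained with near-flat utilities
#'   and flagged with a warning.
#' @seealso [fit_metrics()], [model_scan()], [assign_segments()]
#' @export
fit_latent_class <- function(obs, n_classes, n_restarts = 20L, seed = 1L,
                             tol = 1e-8, max_iter = 500L, restart_iter = 40L) {
  stopifnot(inherits(obs, "maxdiff_choices"))
  C <- as.integer(n_classes)
  R <- length(obs$respondent_ids)
  if (C < 1L) stopf("n_classes must be >= 1")
  if (C > R) stopf("more classes (%d) than respondents (%d)", C, R)
  K <- obs$n_items
  n <- nrow(obs$sets)

  if (C == 1L) {
    fit <- fit_aggregate(obs)
    post <- matrix(1, R, 1L, dimnames = list(obs$respondent_ids, NULL))
    return(structure(list(n_classes = 1L, shares = 1,
                          class_utilities = matrix(fit$utilities, K, 1L,
                                                   dimnames = list(obs$items, NULL)),
                          posterior = post, loglik = fit$loglik,
                          null_loglik = fit$null_loglik,
                          n_params = K - 1L,
                          items = obs$items,
                          convergence = list(n_restarts = 0L,
                                             n_iter = fit$n_iter, tol = tol,
                                             converged = fit$converged)),
                     class = "maxdiff_lc_model"))
  }

  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (s in seq_len(n_restarts)) {
    set.seed(seeds[s])
    g <- matrix(stats::rgamma(R * C, 1), R, C)   # symmetric Dirichlet(1)
    post0 <- g / rowSums(g)
    run <- em_once(obs, C, post0, tol = tol * 10, max_iter = restart_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  best <- em_once(obs, C, best$posterior, tol = tol, max_iter = max_iter)

  ord <- order(best$shares, decreasing = TRUE)
  shares <- best$shares[ord]
  util <- best$utilities[, ord, drop = FALSE]
  post <- best$posterior[, ord, drop = FALSE]
  dimnames(util) <- list(obs$items, NULL)
  rownames(post) <- obs$respondent_ids
  if (any(shares < 1e-6))
    warnf("class(es) %s have collapsed to near-zero share",
          paste(which(shares < 1e-6), collapse = ", "))
  structure(list(n_classes = C, shares = unname(shares),
                 class_utilities = util, posterior = post,
                 loglik = best$loglik,
                 null_loglik = -n * log(obs$items_per_task),
                 n_params = C * (K - 1L) + (C - 1L),
                 items = obs$items,
                 convergence = list(n_restarts = n_restarts,
                                    n_iter = best$n_iter, tol = tol,
                                    converged = best$n_iter < max_iter)),
            class = "maxdiff_lc_model")
}

#' @export
print.maxdiff_lc_model <- function(x, ...) {
  cat(sprintf("Latent-class exploded logit: %d class(es), LL = %.2f, k = %d\n",
              x$n_classes, x$loglik, x$n_params))
  cat("  shares:", paste(sprintf("%.1f%%", 100 * x$shares), collapse = " "), "\n")
  invisible(x)
}

#' Model-selection metrics for a choice model
#'
#' Computes the full metric suite used to compare segmentations: percentage
#' certainty \code{100 * (1 - LL/LL0)}, AIC, CAIC, BIC, sample-size adjusted
#' BIC, likelihood-ratio chi-square against the chance model, and relative
#' chi-square (chi-square / number of parameters). The effective sample
#' size is the number of exploded choices \code{N = R * T * 2}, and the
#' chance baseline is \code{LL0 = -N * log(a)}. The adjusted BIC uses the
#' \code{log((N + 2) / 24)} penalty.
#'
#' @param loglik maximized log-likelihood.
#' @param n_classes number of latent classes C.
#' @param n_items number of items K.
#' @param n_respondents respondents R.
#' @param n_tasks tasks per respondent T.
#' @param items_per_task items shown per task a.
#' @return an object of class \code{maxdiff_fit_metrics} (also a list):
#'   \code{loglik, null_loglik, percentage_certainty, aic, caic, bic, abic,
#'   chi_square, relative_chi_square, n_params, n_choices}.
#' @examples
#' # a two-class model for 378 respondents x 12 tasks of 4 items
#' fit_metrics(-11672.12, n_classes = 2, n_items = 16,
#'             n_respondents = 378, n_tasks = 12, items_per_task = 4)
#' @export
fit_metrics <- function(loglik, n_classes, n_items, n_respondents, n_tasks,
                        items_per_task) {
  stopifnot(is.finite(loglik), n_classes >= 1, n_items >= 2,
            n_respondents >= 1, n_tasks >= 1, items_per_task >= 2)
  k <- n_classes * (n_items - 1) + (n_classes - 1)
  N <- n_respondents * n_tasks * 2
  ll0 <- -N * log(items_per_task)
  chi <- 2 * (loglik - ll0)
  structure(list(loglik = loglik, null_loglik = ll0,
                 percentage_certainty = 100 * (1 - loglik / ll0),
                 aic = -2 * loglik + 2 * k,
                 caic = -2 * loglik + k * (log(N) + 1),
                 bic = -2 * loglik + k * log(N),
                 abic = -2 * loglik + k * log((N + 2) / 24),
                 chi_square = chi,
                 relative_chi_square = chi / k,
                 n_params = k, n_choices = N),
            class = "maxdiff_fit_metrics")
}

#' @export
print.maxdiff_fit_metrics <- function(x, ...) {
  cat("Model fit metrics\n")
  v <- c("Log-likelihood" = x$loglik,
         "Percentage certainty" = x$percentage_certainty,
         "AIC" = x$aic, "CAIC" = x$caic, "BIC" = x$bic, "ABIC" = x$abic,
         "Chi-square" = x$chi_square,
         "Relative chi-square" = x$relative_chi_square)
  print(round(v, 2))
  invisible(x)
}

#' Scan a range of class counts
#'
#' Fits a latent-class model for each candidate number of classes and
#' tabulates the model-selection metrics alongside the modal segment sizes,
#' the quantities on which the analyst's choice of C rests (metric minima,
#' size of metric drops, and balance of the segment sizes). No class count
#' is auto-selected.
#'
#' @param obs a \code{maxdiff_choices} object.
#' @param n_tasks tasks per respondent (for the metric sample size).
#' @param class_range integer vector of class counts to fit.
#' @param ... passed to [fit_latent_class()] (restarts, seed, tolerances).
#' @return an object of class \code{maxdiff_model_scan}: \code{models}
#'   (list), \code{metrics} (data frame, one row per C), \code{sizes}
#'   (list of modal segment size tables).
#' @export
model_scan <- function(obs, n_tasks, class_range = 2:5, ...) {
  stopifnot(inherits(obs, "maxdiff_choices"), length(class_range) >= 1)
  R <- length(obs$respondent_ids)
  models <- lapply(class_range, function(C) fit_latent_class(obs, C, ...))
  metrics <- do.call(rbind, lapply(models, function(m) {
    fm <- fit_metrics(m$loglik, m$n_classes, obs$n_items, R, n_tasks,
                      obs$items_per_task)
    data.frame(n_classes = m$n_classes, loglik = fm$loglik,
               percentage_certainty = fm$percentage_certainty,
               aic = fm$aic, caic = fm$caic, bic = fm$bic, abic = fm$abic,
               chi_square = fm$chi_square,
               relative_chi_square = fm$relative_chi_square,
               n_params = fm$n_params)
  }))
  sizes <- lapply(models, function(m) attr(assign_segments(m), "sizes"))
  structure(list(models = models, metrics = metrics, sizes = sizes),
            class = "maxdiff_model_scan")
}

#' @export
print.maxdiff_model_scan <- function(x, ...) {
  cat("Latent-class model scan\n")
  print(x$metrics, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Modal segment assignment
#'
#' Assigns each respondent to the class with the highest posterior
#' membership probability; exact ties go to the lower class index.
#'
#' @param model a \code{maxdiff_lc_model}.
#' @return data frame with columns \code{respondent_id}, \code{segment}
#'   (integer class), \code{posterior} (that class's probability), with a
#'   \code{"sizes"} attribute holding counts and percentage shares per
#'   segment ("market sizes").
#' @export
assign_segments <- function(model) {
  stopifnot(inherits(model, "maxdiff_lc_model"))
  p <- model$posterior
  seg <- max.col(p, ties.method = "first")
  out <- data.frame(respondent_id = rownames(p), segment = seg,
                    posterior = p[cbind(seq_len(nrow(p)), seg)],
                    row.names = NULL)
  counts <- tabulate(seg, nbins = model$n_classes)
  attr(out, "sizes") <- data.frame(segment = seq_len(model$n_classes),
                                   n = counts,
                                   percent = 100 * counts / nrow(p))
  out
}
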