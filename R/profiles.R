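# Segment profiling and membership prediction. The tests themselves are
# standard (Pearson chi-square, one-way MANOVA with Wilks' lambda,
# multinomial logistic regression); this module wraps them in the shapes
# the segmentation workflow needs: segments x covariate tables, pairwise
# comparisons against a reference segment, and coefficient tables with
# odds ratios against a reference class.

seg_factor <- function(assignments) {
  if (is.data.frame(assignments)) assignments <- assignments$segment
  factor(assignments)
}

#' Chi-square test of a categorical covariate across segments
#'
#' Pearson chi-square test (no continuity correction) of independence
#' between segment membership and a categorical respondent covariate.
#'
#' @param assignments segment labels: an [assign_segments()] data frame or
#'   a vector.
#' @param covariate categorical covariate, same length/order as the
#'   respondents.
#' @return an object of class \code{maxdiff_crosstab}: \code{table}
#'   (segments x categories), \code{expected}, \code{chi_square}, \code{df}
#'   (= (rows-1)(cols-1)), \code{p_value}, \code{low_expected} flag.
#' @details A warning is issued when more than 20% of expected counts fall
#'   below 5, the usual validity caution for the asymptotic reference
#'   distribution.
#' @export
crosstab_test <- function(assignments, covariate) {
  g <- seg_factor(assignments)
  x <- factor(covariate)
  if (length(g) != length(x)) stopf("assignments and covariate lengths differ")
  tab <- table(segment = g, category = x)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("need at least 2 segments and 2 categories")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stopf("empty margin in the contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- mean(ht$expected < 5) > 0.2
  if (low) warnf("more than 20%% of expected counts are below 5; chi-square approximation is doubtful")
  structure(list(table = tab, expected = ht$expected,
                 chi_square = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), low_expected = low),
            class = "maxdiff_crosstab")
}

#' @export
print.maxdiff_crosstab <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2(%d) = %.3f, p = %.4g\n",
              x$df, x$chi_square, x$p_value))
  print(x$table)
  invisible(x)
}

#' One-way MANOVA of numeric covariates across segments
#'
#' Tests whether segment mean vectors differ on a set of numeric covariates
#' (Wilks' lambda with Rao's F approximation), reports per-variable
#' univariate one-way F tests, and compares each segment's mean against a
#' reference segment per variable with adjusted p-values (pooled-variance t
#' tests on the within-group mean square).
#'
#' @param assignments segment labels (see [crosstab_test()]).
#' @param covariates data frame of numeric columns, one row per respondent.
#' @param reference segment used as the comparison baseline (default the
#'   first level).
#' @param p_adjust adjustment for the pairwise comparisons:
#'   \code{"bonferroni"} (default) or \code{"none"}.
#' @return an object of class \code{maxdiff_manova}: \code{wilks_lambda},
#'   \code{approx_f}, \code{df} (numerator, denominator), \code{p_value},
#'   \code{univariate} (per-variable F and p), \code{pairwise} (long data
#'   frame: variable, segment, reference, mean_diff, p_adj).
#' @export
manova_profile <- function(assignments, covariates, reference = NULL,
                           p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  g <- seg_factor(assignments)
  Y <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(Y)) stopf("covariates must all be numeric")
  if (nrow(Y) != length(g)) stopf("assignments and covariates lengths differ")
  if (nlevels(g) < 2L) stopf("need at least 2 segments")
  if (min(table(g)) <= ncol(Y))
    stopf("each segment needs more members than there are covariates")
  reference <- as.character(reference %||% levels(g)[1L])
  if (!reference %in% levels(g)) stopf("reference segment '%s' not found", reference)

  if (ncol(Y) == 1L) {
    # one dependent variable: Wilks' lambda reduces to SSW / SST and the
    # approximate F is the one-way ANOVA F
    fit <- stats::aov(Y[, 1L] ~ g)
    s <- summary(fit)[[1L]]
    lambda <- s["Residuals", "Sum Sq"] / sum(s[, "Sum Sq"])
    row <- c(Wilks = lambda, `approx F` = s[1L, "F value"],
             `num Df` = s[1L, "Df"], `den Df` = s[2L, "Df"],
             `Pr(>F)` = s[1L, "Pr(>F)"])
    uni_tab <- data.frame(variable = colnames(Y), f = s[1L, "F value"],
                          df1 = s[1L, "Df"], df2 = s[2L, "Df"],
                          p = s[1L, "Pr(>F)"])
    fit$df.residual <- s[2L, "Df"]
  } else {
    fit <- stats::manova(Y ~ g)
    sm <- tryCatch(summary(fit, test = "Wilks"),
                   error = function(e) stopf("within-group SSCP is singular (%s); drop collinear covariates", conditionMessage(e)))
    row <- sm$stats[1L, ]
    uni <- stats::summary.aov(fit)
    uni_tab <- do.call(rbind, lapply(seq_along(uni), function(i) {
      s <- uni[[i]]
      if (!is.data.frame(s)) s <- s[[1L]]
      data.frame(variable = colnames(Y)[i], f = s[1L, "F value"],
                 df1 = s[1L, "Df"], df2 = s[2L, "Df"],
                 p = s[1L, "Pr(>F)"])
    }))
  }

  # pairwise vs reference, pooled within-group variance per variable
  n_g <- table(g)
  res <- as.matrix(stats::resid(fit))
  mse <- stats::setNames(colSums(res^2) / fit$df.residual, colnames(Y))
  others <- setdiff(levels(g), reference)
  pw <- do.call(rbind, lapply(colnames(Y), function(v) {
    mdiff <- tapply(Y[, v], g, mean)
    se <- sqrt(mse[v] * (1 / n_g[others] + 1 / n_g[reference]))
    tval <- (mdiff[others] - mdiff[reference]) / se
    p <- 2 * stats::pt(-abs(tval), fit$df.residual)
    if (p_adjust == "bonferroni") p <- pmin(1, p * length(others))
    data.frame(variable = v, segment = others, reference = reference,
               mean_diff = unname(mdiff[others] - mdiff[reference]),
               p_adj = unname(p), row.names = NULL)
  }))
  structure(list(wilks_lambda = unname(row["Wilks"]),
                 approx_f = unname(row["approx F"]),
                 df = unname(c(row["num Df"], row["den Df"])),
                 p_value = unname(row["Pr(>F)"]),
                 univariate = uni_tab, pairwise = pw,
                 reference = reference, p_adjust = p_adjust),
            class = "maxdiff_manova")
}

#' @export
print.maxdiff_manova <- function(x, ...) {
  cat(sprintf("One-way MANOVA: Wilks' lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$wilks_lambda, x$df[1L], x$df[2L], x$approx_f, x$p_value))
  cat("Univariate tests:\n")
  print(x$univariate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multinomial logistic regression for segment membership
#'
#' Fits a multinomial logistic regression predicting segment membership
#' from respondent covariates, with a designated reference segment whose
#' linear predictor is fixed at zero. Reports per non-reference segment the
#' coefficients B, standard errors, Wald p-values, and odds ratios Exp(B).
#' Categorical predictors are expanded against their declared factor
#' reference level; numeric predictors are used on their raw scale so each
#' Exp(B) is the odds multiplier per scale point.
#'
#' @param assignments segment labels (vector or [assign_segments()] frame).
#' @param predictors data frame of predictors (numeric and/or factor), one
#'   row per respondent; set factor reference levels with
#'   [stats::relevel()] beforehand.
#' @param reference_class segment used as the reference category.
#' @param ridge weight-decay penalty used only when the unpenalized fit
#'   shows signs of separation (default \code{1e-3} after a warning).
#' @return an object of class \code{maxdiff_membership_model}:
#'   \code{coefficients}, \code{se}, \code{p_value}, \code{exp_b} (each a
#'   (C-1) x p matrix, one row per non-reference segment),
#'   \code{reference}, \code{class_labels}, \code{terms}, \code{xlevels},
#'   \code{loglik}, \code{fit} (the underlying \code{nnet::multinom} object).
#' @export
fit_membership_model <- function(assignments, predictors,
                                 reference_class = NULL, ridge = 1e-3) {
  g <- seg_factor(assignments)
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(g)) stopf("assignments and predictors lengths differ")
  if (nlevels(g) < 2L) stopf("need at least 2 segments")
  reference_class <- as.character(reference_class %||% levels(g)[1L])
  if (!reference_class %in% levels(g))
    stopf("reference class '%s' not among segments", reference_class)
  g <- stats::relevel(g, ref = reference_class)

  dat <- cbind(.segment = g, predictors)
  fml <- if (ncol(predictors)) {
    stats::reformulate(names(predictors), response = ".segment")
  } else stats::as.formula(.segment ~ 1)
  mf <- stats::model.frame(fml, data = dat)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  if (nrow(X) <= ncol(X) * (nlevels(g) - 1L))
    stopf("more parameters than observations")

  fit <- nnet::multinom(fml, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = 500L)
  cf <- stats::coef(fit)
  if (nlevels(g) == 2L) cf <- matrix(cf, 1L, dimnames = list(levels(g)[2L], names(cf)))
  if (any(abs(cf) > 15)) {
    warnf("apparent separation (|B| > 15); refitting with ridge penalty %g", ridge)
    fit <- nnet::multinom(fml, data = dat, Hess = TRUE, trace = FALSE,
                          maxit = 500L, decay = ridge)
    cf <- stats::coef(fit)
    if (nlevels(g) == 2L) cf <- matrix(cf, 1L, dimnames = list(levels(g)[2L], names(cf)))
  }
  se <- summary(fit)$standard.errors
  if (nlevels(g) == 2L) se <- matrix(se, 1L, dimnames = dimnames(cf))
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = cf, se = se, p_value = p, exp_b = exp(cf),
                 reference = reference_class,
                 class_labels = levels(g),
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 loglik = -fit$value,
                 n = nrow(X),
                 fit = fit),
            class = "maxdiff_membership_model")
}

#' @export
print.maxdiff_membership_model <- function(x, digits = 3, ...) {
  cat(sprintf("Multinomial logistic membership model (reference: %s)\n", x$reference))
  print(coef_table(x), row.names = FALSE, digits = digits)
  invisible(x)
}

#' Coefficient table of a membership model
#'
#' @param model a \code{maxdiff_membership_model}.
#' @return data frame with columns \code{segment,predictor,B,SE,p,ExpB}.
#' @export
coef_table <- function(model) {
  stopifnot(inherits(model, "maxdiff_membership_model"))
  cf <- model$coefficients
  do.call(rbind, lapply(rownames(cf), function(s)
    data.frame(segment = s, predictor = colnames(cf),
               B = cf[s, ], SE = model$se[s, ], p = model$p_value[s, ],
               ExpB = model$exp_b[s, ], row.names = NULL)))
}

#' Save or load a membership model as JSON
#'
#' Serializes the coefficient matrices, reference class, predictor formula
#' and factor levels of a fitted membership model so predictions can be
#' made in a later session without refitting.
#'
#' @param model a \code{maxdiff_membership_model}.
#' @param path JSON file path.
#' @return \code{write_membership_model} returns \code{path} invisibly;
#'   \code{read_membership_model} returns a
#'   \code{maxdiff_membership_model} usable with [predict_membership()].
#' @export
write_membership_model <- function(model, path) {
  stopifnot(inherits(model, "maxdiff_membership_model"))
  out <- list(coefficients = as.data.frame(model$coefficients),
              se = as.data.frame(model$se),
              segments = rownames(model$coefficients),
              reference = model$reference,
              class_labels = model$class_labels,
              formula = paste(deparse(stats::formula(model$terms)), collapse = " "),
              xlevels = model$xlevels,
              loglik = model$loglik)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_membership_model
#' @export
read_membership_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.matrix(m$coefficients)
  rownames(cf) <- m$segments
  se <- as.matrix(m$se)
  rownames(se) <- m$segments
  tt <- stats::terms(stats::as.formula(m$formula))
  structure(list(coefficients = cf, se = se,
                 p_value = 2 * stats::pnorm(-abs(cf / se)),
                 exp_b = exp(cf),
                 reference = m$reference,
                 class_labels = m$class_labels,
                 terms = stats::delete.response(tt),
                 xlevels = as.list(m$xlevels),
                 loglik = m$loglik, fit = NULL),
            class = "maxdiff_membership_model")
}

#' Predict segment membership probabilities
#'
#' Evaluates the fitted multinomial logistic model on new respondents:
#' softmax over the linear predictors with the reference class fixed at
#' zero. Probabilities sum to 1 per respondent.
#'
#' @param model a \code{maxdiff_membership_model}.
#' @param newdata data frame with the model's predictor columns.
#' @return list with \code{probabilities} (n x C matrix, columns in
#'   \code{model$class_labels} order, reference first) and \code{modal}
#'   (predicted class labels).
#' @export
predict_membership <- function(model, newdata) {
  stopifnot(inherits(model, "maxdiff_membership_model"))
  newdata <- as.data.frame(newdata)
  need <- all.vars(stats::delete.response(model$terms))
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stopf("missing predictor(s): %s", paste(miss, collapse = ", "))
  tt <- stats::delete.response(model$terms)
  mf <- stats::model.frame(tt, newdata, xlev = model$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- X %*% t(model$coefficients)
  expeta <- cbind(1, exp(eta))
  probs <- expeta / rowSums(expeta)
  colnames(probs) <- model$class_labels
  modal <- model$class_labels[max.col(probs, ties.method = "first")]
  list(probabilities = probs, modal = modal)
}
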