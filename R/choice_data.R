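#' Construct a validated set of best-worst responses
#'
#' Bundles response records with the design they were collected under and
#' optional respondent covariates, enforcing the structural rules of a
#' MaxDiff survey: best and worst differ, both were actually shown in that
#' task, each respondent answers each task at most once, and each
#' respondent maps to exactly one questionnaire version.
#'
#' @param records data frame with columns \code{respondent_id},
#'   \code{version}, \code{task}, \code{best}, \code{worst}; best/worst are
#'   item indices (1-based) or item labels.
#' @param design the \code{maxdiff_design} the responses refer to.
#' @param covariates optional data frame keyed by \code{respondent_id}.
#' @return an object of class \code{maxdiff_responses}.
#' @seealso [read_responses()], [explode_tasks()]
#' @export
response_set <- function(records, design, covariates = NULL) {
  stopifnot(inherits(design, "maxdiff_design"))
  sp <- design$spec
  need <- c("respondent_id", "version", "task", "best", "worst")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$respondent_id <- as.character(records$respondent_id)
  for (col in c("best", "worst")) {
    if (is.character(records[[col]]) || is.factor(records[[col]])) {
      idx <- match(as.character(records[[col]]), sp$items)
      if (anyNA(idx))
        stopf("unknown item label(s) in '%s': %s", col,
              paste(unique(records[[col]][is.na(idx)]), collapse = ", "))
      records[[col]] <- idx
    }
    records[[col]] <- as.integer(records[[col]])
  }
  records$version <- as.integer(records$version)
  records$task <- as.integer(records$task)

  bad <- records$version < 1L | records$version > sp$n_versions
  if (any(bad))
    stopf("record %d refers to version %d; design has %d versions",
          which(bad)[1L], records$version[which(bad)[1L]], sp$n_versions)
  bad <- records$task < 1L | records$task > sp$n_tasks
  if (any(bad))
    stopf("record %d refers to task %d; versions have %d tasks",
          which(bad)[1L], records$task[which(bad)[1L]], sp$n_tasks)
  bad <- records$best == records$worst
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("respondent '%s' task %d: best and worst are the same item",
          records$respondent_id[i], records$task[i])
  }
  for (i in seq_len(nrow(records))) {
    shown <- design$versions[[records$version[i]]][records$task[i], ]
    if (!(records$best[i] %in% shown) || !(records$worst[i] %in% shown))
      stopf("respondent '%s' task %d: chosen item not shown in that task",
            records$respondent_id[i], records$task[i])
  }
  dup <- duplicated(records[c("respondent_id", "task")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stopf("respondent '%s' answers task %d more than once",
          records$respondent_id[i], records$task[i])
  }
  vmap <- tapply(records$version, records$respondent_id, function(v) length(unique(v)))
  if (any(vmap > 1L))
    stopf("respondent '%s' appears under more than one version",
          names(vmap)[which(vmap > 1L)[1L]])
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"respondent_id" %in% names(covariates))
      stopf("covariates must have a respondent_id column")
    covariates$respondent_id <- as.character(covariates$respondent_id)
  }
  structure(list(design = design, records = records, covariates = covariates),
            class = "maxdiff_responses")
}

#' @export
print.maxdiff_responses <- function(x, ...) {
  cat(sprintf("MaxDiff responses: %d records from %d respondents (%d items, %d per task)\n",
              nrow(x$records), length(unique(x$records$respondent_id)),
              x$design$spec$n_items, x$design$spec$items_per_task))
  invisible(x)
}

#' Read best-worst responses from CSV
#'
#' Expects columns \code{respondent_id,version,task,best,worst} with items
#' given as labels matching the design. All [response_set()] validation
#' applies; malformed records are rejected with a message naming the
#' respondent and task.
#'
#' @param path responses CSV path.
#' @param design the \code{maxdiff_design} the responses refer to.
#' @param covariates_path optional covariates CSV
#'   (\code{respondent_id} plus named columns).
#' @return a \code{maxdiff_responses} object.
#' @export
read_responses <- function(path, design, covariates_path = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  cov <- if (!is.null(covariates_path))
    utils::read.csv(covariates_path, stringsAsFactors = FALSE) else NULL
  response_set(records, design, cov)
}

#' @rdname read_responses
#' @param rs a \code{maxdiff_responses} object.
#' @export
write_responses <- function(rs, path) {
  stopifnot(inherits(rs, "maxdiff_responses"))
  out <- rs$records
  out$best <- rs$design$spec$items[out$best]
  out$worst <- rs$design$spec$items[out$worst]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Explode best-worst records into choice observations
#'
#' Converts every response record into the two choice observations of the
#' exploded-logit representation: the best pick as a standard multinomial
#' choice among the shown items (sign +1), and the worst pick as a choice
#' among the same shown items under negated utilities (sign -1).
#'
#' @param rs a \code{maxdiff_responses} object.
#' @return an object of class \code{maxdiff_choices} with components
#'   \code{sets} (n x a item-index matrix), \code{choice_col} (column of the
#'   chosen item within \code{sets}), \code{sign} (+1 best / -1 worst),
#'   \code{resp} (respondent index), \code{respondent_ids}, \code{n_items},
#'   \code{items_per_task}, \code{n_tasks_per_resp}.
#' @export
explode_tasks <- function(rs) {
  stopifnot(inherits(rs, "maxdiff_responses"))
  rec <- rs$records
  sp <- rs$design$spec
  n <- nrow(rec)
  ids <- unique(rec$respondent_id)
  ridx <- match(rec$respondent_id, ids)
  sets <- matrix(0L, n, sp$items_per_task)
  for (i in seq_len(n))
    sets[i, ] <- rs$design$versions[[rec$version[i]]][rec$task[i], ]
  sets2 <- rbind(sets, sets)
  chosen <- c(rec$best, rec$worst)
  choice_col <- integer(2L * n)
  if (n > 0L)
    choice_col <- max.col(sets2 == chosen, ties.method = "first")
  structure(list(sets = sets2,
                 choice_col = choice_col,
                 sign = rep(c(1, -1), each = n),
                 resp = c(ridx, ridx),
                 respondent_ids = ids,
                 n_items = sp$n_items,
                 items_per_task = sp$items_per_task,
                 items = sp$items,
                 n_records = n),
            class = "maxdiff_choices")
}

#' Chance-model log-likelihood
#'
#' Log-likelihood of the null (chance) model in which every pick, best and
#' worst alike, is a uniform choice among the \code{a} shown items:
#' \code{n_records * 2 * log(1/a)}. This is the baseline LL0 entering
#' percentage certainty and the likelihood-ratio chi-square.
#'
#' @param rs a \code{maxdiff_responses} object, or a \code{maxdiff_choices}
#'   object produced by [explode_tasks()].
#' @return the chance log-likelihood (a negative number).
#' @export
null_loglik <- function(rs) {
  if (inherits(rs, "maxdiff_responses")) {
    n <- nrow(rs$records); a <- rs$design$spec$items_per_task
    return(-2 * n * log(a))
  }
  if (inherits(rs, "maxdiff_choices"))
    return(-nrow(rs$sets) * log(rs$items_per_task))
  stopf("null_loglik expects maxdiff_responses or maxdiff_choices")
}
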