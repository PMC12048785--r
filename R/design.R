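#' Specify a MaxDiff experimental design
#'
#' Describes the layout of a best-worst scaling (MaxDiff) experiment:
#' \code{n_items} items in total, of which \code{items_per_task} are shown in
#' each choice task, \code{n_tasks} tasks per questionnaire version, and
#' \code{n_versions} versions of the questionnaire. Each respondent answers
#' one version.
#'
#' @param n_items number of items (K) to be scaled.
#' @param items_per_task number of items (a) shown per task; at least 2 and
#'   at most \code{n_items}.
#' @param n_tasks number of tasks (T) per questionnaire version.
#' @param n_versions number of questionnaire versions (V).
#' @param items optional character vector of K item labels; defaults to
#'   \code{"item01"}, \code{"item02"}, ...
#' @param seed integer seed controlling design construction.
#' @return an object of class \code{maxdiff_design_spec}.
#' @details When \code{n_tasks * items_per_task} is not a multiple of
#'   \code{n_items}, exact within-version one-way balance is impossible; the
#'   spec is still accepted but carries a \code{balanced} flag of
#'   \code{FALSE} and item appearance counts differ by one within a version.
#' @seealso [generate_design()], [design_diagnostics()]
#' @export
design_spec <- function(n_items, items_per_task, n_tasks, n_versions,
                        items = NULL, seed = 1L) {
  n_items <- as.integer(n_items)
  items_per_task <- as.integer(items_per_task)
  n_tasks <- as.integer(n_tasks)
  n_versions <- as.integer(n_versions)
  if (n_items < 2L) stopf("need at least 2 items, got %d", n_items)
  if (items_per_task < 2L) stopf("items_per_task must be >= 2, got %d", items_per_task)
  if (items_per_task > n_items)
    stopf("infeasible design: items_per_task (%d) exceeds n_items (%d)",
          items_per_task, n_items)
  if (n_tasks < 1L || n_versions < 1L) stopf("n_tasks and n_versions must be >= 1")
  if (is.null(items)) items <- sprintf("item%02d", seq_len(n_items))
  if (length(items) != n_items || anyDuplicated(items))
    stopf("items must be %d distinct labels", n_items)
  balanced <- (n_tasks * items_per_task) %% n_items == 0L
  if (!balanced)
    warnf("n_tasks * items_per_task (%d) is not a multiple of n_items (%d); per-version item counts will differ by one",
          n_tasks * items_per_task, n_items)
  structure(list(n_items = n_items, items_per_task = items_per_task,
                 n_tasks = n_tasks, n_versions = n_versions,
                 items = as.character(items), seed = as.integer(seed),
                 balanced = balanced),
            class = "maxdiff_design_spec")
}

#' Generate a balanced MaxDiff design
#'
#' Builds questionnaire versions by seeded randomized block construction in
#' the spirit of a balanced incomplete block design: within every version
#' each item appears exactly \code{floor(T*a/K)} or \code{ceiling(T*a/K)}
#' times (exactly \code{T*a/K} when K divides T*a), and items are placed
#' greedily to keep pairwise co-occurrence counts as even as possible, first
#' within the version and then across the whole design. Item order within a
#' task (the display positions) is randomized.
#'
#' @param spec a [design_spec()].
#' @return an object of class \code{maxdiff_design}: the spec plus a list of
#'   V integer matrices (T rows, a columns) of item indices.
#' @details Construction is deterministic for a fixed \code{spec$seed}.
#'   Feasibility is guaranteed by a forcing rule: whenever an item's
#'   remaining appearance quota equals the number of remaining tasks it is
#'   placed in the current task, which keeps every quota satisfiable.
#' @examples
#' d <- generate_design(design_spec(16, 4, 12, 10, seed = 1))
#' design_diagnostics(d)
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "maxdiff_design_spec"))
  K <- spec$n_items; a <- spec$items_per_task
  Tn <- spec$n_tasks; V <- spec$n_versions
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  r_base <- (Tn * a) %/% K
  extras <- (Tn * a) %% K
  pair_global <- matrix(0L, K, K)   # co-occurrence counts accumulated so far
  versions <- vector("list", V)

  for (v in seq_len(V)) {
    capacity <- rep.int(r_base, K)
    if (extras > 0L) {
      # spread the remainder over the least-used items so the whole design
      # stays close to one-way balance
      tot <- rowSums(pair_global)
      bump <- order(tot, sample.int(K))[seq_len(extras)]
      capacity[bump] <- capacity[bump] + 1L
    }
    pair_version <- matrix(0L, K, K)
    tasks <- matrix(0L, Tn, a)
    for (t in seq_len(Tn)) {
      remaining <- Tn - t + 1L
      pick <- which(capacity >= remaining)       # forced items
      if (length(pick) > a)
        stopf("internal error: infeasible task construction (version %d, task %d)", v, t)
      while (length(pick) < a) {
        cand <- setdiff(which(capacity > 0L), pick)
        # fewest co-occurrences with items already in the task, version
        # balance weighted above global balance; random tie-break
        score_v <- if (length(pick)) colSums(pair_version[pick, cand, drop = FALSE]) else numeric(length(cand))
        score_g <- if (length(pick)) colSums(pair_global[pick, cand, drop = FALSE]) else numeric(length(cand))
        ord <- order(score_v, score_g, -capacity[cand], sample.int(length(cand)))
        pick <- c(pick, cand[ord[1L]])
      }
      pick <- pick[sample.int(a)]                # randomize display positions
      tasks[t, ] <- pick
      capacity[pick] <- capacity[pick] - 1L
      pair_version[pick, pick] <- pair_version[pick, pick] + 1L
      pair_global[pick, pick] <- pair_global[pick, pick] + 1L
    }
    versions[[v]] <- tasks
  }
  structure(list(spec = spec, versions = versions), class = "maxdiff_design")
}

#' Audit the balance of a MaxDiff design
#'
#' Computes the one-way (per-version item appearance), pairwise
#' (co-occurrence) and positional frequency summaries of a design, together
#' with pass/fail merit flags.
#'
#' @param design a [generate_design()] result.
#' @param pairwise_ratio_max merit threshold: the design fails when the
#'   ratio of the largest to the smallest pairwise co-occurrence count
#'   exceeds this value (default 2).
#' @return an object of class \code{maxdiff_balance_report} with components
#'   \code{oneway_min}, \code{oneway_max} (per-version extremes),
#'   \code{pairwise_min/max/mean}, \code{positional_min/max},
#'   \code{pairwise_counts} (K x K), \code{positional_counts} (K x a) and
#'   \code{merit_flags}.
#' @details The mean pairwise co-occurrence obeys the closed-form identity
#'   \code{V * T * choose(a, 2) / choose(K, 2)}.
#' @export
design_diagnostics <- function(design, pairwise_ratio_max = 2) {
  stopifnot(inherits(design, "maxdiff_design"))
  sp <- design$spec
  K <- sp$n_items; a <- sp$items_per_task
  oneway <- sapply(design$versions, function(m) tabulate(m, nbins = K))  # K x V
  pair <- matrix(0L, K, K)
  pos <- matrix(0L, K, a)
  for (m in design$versions) {
    for (t in seq_len(nrow(m))) {
      s <- m[t, ]
      pair[s, s] <- pair[s, s] + 1L
    }
    for (j in seq_len(a)) {
      cnt <- tabulate(m[, j], nbins = K)
      pos[, j] <- pos[, j] + cnt
    }
  }
  diag(pair) <- 0L
  up <- pair[upper.tri(pair)]
  oneway_exact <- all(oneway == oneway[1L, 1L]) ||
    (max(oneway) - min(oneway) <= 1L && !sp$balanced)
  ratio <- if (min(up) > 0L) max(up) / min(up) else Inf
  flags <- c(oneway_balanced = all(apply(oneway, 2L, function(x) max(x) - min(x)) <= (if (sp$balanced) 0L else 1L)),
             pairwise_ratio_ok = is.finite(ratio) && ratio <= pairwise_ratio_max)
  structure(list(
    oneway_min = min(oneway), oneway_max = max(oneway),
    pairwise_min = min(up), pairwise_max = max(up),
    pairwise_mean = mean(up),
    positional_min = min(pos), positional_max = max(pos),
    pairwise_counts = pair, positional_counts = pos,
    merit_flags = c(flags, pass = all(flags)),
    oneway_exact = oneway_exact),
    class = "maxdiff_balance_report")
}

#' @export
print.maxdiff_balance_report <- function(x, ...) {
  cat("MaxDiff design balance report\n")
  cat(sprintf("  one-way per version : min %d, max %d\n", x$oneway_min, x$oneway_max))
  cat(sprintf("  pairwise co-occur.  : min %d, max %d, mean %.2f\n",
              x$pairwise_min, x$pairwise_max, x$pairwise_mean))
  cat(sprintf("  positional counts   : min %d, max %d\n", x$positional_min, x$positional_max))
  cat(sprintf("  merit criteria      : %s\n",
              if (x$merit_flags[["pass"]]) "pass" else "FAIL"))
  invisible(x)
}

#' @export
print.maxdiff_design <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("MaxDiff design: %d items, %d per task, %d tasks x %d versions (seed %d)\n",
              sp$n_items, sp$items_per_task, sp$n_tasks, sp$n_versions, sp$seed))
  invisible(x)
}

#' Item exposure for a respondent sample
#'
#' Projects how often each item is seen when \code{n_respondents} are
#' assigned to questionnaire versions round-robin (respondent i gets version
#' \code{(i - 1) \%\% V + 1}), as done when fielding the survey. Used to
#' check the sample-size rule of thumb that every item should be seen
#' several hundred times.
#'
#' @param design a [generate_design()] result.
#' @param n_respondents number of respondents fielded.
#' @return integer vector of total appearances per item, named by item label.
#' @export
item_appearances <- function(design, n_respondents) {
  stopifnot(inherits(design, "maxdiff_design"))
  sp <- design$spec
  counts <- integer(sp$n_items)
  vidx <- ((seq_len(n_respondents) - 1L) %% sp$n_versions) + 1L
  per_version <- sapply(design$versions, function(m) tabulate(m, nbins = sp$n_items))
  for (v in vidx) counts <- counts + per_version[, v]
  names(counts) <- sp$items
  counts
}

#' Read and write MaxDiff designs as CSV
#'
#' The file format has one row per displayed item with columns
#' \code{version,task,position,item}; version, task and position are
#' 1-based and \code{item} is the item label. The round trip
#' write-then-read is lossless.
#'
#' @param design a \code{maxdiff_design}.
#' @param path file path.
#' @param seed seed recorded in the reconstructed spec (reading only).
#' @return \code{read_design} returns a \code{maxdiff_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "maxdiff_design"))
  sp <- design$spec
  rows <- do.call(rbind, lapply(seq_along(design$versions), function(v) {
    m <- design$versions[[v]]
    data.frame(version = v,
               task = rep(seq_len(nrow(m)), each = ncol(m)),
               position = rep(seq_len(ncol(m)), nrow(m)),
               item = sp$items[t(m)])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, seed = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("version", "task", "position", "item")
  if (!all(need %in% names(df)))
    stopf("design file must have columns %s", paste(need, collapse = ", "))
  items <- sort(unique(df$item))
  K <- length(items)
  V <- max(df$version); Tn <- max(df$task); a <- max(df$position)
  versions <- vector("list", V)
  df$idx <- match(df$item, items)
  for (v in seq_len(V)) {
    sub <- df[df$version == v, ]
    m <- matrix(0L, Tn, a)
    m[cbind(sub$task, sub$position)] <- sub$idx
    if (any(m == 0L)) stopf("version %d is missing task/position entries", v)
    versions[[v]] <- m
  }
  spec <- suppressWarnings(design_spec(K, a, Tn, V, items = items, seed = seed))
  structure(list(spec = spec, versions = versions), class = "maxdiff_design")
}
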