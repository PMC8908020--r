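#' Exhaustive core-set search (Step II)
#'
#' Enumerates every subset of 1 to `max_size` candidate variables (optionally
#' filtered by a constraint), scores each by its leave-one-out cross-validated
#' logistic-regression misclassification rate, and returns all results ranked
#' by (MR ascending, set size, lexicographic variable names). Ties are all
#' retained — several core sets typically share the best MR.
#'
#' @param table Subject variable table with `group` and the candidates.
#' @param candidates Character vector of candidate variable names (typically
#'   [included_variables()] of a Step-I screen).
#' @param max_size Largest core-set size; default 4.
#' @param threshold Classification threshold; default 0.5.
#' @param constraint Optional constraint: a predicate `function(variables)`
#'   returning `TRUE` to keep a set, or a character vector of allowed
#'   variable names (sets must be drawn entirely from it).
#' @param top_k Number of top rows (plus ties at the k-th MR) kept per size by
#'   [report_coresets()]; stored in the result. Default 5.
#' @param max_iter,tol,guard IRLS controls, see [fit_logistic()].
#' @return An object of class `coreset_search`: `results` (tibble with
#'   `variables` list-column, `label`, `size`, `mr`, `n_flagged_folds`),
#'   plus the configuration and `n`.
#' @examples
#' tab <- simulate_cohort(cohort_spec(), seed = 11)
#' sr <- search_coresets(tab, c("gait_speed", "stride_length", "pelvis_sag_rom"),
#'                       max_size = 2)
#' head(sr$results)
#' @export
search_coresets <- function(table, candidates, max_size = 4, threshold = 0.5,
                            constraint = NULL, top_k = 5,
                            max_iter = 50, tol = 1e-8, guard = 1e4) {
  assert_that(length(candidates) >= 1, "need at least one candidate.")
  assert_that(max_size >= 1 && max_size <= length(candidates),
              "`max_size` must be between 1 and the number of candidates.")
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0, 1).")
  y <- group_indicator(table$group)
  X <- coreset_matrix(table, candidates)
  colnames(X) <- candidates

  sets <- enumerate_coresets(candidates, max_size)
  keep <- if (is.null(constraint)) {
    rep(TRUE, length(sets))
  } else if (is.function(constraint)) {
    vapply(sets, constraint, logical(1))
  } else if (is.character(constraint)) {
    vapply(sets, function(s) all(s %in% constraint), logical(1))
  } else {
    abort("`constraint` must be NULL, a predicate function, or a character vector.")
  }
  sets <- sets[keep]

  results <- if (length(sets) == 0) {
    tibble::tibble(variables = list(), label = character(), size = integer(),
                   mr = numeric(), n_flagged_folds = integer())
  } else {
    idx <- lapply(sets, function(s) match(s, candidates))
    sc <- search_mr_cpp(X, as.numeric(y), idx, threshold = threshold,
                        max_iter = max_iter, tol = tol, guard = guard)
    tibble::tibble(
      variables = sets,
      label = vapply(sets, paste, character(1), collapse = " + "),
      size = lengths(sets),
      mr = as.numeric(sc$mr),
      n_flagged_folds = as.integer(sc$n_flagged_folds))
  }
  results <- dplyr::arrange(results, .data$mr, .data$size, .data$label)
  structure(list(results = results, candidates = candidates, n = length(y),
                 config = list(max_size = max_size, threshold = threshold,
                               top_k = top_k,
                               constrained = !is.null(constraint))),
            class = "coreset_search")
}

#' @export
print.coreset_search <- function(x, ...) {
  cat(sprintf("<coreset_search> %d sets scored over %d candidates (n = %d)\n",
              nrow(x$results), length(x$candidates), x$n))
  if (nrow(x$results) > 0) {
    best <- x$results[1, ]
    cat(sprintf("  best: {%s} MR = %.3f\n", best$label, best$mr))
  }
  invisible(x)
}

#' @export
tidy.coreset_search <- function(x, ...) x$results

#' @export
glance.coreset_search <- function(x, ...) {
  if (nrow(x$results) == 0) {
    return(tibble::tibble(size = integer(), best_mr = numeric(), n_sets = integer()))
  }
  dplyr::summarise(dplyr::group_by(x$results, .data$size),
                   best_mr = min(.data$mr), n_sets = dplyr::n(), .groups = "drop")
}

#' Best misclassification rate by core-set size
#'
#' Per-size minima, and the pooled minimum over all sizes up to each size
#' (non-increasing by construction).
#'
#' @param search A `coreset_search`.
#' @return A tibble: `size`, `best_mr`, `best_mr_pooled`.
#' @export
best_mr_by_size <- function(search) {
  g <- glance(search)
  dplyr::mutate(dplyr::arrange(g, .data$size),
                best_mr_pooled = cummin(.data$best_mr))
}

#' Ranked core-set report (lowest-MR tables)
#'
#' For each set size, the `top_k` lowest-MR core sets plus every set tied with
#' the k-th MR; MR is display-rounded to 2 decimals and tied sets share one
#' MR group, the layout of the conventional results table. When a constrained
#' search returns nothing, an explicit no-sets row is emitted.
#'
#' @param search A `coreset_search`.
#' @param top_k Rows per size before tie expansion; defaults to the value
#'   stored in the search config.
#' @return A tibble: `size`, `rank`, `label`, `mr`, `mr_display`, `tie_group`.
#' @export
report_coresets <- function(search, top_k = NULL) {
  top_k <- top_k %||% search$config$top_k
  res <- search$results
  if (nrow(res) == 0) {
    return(tibble::tibble(size = NA_integer_, rank = NA_integer_,
                          label = "no sets satisfy constraint",
                          mr = NA_real_, mr_display = NA_character_,
                          tie_group = NA_integer_))
  }
  out <- dplyr::group_modify(dplyr::group_by(res, .data$size), function(d, key) {
    d <- dplyr::arrange(d, .data$mr, .data$label)
    if (nrow(d) > top_k) {
      cut <- d$mr[top_k]
      d <- d[seq_len(max(top_k, sum(d$mr <= cut))), , drop = FALSE]
    }
    dplyr::mutate(d, rank = dplyr::min_rank(.data$mr),
                  tie_group = dplyr::dense_rank(.data$mr))
  })
  out <- dplyr::ungroup(out)
  dplyr::select(dplyr::mutate(out, mr_display = sprintf("%.2f", .data$mr)),
                "size", "rank", "label", "mr", "mr_display", "tie_group")
}
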