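#' Maximum-likelihood logistic regression with separation handling
#'
#' Fits the binary logistic model by iteratively reweighted least squares.
#' Convergence is declared when the largest coefficient change falls below
#' `tol` or the log-likelihood change below 1e-10; if the coefficient norm
#' exceeds `guard` the data are (quasi-)separated, iteration stops, and the
#' fit is flagged but remains usable for classification through the linear
#' predictor's sign. Standard errors from the Fisher information are reported
#' for converged fits.
#'
#' @param predictors Numeric matrix or data frame (n x p), without an
#'   intercept column; constant columns are rejected by name.
#' @param labels Binary vector (0/1, logical, or a control/stroke factor);
#'   both classes must be present.
#' @param max_iter,tol,guard IRLS controls (defaults 50, 1e-8, 1e4).
#' @return An object of class `gait_logistic`: coefficients (intercept
#'   first), `converged`, `separated`, `iterations`, `loglik`,
#'   `fitted_prob`, `linear_predictor`, `std_error` (NA when flagged).
#' @examples
#' x <- c(rep(1, 8), rep(0, 8))
#' y <- c(rep(1, 6), rep(0, 2), rep(1, 2), rep(0, 6))
#' fit_logistic(matrix(x, ncol = 1), y)$coefficients
#' @export
fit_logistic <- function(predictors, labels, max_iter = 50, tol = 1e-8, guard = 1e4) {
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  y <- if (is.factor(labels) || is.character(labels)) group_indicator(labels)
       else as.integer(labels)
  assert_that(all(y %in% c(0L, 1L)), "`labels` must be binary (0/1).")
  assert_that(nrow(X) == length(y), "predictors and labels differ in length.")
  if (length(unique(y)) < 2) abort("all labels are one class; cannot fit.")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
    abort(paste0("constant predictor column(s): ",
                 paste(nm[sds < 1e-12], collapse = ", ")))
  }
  assert_that(nrow(X) > ncol(X) + 1, "need n > p + 1 observations.")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- irls_fit_cpp(Xi, as.numeric(y), max_iter = max_iter, tol = tol, guard = guard)
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(Xi)
  se <- rep(NA_real_, length(beta))
  if (fit$converged) {
    mu <- stats::plogis(drop(fit$linear_predictor))
    W <- mu * (1 - mu)
    info <- crossprod(Xi * sqrt(W))
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e) se)
  }
  structure(list(coefficients = beta, std_error = setNames(se, names(beta)),
                 converged = fit$converged, separated = fit$separated,
                 iterations = fit$iterations, loglik = fit$loglik,
                 linear_predictor = drop(fit$linear_predictor),
                 fitted_prob = stats::plogis(drop(fit$linear_predictor)),
                 n = nrow(X)),
            class = "gait_logistic")
}

#' @export
print.gait_logistic <- function(x, ...) {
  cat("<gait_logistic>", if (x$separated) "(separation flagged)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.gait_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
                 std_error = unname(x$std_error))
}

#' @export
glance.gait_logistic <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, separated = x$separated, n = x$n)
}

coreset_matrix <- function(table, variables) {
  missing <- setdiff(variables, names(table))
  assert_that(length(missing) == 0,
              paste0("variables not in table: ", paste(missing, collapse = ", ")))
  X <- as.matrix(dplyr::select(tibble::as_tibble(table), dplyr::all_of(variables)))
  storage.mode(X) <- "double"
  assert_that(all(is.finite(X)), "core-set variables must be finite (no NAs).")
  X
}

#' Leave-one-out cross-validated misclassification rate of a core set
#'
#' Each subject is held out in turn; a logistic regression on the core-set
#' variables is fitted to the remaining subjects (with training-fold
#' standardization of predictors, which cannot change the classification),
#' and the held-out subject is classified post-stroke iff the predicted
#' probability strictly exceeds the threshold. The misclassification rate
#' (MR) is the proportion of wrongly classified subjects; the confusion
#' entries are reported as proportions of all subjects, so
#' TP + TN + FP + FN = 1 and MR = FP + FN.
#'
#' @param table Subject variable table with `group` and the variables.
#' @param variables Character vector naming the core-set variables.
#' @param threshold Classification threshold on the predicted probability of
#'   the stroke class; default 0.5, with ties classified as control (strictly
#'   "above" classifies as stroke).
#' @param max_iter,tol,guard IRLS controls, see [fit_logistic()].
#' @return An object of class `coreset_result`: `variables`, `mr`,
#'   `confusion` (tibble of counts and proportions), `per_subject` (tibble of
#'   left-out probabilities and classifications), `n_flagged_folds`, `n`.
#' @examples
#' tab <- simulate_cohort(cohort_spec(), seed = 3)
#' loocv_mr(tab, c("single_support_pct", "pelvis_sag_rom"))$mr
#' @export
loocv_mr <- function(table, variables, threshold = 0.5, max_iter = 50,
                     tol = 1e-8, guard = 1e4) {
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0, 1).")
  y <- group_indicator(table$group)
  assert_that(length(y) >= 6, "need at least 6 subjects for LOOCV.")
  assert_that(sum(y == 1) >= 2 && sum(y == 0) >= 2,
              "each class needs >= 2 members so no training fold loses a class.")
  X <- coreset_matrix(table, variables)
  res <- loocv_cpp(X, as.numeric(y), threshold = threshold, max_iter = max_iter,
                   tol = tol, guard = guard)
  pred <- as.integer(res$predicted)
  per_subject <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(table)) table$subject_id else seq_along(y),
    group = as_group_factor(table$group),
    prob_stroke = as.numeric(res$prob),
    classified = factor(ifelse(pred == 1, "stroke", "control"),
                        levels = c("control", "stroke")),
    correct = pred == y,
    fold_flagged = as.logical(res$flagged))
  structure(list(variables = variables, mr = res$mr,
                 confusion = confusion_counts(y, pred),
                 per_subject = per_subject,
                 n_flagged_folds = sum(res$flagged), n = length(y),
                 threshold = threshold),
            class = "coreset_result")
}

confusion_counts <- function(truth, pred) {
  n <- length(truth)
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tibble::tibble(outcome = c("true_positive", "true_negative",
                             "false_positive", "false_negative"),
                 count = c(tp, tn, fp, fn),
                 proportion = c(tp, tn, fp, fn) / n)
}

#' @export
print.coreset_result <- function(x, ...) {
  cat(sprintf("<coreset_result> {%s}\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  LOOCV MR = %.3f on n = %d (%d separation-flagged folds)\n",
              x$mr, x$n, x$n_flagged_folds))
  invisible(x)
}

#' @export
tidy.coreset_result <- function(x, ...) x$per_subject

#' @export
glance.coreset_result <- function(x, ...) {
  pr <- setNames(x$confusion$proportion, x$confusion$outcome)
  tibble::tibble(mr = x$mr, tp = pr[["true_positive"]], tn = pr[["true_negative"]],
                 fp = pr[["false_positive"]], fn = pr[["false_negative"]],
                 n = x$n, n_flagged_folds = x$n_flagged_folds)
}

#' Confusion-matrix report for a core set
#'
#' Rates of true positive, true negative, false positive and false negative
#' classifications as proportions of all subjects (display-rounded to 2
#' decimals, raw counts retained). Accepts either a [loocv_mr()] result or
#' raw counts.
#'
#' @param result A `coreset_result`, or `NULL` when counts are given.
#' @param tp,tn,fp,fn Raw counts (used when `result` is `NULL`).
#' @return A tibble: `outcome`, `count`, `proportion`, `rate` (2-dp display).
#' @examples
#' confusion_report(tp = 28, tn = 41, fp = 0, fn = 3)
#' @export
confusion_report <- function(result = NULL, tp = NULL, tn = NULL, fp = NULL, fn = NULL) {
  conf <- if (!is.null(result)) {
    assert_that(inherits(result, "coreset_result"), "`result` must be a coreset_result.")
    result$confusion
  } else {
    assert_that(!is.null(tp) && !is.null(tn) && !is.null(fp) && !is.null(fn),
                "supply either `result` or all four counts.")
    n <- tp + tn + fp + fn
    tibble::tibble(outcome = c("true_positive", "true_negative",
                               "false_positive", "false_negative"),
                   count = c(tp, tn, fp, fn),
                   proportion = c(tp, tn, fp, fn) / n)
  }
  dplyr::mutate(conf, rate = round(.data$proportion, 2))
}

#' Enumerate all candidate core sets
#'
#' All subsets of the candidate variables of size 1 up to `max_size`, in
#' deterministic order: by size, then lexicographically by variable names.
#'
#' @param candidates Character vector of distinct variable names.
#' @param max_size Largest subset size (default 4); must not exceed the
#'   number of candidates.
#' @return A list of character vectors.
#' @examples
#' length(enumerate_coresets(letters[1:25], 4))  # 15275
#' @export
enumerate_coresets <- function(candidates, max_size = 4) {
  assert_that(!anyDuplicated(candidates), "`candidates` must be distinct.")
  assert_that(is_count(max_size) && max_size >= 1, "`max_size` must be a positive integer.")
  if (max_size > length(candidates)) {
    abort(sprintf("max_size (%d) exceeds the number of candidates (%d).",
                  max_size, length(candidates)))
  }
  sorted <- sort(candidates)
  out <- list()
  for (k in seq_len(max_size)) {
    sets <- combn(sorted, k, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}
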