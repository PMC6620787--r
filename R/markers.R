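#' Parameters for marker stability selection
#'
#' @param n_trees trees per random forest (selection and per-fold classifier).
#' @param max_iterations cap on shadow-feature iterations.
#' @param alpha two-sided significance level of the binomial confirmation
#'   test against the max-shadow importance.
#' @param frequency_threshold fraction of folds in which an OTU must be
#'   selected to be called a marker ("more than 90%" with the default 0.9).
#' @param seed master RNG seed; per-fold seeds are derived from it.
#' @param tentative_policy what to do with features still undecided at
#'   `max_iterations`: `"drop"` (conservative default) or `"median_fix"`
#'   (keep those whose median importance beats the median max-shadow
#'   importance).
#' @param normalize `"global"` normalizes the whole table once before the
#'   fold split (the order the published pipeline states); `"per_fold"`
#'   renormalizes inside every training fold — the leakage-free variant.
#' @return a `selection_params` list.
#' @export
selection_params <- function(n_trees = 500, max_iterations = 100,
                             alpha = 0.05, frequency_threshold = 0.9,
                             seed = 1,
                             tentative_policy = c("drop", "median_fix"),
                             normalize = c("global", "per_fold")) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (frequency_threshold <= 0 || frequency_threshold > 1)
    stop("frequency_threshold must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 max_iterations = as.integer(max_iterations),
                 alpha = alpha,
                 frequency_threshold = frequency_threshold,
                 seed = as.integer(seed),
                 tentative_policy = match.arg(tentative_policy),
                 normalize = match.arg(normalize)),
            class = "selection_params")
}

#' Minimum fold count that qualifies an OTU as a marker
#'
#' The smallest integer k with k strictly greater than
#' `frequency_threshold * n_folds`: with 54 folds and a "more than 90%"
#' rule this is 49.
#'
#' @param n_folds number of cross-validation folds.
#' @param frequency_threshold fraction in (0, 1].
#' @return integer cutoff.
#' @export
marker_cutoff <- function(n_folds, frequency_threshold = 0.9) {
  if (n_folds < 1) stop("n_folds must be >= 1")
  if (frequency_threshold <= 0 || frequency_threshold > 1)
    stop("frequency_threshold must be in (0, 1]")
  x <- frequency_threshold * n_folds
  # guard the strict inequality against floating error at integer boundaries
  if (isTRUE(all.equal(x, round(x)))) x <- round(x)
  as.integer(floor(x) + 1)
}

# Two-sided binomial decision for a feature that beat the max shadow in
# `hits` of `n` iterations: +1 confirm, -1 reject, 0 still tentative.
binom_decision <- function(hits, n, alpha) {
  if (stats::pbinom(hits - 1, n, 0.5, lower.tail = FALSE) < alpha / 2) return(1L)
  if (stats::pbinom(hits, n, 0.5) < alpha / 2) return(-1L)
  0L
}

#' All-relevant feature selection with shadow features
#'
#' Augments the feature matrix with shuffled "shadow" copies of every live
#' feature, fits a random forest exposing permutation importance (mean
#' decrease in accuracy), and records for each feature whether it beat the
#' best shadow (comparisons use the scaled, Z-score form of the permutation
#' importance; the shadow pool is padded to at least five columns near the
#' end of a run). Across iterations a two-sided binomial test at `alpha`,
#' Bonferroni-adjusted over the number of features, confirms features that
#' beat the shadows significantly more often than chance and rejects those
#' that do so significantly less often; rejected features leave the model. Iteration stops when every feature is decided
#' or `max_iterations` is reached; leftover tentative features are handled
#' per `tentative_policy`.
#'
#' @param X numeric matrix, samples x features, with feature colnames.
#' @param y two-level factor (or coercible) of sample labels.
#' @param params a [selection_params()] list.
#' @return character vector of confirmed feature names.
#' @export
shadow_feature_select <- function(X, y, params = selection_params()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels are single-class")
  if (any(table(y) < 2)) stop("need >= 2 samples per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  with_seed(params$seed, {
    live <- colnames(X)
    hits <- stats::setNames(integer(length(live)), live)
    imp_hist <- stats::setNames(vector("list", length(live)), live)
    shadow_max_hist <- numeric(0)
    confirmed <- character(0)
    iter <- 0L
    alpha_adj <- params$alpha / ncol(X)  # Bonferroni over all features
    while (length(live) > 0 && iter < params$max_iterations) {
      iter <- iter + 1L
      Xl <- X[, live, drop = FALSE]
      # shadow pool: shuffled copy of every live feature, padded to >= 5
      src <- live
      if (length(src) < 5) src <- rep(src, length.out = 5)
      shadows <- vapply(src, function(f) sample(X[, f]),
                        numeric(nrow(X)))
      if (!is.matrix(shadows)) shadows <- matrix(shadows, nrow = nrow(X))
      colnames(shadows) <- paste0(".shadow.", seq_along(src))
      fit <- randomForest::randomForest(cbind(Xl, shadows), y,
                                        ntree = params$n_trees,
                                        importance = TRUE)
      # decisions use the scaled (Z-score) permutation importance
      imp_m <- randomForest::importance(fit, type = 1, scale = TRUE)
      imp <- stats::setNames(imp_m[, 1], rownames(imp_m))
      shadow_max <- max(imp[colnames(shadows)])
      shadow_max_hist <- c(shadow_max_hist, shadow_max)
      hits[live] <- hits[live] + (imp[live] > shadow_max)
      for (f in live) imp_hist[[f]] <- c(imp_hist[[f]], imp[[f]])
      decided <- vapply(live, function(f)
        binom_decision(hits[[f]], iter, alpha_adj), integer(1))
      confirmed <- c(confirmed, live[decided == 1L])
      live <- live[decided == 0L]
    }
    if (length(live) > 0 && params$tentative_policy == "median_fix") {
      keep <- vapply(live, function(f)
        stats::median(imp_hist[[f]]) > stats::median(shadow_max_hist),
        logical(1))
      confirmed <- c(confirmed, live[keep])
    }
    intersect(colnames(X), confirmed)  # restore original column order
  })
}

#' Leave-one-out stability selection of marker OTUs
#'
#' For every sample in a two-group cohort: hold it out, run shadow-feature
#' selection on the remaining samples, fit a random forest on the selected
#' OTUs only, predict the held-out sample, and record the selected OTUs and
#' their permutation-importance ranks (rank 1 = largest mean decrease in
#' accuracy). OTUs selected in at least [marker_cutoff()] folds are the
#' markers.
#'
#' @param table a `daqu_otu_table` whose metadata `group` column has exactly
#'   two levels (subset first if needed); counts are CSS-normalized
#'   internally according to `params$normalize`.
#' @param params a [selection_params()] list.
#' @param css_quantile passed to [css_normalize()].
#' @return a `marker_report`: list with `selected_fold_count`,
#'   `rank_histogram`, `importance_values`, `markers`, `predictions`,
#'   `accuracy`, `cutoff`, `n_folds`, `params`.
#' @export
loocv_markers <- function(table, params = selection_params(),
                          css_quantile = 0.5) {
  stopifnot(inherits(table, "daqu_otu_table"))
  y_all <- factor(table$metadata$group)
  if (nlevels(y_all) != 2) stop("loocv_markers needs exactly two groups")
  if (any(table(y_all) < 3)) stop("need >= 3 samples per class")
  n <- ncol(table$counts)
  otus <- rownames(table$counts)

  if (params$normalize == "global")
    X_global <- t(css_normalize(table, quantile = css_quantile)$normalized)

  fold_seeds <- with_seed(params$seed,
                          sample.int(.Machine$integer.max - 1L, n))
  sel_count <- stats::setNames(integer(length(otus)), otus)
  rank_hist <- stats::setNames(vector("list", length(otus)), otus)
  imp_vals <- stats::setNames(vector("list", length(otus)), otus)
  predictions <- data.frame(sample_id = colnames(table$counts),
                            truth = as.character(y_all),
                            predicted = NA_character_,
                            stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (params$normalize == "per_fold") {
      train_tab <- subset_otu_table(table, samples = colnames(table$counts)[-i])
      X_train <- t(css_normalize(train_tab, quantile = css_quantile)$normalized)
      # held-out sample scaled with its own CSS factor from the full table
      X_test <- t(css_normalize(table, quantile = css_quantile)$normalized)[i, , drop = FALSE]
    } else {
      X_train <- X_global[-i, , drop = FALSE]
      X_test <- X_global[i, , drop = FALSE]
    }
    y_train <- y_all[-i]
    fp <- params
    fp$seed <- fold_seeds[i]
    sel <- shadow_feature_select(X_train, y_train, fp)
    if (length(sel) == 0) next  # fold left unpredicted
    sel_count[sel] <- sel_count[sel] + 1L
    fit <- with_seed(fold_seeds[i],
      randomForest::randomForest(X_train[, sel, drop = FALSE], y_train,
                                 ntree = params$n_trees, importance = TRUE))
    imp <- stats::setNames(fit$importance[, "MeanDecreaseAccuracy"],
                           rownames(fit$importance))
    rk <- rank(-imp, ties.method = "first")
    for (f in sel) {
      rank_hist[[f]] <- c(rank_hist[[f]], rk[[f]])
      imp_vals[[f]] <- c(imp_vals[[f]], imp[[f]])
    }
    predictions$predicted[i] <-
      as.character(stats::predict(fit, X_test[, sel, drop = FALSE]))
  }
  cutoff <- marker_cutoff(n, params$frequency_threshold)
  done <- !is.na(predictions$predicted)
  structure(list(
    selected_fold_count = sel_count,
    rank_histogram = lapply(rank_hist, function(r)
      if (is.null(r)) integer(0) else table(factor(r, levels = seq_len(max(r))))),
    importance_values = imp_vals,
    markers = names(sel_count)[sel_count >= cutoff],
    predictions = predictions,
    accuracy = if (any(done))
      mean(predictions$predicted[done] == predictions$truth[done]) else NA_real_,
    cutoff = cutoff,
    n_folds = n,
    params = params
  ), class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker_report: %d folds, cutoff %d, %d marker(s), accuracy %.3f\n",
              x$n_folds, x$cutoff, length(x$markers), x$accuracy))
  if (length(x$markers) > 0) cat("markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Rank-frequency table of OTUs used across LOOCV classifiers
#'
#' Long-format table of how often each OTU occupied each importance rank,
#' restricted to OTUs used in at least `min_folds` classifiers and ordered
#' by total selection count (descending).
#'
#' @param report a `marker_report`.
#' @param min_folds minimum number of classifiers an OTU must appear in.
#' @return data.frame with columns `otu_id`, `rank`, `frequency`.
#' @export
rank_frequency_table <- function(report, min_folds = 10) {
  stopifnot(inherits(report, "marker_report"))
  used <- report$selected_fold_count[report$selected_fold_count >= min_folds]
  used <- sort(used, decreasing = TRUE)
  rows <- lapply(names(used), function(f) {
    h <- report$rank_histogram[[f]]
    h <- h[h > 0]
    if (length(h) == 0) return(NULL)
    data.frame(otu_id = f, rank = as.integer(names(h)),
               frequency = as.integer(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(otu_id = character(0), rank = integer(0),
                      frequency = integer(0))
  rownames(out) <- NULL
  out
}
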