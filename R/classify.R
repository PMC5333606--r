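#' Configure the classification protocol
#'
#' Settings for the linear-kernel support vector machine and the 10-fold
#' cross-validation / greedy forward-selection protocol. The kernel is fixed
#' to linear so that only linear relationships are mined and the
#' contribution of the network features stays interpretable; the
#' regularization constant is left at its default (no hyperparameter
#' tuning), keeping the comparison about features rather than tuning.
#'
#' @param cost Regularization constant C of the SVM (> 0, default 1).
#' @param standardize Standardize features with training-fold statistics
#'   before the SVM (default `TRUE`); linear SVMs are scale-sensitive and
#'   clinical features have heterogeneous units.
#' @param seed Seed for fold assignment (and any other protocol
#'   randomness).
#' @param n_folds Number of cross-validation folds (>= 2, default 10).
#' @param selection_tolerance Minimum absolute gain in mean CV accuracy for
#'   greedy selection to accept a further feature (default 0.005).
#' @param max_features Cap on the number of greedily selected features.
#' @param network_threshold Binarization threshold on `|w|` for the
#'   per-fold networks (default 0.5).
#' @param kernel Fixed to `"linear"`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(cost = 1, standardize = TRUE, seed = 1L,
                              n_folds = 10L, selection_tolerance = 0.005,
                              max_features = 5L, network_threshold = 0.5,
                              kernel = "linear") {
  kernel <- match.arg(kernel)
  if (!is.numeric(cost) || cost <= 0) abort("config error: cost must be > 0")
  if (n_folds < 2) abort("config error: n_folds must be >= 2")
  if (!is.numeric(network_threshold) || network_threshold < 0) {
    abort("config error: network_threshold must be >= 0")
  }
  if (max_features < 1) abort("config error: max_features must be >= 1")
  structure(list(kernel = kernel, cost = cost, standardize = standardize,
                 seed = as.integer(seed), n_folds = as.integer(n_folds),
                 selection_tolerance = selection_tolerance,
                 max_features = as.integer(max_features),
                 network_threshold = network_threshold),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config> linear SVM, C = ", x$cost,
      ", ", x$n_folds, "-fold CV, |w| > ", x$network_threshold,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Stratified cross-validation fold assignment
#'
#' Randomly partitions the cohort into `n_folds` subsamples, stratified by
#' the class label so that per-class fold sizes differ by at most one (a
#' balanced cohort keeps its balance inside every fold).
#'
#' @param cohort Cohort table with a binary label column.
#' @param config A [classifier_config()] (supplies `n_folds` and `seed`).
#' @param label_col Label column name.
#' @return An integer vector of fold ids (1..n_folds), one per row.
#' @export
make_folds <- function(cohort, config = classifier_config(),
                       label_col = "DEATH") {
  lab <- check_label(cohort, label_col)
  k <- config$n_folds
  for (cl in c(0L, 1L)) {
    n_cl <- sum(lab == cl)
    if (n_cl == 0) abort(paste0("class ", cl, " absent from the cohort"))
    if (n_cl < k) {
      abort(paste0("class ", cl, " has ", n_cl,
                   " subjects; need at least one per fold (", k, ")"))
    }
  }
  folds <- integer(length(lab))
  withr::with_seed(config$seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(lab == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# --- linear SVM engine ------------------------------------------------------

# Train on standardized predictors; y01 in {0,1}. Deterministic. The
# stopping tolerance follows the convention of dual coordinate-descent
# linear-SVM solvers (projected-gradient violation below 0.1).
fit_linear_svc <- function(X, y01, cost, eps = 0.1, max_epochs = 1000L) {
  svc_linear_dcd(X, ifelse(y01 == 1, 1, -1), cost, eps, max_epochs)
}

predict_linear_svc <- function(fit, X) {
  as.integer(drop(X %*% fit$w) + fit$b > 0)
}

# --- fold contexts ----------------------------------------------------------

# Per-fold training artifacts. Everything fitted here (pairwise baselines on
# the training fold's survivors, later the standardization statistics and
# the SVM itself) derives from training rows only; the network features of
# test subjects are computed from the training-fold baseline, so no test
# subject influences any fitted quantity.
.fold_contexts <- function(cohort, folds, config, use_network,
                           label_col = "DEATH", canonical = TRUE) {
  lab <- check_label(cohort, label_col)
  feats <- feature_names_of(cohort, label_col)
  if (use_network && any(c("link_density", "information_content") %in% feats)) {
    abort("cohort feature names collide with the network feature names")
  }
  F <- as.matrix(cohort[, feats, drop = FALSE])
  n_f <- ncol(F)
  ctxs <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    train <- which(folds != f)
    test <- which(folds == f)
    if (length(unique(lab[train])) < 2) {
      abort(paste0("degenerate training fold ", f, ": only one class present"))
    }
    X <- F
    if (use_network) {
      surv <- train[lab[train] == 0L]
      if (length(surv) < 3) {
        abort(paste0("insufficient data: training fold ", f,
                     " has fewer than 3 survivors"))
      }
      model <- fit_baseline(as.data.frame(F[surv, , drop = FALSE]),
                            feature_names = feats)
      pairs <- model$pairs
      nf <- fold_network_features(
        F, match(pairs$feature_k, feats), match(pairs$feature_l, feats),
        ifelse(pairs$degenerate, 0, pairs$alpha),
        ifelse(pairs$degenerate, 0, pairs$beta),
        ifelse(pairs$degenerate, 1, pairs$sigma),
        pairs$degenerate, config$network_threshold)
      ic <- vapply(seq_len(nrow(F)), function(i) {
        ic_from_edges(nf$ki[[i]], nf$li[[i]], n_f, canonical)
      }, numeric(1))
      X <- cbind(F, link_density = nf$density, information_content = ic)
      ctxs[[f]] <- list(train = train, test = test, X = X, model = model)
    } else {
      ctxs[[f]] <- list(train = train, test = test, X = X, model = NULL)
    }
  }
  list(folds = ctxs, y = lab)
}

# Standardization statistics from training rows only.
.scale_stats <- function(Xtr) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

# Accuracy per fold for a given feature subset, reusing precomputed fold
# contexts.
.cv_eval <- function(contexts, features, config) {
  y <- contexts$y
  vapply(contexts$folds, function(ctx) {
    Xtr <- ctx$X[ctx$train, features, drop = FALSE]
    Xte <- ctx$X[ctx$test, features, drop = FALSE]
    if (config$standardize) {
      st <- .scale_stats(Xtr)
      Xtr <- scale(Xtr, st$center, st$scale)
      Xte <- scale(Xte, st$center, st$scale)
    }
    fit <- fit_linear_svc(Xtr, y[ctx$train], config$cost)
    mean(predict_linear_svc(fit, Xte) == y[ctx$test])
  }, numeric(1))
}

new_cv_report <- function(scenario, fold_scores, selected_features,
                          selection_trace = NULL, step_scores = NULL,
                          config = NULL) {
  structure(list(scenario = scenario,
                 fold_scores = fold_scores,
                 mean_score = mean(fold_scores),
                 error = 1 - mean(fold_scores),
                 selected_features = selected_features,
                 selection_trace = selection_trace,
                 step_scores = step_scores,
                 n_folds = length(fold_scores),
                 config = config),
            class = "parenclitic_cv")
}

#' Cross-validated accuracy of a fixed feature set
#'
#' Runs the stratified `n_folds`-fold protocol for the given features. When
#' `use_network_features` is `TRUE`, every fold refits the pairwise
#' baselines on the *training fold's survivors only*, builds and binarizes
#' the deviation networks of both training and test subjects from that
#' baseline, and makes `link_density` and `information_content` available
#' as features — so no test subject ever touches baseline fitting,
#' standardization statistics, or SVM training.
#'
#' @param cohort Cohort table.
#' @param features Character vector of feature names to use (may include
#'   `"link_density"` / `"information_content"` when
#'   `use_network_features = TRUE`).
#' @param config A [classifier_config()].
#' @param use_network_features Recompute per-fold baselines and expose the
#'   two network features.
#' @param label_col Label column name.
#' @return A `parenclitic_cv` report: fold accuracies, their mean, the
#'   error `1 - mean`, and the feature set used. `tidy()` gives per-fold
#'   rows, `glance()` a one-row summary.
#' @export
cross_validate <- function(cohort, features, config = classifier_config(),
                           use_network_features = FALSE,
                           label_col = "DEATH") {
  cohort <- tibble::as_tibble(cohort)
  if (length(features) == 0) abort("no features given")
  avail <- feature_names_of(cohort, label_col)
  if (use_network_features) {
    avail <- c(avail, "link_density", "information_content")
  }
  bad <- setdiff(features, avail)
  if (length(bad) > 0) {
    abort(paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
  }
  folds <- make_folds(cohort, config, label_col)
  contexts <- .fold_contexts(cohort, folds, config, use_network_features,
                             label_col)
  scores <- .cv_eval(contexts, features, config)
  new_cv_report(if (use_network_features) "enhanced" else "raw",
                scores, features, config = config)
}

#' Greedy forward feature selection under cross-validation
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes the mean cross-validated accuracy (ties: first candidate in
#' the supplied order), stopping when the best remaining candidate improves
#' the score by less than `selection_tolerance` or when `max_features` is
#' reached. The same fold partition is used for every evaluation and for
#' the reported score (non-nested selection; see the package vignette for
#' the optimistic-bias caveat).
#'
#' @inheritParams cross_validate
#' @param candidates Candidate feature names, in tie-break order.
#' @return A `parenclitic_cv` report for the selected set, with
#'   `selected_features` (in selection order), `step_scores` (accepted mean
#'   accuracy after each step) and `selection_trace` (a tibble of every
#'   candidate evaluation: `step`, `feature`, `mean_score`).
#' @export
greedy_select <- function(cohort, candidates, config = classifier_config(),
                          use_network_features = FALSE,
                          label_col = "DEATH") {
  cohort <- tibble::as_tibble(cohort)
  if (length(candidates) == 0) abort("empty candidate list")
  avail <- feature_names_of(cohort, label_col)
  if (use_network_features) {
    avail <- c(avail, "link_density", "information_content")
  }
  bad <- setdiff(candidates, avail)
  if (length(bad) > 0) {
    abort(paste0("unknown candidate feature(s): ", paste(bad, collapse = ", ")))
  }
  folds <- make_folds(cohort, config, label_col)
  contexts <- .fold_contexts(cohort, folds, config, use_network_features,
                             label_col)

  selected <- character(0)
  remaining <- candidates
  best_prev <- -Inf
  step_scores <- numeric(0)
  trace <- list()
  best_fold_scores <- NULL
  step <- 0L
  while (length(remaining) > 0 && length(selected) < config$max_features) {
    step <- step + 1L
    cand_means <- numeric(length(remaining))
    cand_folds <- vector("list", length(remaining))
    for (ci in seq_along(remaining)) {
      fs <- .cv_eval(contexts, c(selected, remaining[ci]), config)
      cand_folds[[ci]] <- fs
      cand_means[ci] <- mean(fs)
    }
    trace[[step]] <- tibble::tibble(step = step, feature = remaining,
                                    mean_score = cand_means)
    bi <- which.max(cand_means)  # ties: first in candidate order
    gain <- cand_means[bi] - best_prev
    if (step > 1 && gain < config$selection_tolerance) break
    selected <- c(selected, remaining[bi])
    best_prev <- cand_means[bi]
    best_fold_scores <- cand_folds[[bi]]
    step_scores <- c(step_scores, cand_means[bi])
    remaining <- remaining[-bi]
  }

  new_cv_report(if (use_network_features) "enhanced" else "raw",
                best_fold_scores, selected,
                selection_trace = dplyr::bind_rows(trace),
                step_scores = step_scores, config = config)
}

#' Compare raw-feature and network-enhanced classification
#'
#' Runs the two scenarios on one cohort with a shared fold partition:
#' `raw` (greedy selection over the raw features) and `enhanced` (the same
#' candidates plus the two per-fold network features `link_density` and
#' `information_content`, with the baseline refit on each training fold's
#' survivors). Reports both scores and the relative error reduction
#' `1 - error_enhanced / error_raw`.
#'
#' @inheritParams cross_validate
#' @return An object of class `parenclitic_comparison` with elements `raw`
#'   and `enhanced` (both `parenclitic_cv`) and
#'   `relative_error_reduction`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synthetic_config(n_controls = 150, n_cases = 150,
#'                                            n_numeric = 12, n_binary = 2,
#'                                            seed = 3))
#' cmp <- run_comparison(cohort, classifier_config(seed = 3))
#' glance(cmp)
#' }
#' @export
run_comparison <- function(cohort, config = classifier_config(),
                           label_col = "DEATH") {
  cohort <- tibble::as_tibble(cohort)
  raw_features <- feature_names_of(cohort, label_col)
  raw <- greedy_select(cohort, raw_features, config,
                       use_network_features = FALSE, label_col = label_col)
  enhanced <- greedy_select(cohort,
                            c(raw_features, "link_density", "information_content"),
                            config, use_network_features = TRUE,
                            label_col = label_col)
  rer <- if (raw$error > 0) 1 - enhanced$error / raw$error else NA_real_
  structure(list(raw = raw, enhanced = enhanced,
                 relative_error_reduction = rer),
            class = "parenclitic_comparison")
}

# --- print / tidy methods ---------------------------------------------------

#' @export
print.parenclitic_cv <- function(x, ...) {
  cat("<parenclitic_cv> scenario: ", x$scenario, "\n", sep = "")
  cat("  mean accuracy: ", sprintf("%.4f", x$mean_score),
      "  (error ", sprintf("%.4f", x$error), ", ", x$n_folds, " folds)\n",
      sep = "")
  cat("  features: ", paste(x$selected_features, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `parenclitic_cv`.
#' @param ... Unused.
#' @export
tidy.parenclitic_cv <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_scores), accuracy = x$fold_scores)
}

#' @rdname cross_validate
#' @export
glance.parenclitic_cv <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, mean_score = x$mean_score,
                 error = x$error, n_folds = x$n_folds,
                 n_features = length(x$selected_features))
}

#' @export
print.parenclitic_comparison <- function(x, ...) {
  cat("<parenclitic_comparison>\n")
  cat("  raw:      ", sprintf("%.4f", x$raw$mean_score), " [",
      paste(x$raw$selected_features, collapse = ", "), "]\n", sep = "")
  cat("  enhanced: ", sprintf("%.4f", x$enhanced$mean_score), " [",
      paste(x$enhanced$selected_features, collapse = ", "), "]\n", sep = "")
  cat("  relative error reduction: ",
      sprintf("%.1f%%", 100 * x$relative_error_reduction), "\n", sep = "")
  invisible(x)
}

#' @rdname run_comparison
#' @param x A `parenclitic_comparison`.
#' @param ... Unused.
#' @export
tidy.parenclitic_comparison <- function(x, ...) {
  dplyr::bind_rows(glance(x$raw), glance(x$enhanced))
}

#' @rdname run_comparison
#' @export
glance.parenclitic_comparison <- function(x, ...) {
  tibble::tibble(raw_score = x$raw$mean_score,
                 enhanced_score = x$enhanced$mean_score,
                 raw_error = x$raw$error,
                 enhanced_error = x$enhanced$error,
                 relative_error_reduction = x$relative_error_reduction)
}
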