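#' Fit pairwise linear baselines on a control population
#'
#' For every unordered feature pair \{k, l\} (k before l in `feature_names`
#' order) fits the ordinary least-squares regression of `f_l` on `f_k` over
#' the control subjects, recording the intercept `alpha`, slope `beta`, and
#' `sigma`, the sample standard deviation (denominator n - 1) of the
#' residual vector. These per-pair fits define the "healthy" relation that
#' individual subjects are later compared against; in a survival setting the
#' controls are the surviving patients.
#'
#' Subjects with a missing value for either member of a pair are excluded
#' from that pair's fit (`n_train` is per pair). Pairs with (near) zero
#' predictor variance or (near) zero residual spread are flagged degenerate
#' and never produce links: their Z-scores would be unstable or undefined.
#'
#' @param controls A data frame of control subjects (e.g. the survivor rows
#'   of a cohort table). Non-feature columns `subject_id` and `label_col`
#'   are ignored.
#' @param feature_names Features to model, in the order that defines the
#'   node set. Default: every column except `subject_id` and `label_col`.
#' @param label_col Name of the label column to ignore. Default `"DEATH"`.
#' @param sigma_tol Residual-sd tolerance below which a pair is degenerate.
#' @param var_tol Predictor-variance tolerance below which a pair is
#'   degenerate.
#' @param symmetrize Also fit the reverse regression (`f_k` on `f_l`) for
#'   every pair; [compute_network()] then scores each pair by whichever
#'   direction gives the larger absolute Z-score. The default (`FALSE`)
#'   fits one direction per pair, so a deviated feature shows up most
#'   strongly in pairs where it is the response; the symmetrized variant
#'   makes the deviation visible from both sides at twice the fitting
#'   cost.
#'
#' @return An object of class `parenclitic_baseline`; `tidy()` returns the
#'   per-pair table `(feature_k, feature_l, alpha, beta, sigma, n_train,
#'   degenerate)`.
#' @examples
#' controls <- tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(1.1, 1.9, 3.2, 3.8))
#' tidy(fit_baseline(controls))
#' @export
fit_baseline <- function(controls, feature_names = NULL, label_col = "DEATH",
                         sigma_tol = 1e-8, var_tol = 1e-12,
                         symmetrize = FALSE) {
  controls <- tibble::as_tibble(controls)
  if (is.null(feature_names)) {
    feature_names <- feature_names_of(controls, label_col)
  }
  if (length(feature_names) < 2) {
    abort("need at least 2 features to fit pairwise baselines")
  }
  missing_feats <- setdiff(feature_names, names(controls))
  if (length(missing_feats) > 0) {
    abort(paste0("feature(s) not present: ", paste(missing_feats, collapse = ", ")))
  }
  for (nm in feature_names) {
    if (!is.numeric(controls[[nm]])) {
      abort(paste0("feature '", nm, "' is not numeric"))
    }
  }
  if (nrow(controls) < 3) {
    abort("insufficient data: need at least 3 control subjects")
  }

  F <- as.matrix(controls[, feature_names, drop = FALSE])
  n_f <- ncol(F)
  # center for numerical stability; alpha is mapped back afterwards
  mu <- colMeans(F, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  Fc <- sweep(F, 2, mu)

  obs <- !is.na(Fc)
  F0 <- Fc
  F0[!obs] <- 0
  Mo <- matrix(as.numeric(obs), nrow(F), n_f)
  N <- crossprod(Mo)                #  [k,l] pairwise-complete count
  Sk <- crossprod(F0, Mo)           #  sum f_k over joint rows
  Skk <- crossprod(F0^2, Mo)
  Skl <- crossprod(F0)

  pr <- pair_index(n_f)
  k <- pr$k; l <- pr$l
  n_kl <- N[cbind(k, l)]
  sk <- Sk[cbind(k, l)]; sl <- t(Sk)[cbind(k, l)]
  skk <- Skk[cbind(k, l)]; sll <- t(Skk)[cbind(k, l)]
  skl <- Skl[cbind(k, l)]

  sxx <- skk - sk^2 / n_kl
  syy <- sll - sl^2 / n_kl
  sxy <- skl - sk * sl / n_kl

  fit_direction <- function(sx, sy, sxx_, syy_, sxy_, mu_x, mu_y) {
    ok_n <- n_kl >= 3
    var_x <- ifelse(ok_n, sxx_ / (n_kl - 1), NA_real_)
    beta <- ifelse(ok_n & var_x > var_tol, sxy_ / sxx_, NA_real_)
    alpha_c <- ifelse(is.na(beta), NA_real_, (sy - beta * sx) / n_kl)
    ss_res <- pmax(syy_ - ifelse(is.na(beta), 0, beta) * sxy_, 0)
    sigma <- ifelse(is.na(beta), NA_real_, sqrt(ss_res / (n_kl - 1)))
    degenerate <- !ok_n | is.na(beta) | sigma < sigma_tol
    # back to the original feature location
    list(alpha = unname(alpha_c + mu_y - beta * mu_x), beta = unname(beta),
         sigma = unname(sigma), degenerate = unname(degenerate))
  }

  fwd <- fit_direction(sk, sl, sxx, syy, sxy, mu[k], mu[l])
  pairs <- tibble::tibble(
    feature_k = feature_names[k], feature_l = feature_names[l],
    alpha = fwd$alpha, beta = fwd$beta, sigma = fwd$sigma,
    n_train = as.integer(n_kl), degenerate = fwd$degenerate)
  if (symmetrize) {
    rev <- fit_direction(sl, sk, syy, sxx, sxy, mu[l], mu[k])
    pairs$degenerate_fwd <- fwd$degenerate
    pairs$alpha_rev <- rev$alpha
    pairs$beta_rev <- rev$beta
    pairs$sigma_rev <- rev$sigma
    pairs$degenerate_rev <- rev$degenerate
    # a pair is unusable only if neither direction is fittable
    pairs$degenerate <- fwd$degenerate & rev$degenerate
  }

  structure(
    list(feature_names = feature_names, pairs = pairs,
         sigma_tol = sigma_tol, var_tol = var_tol, symmetrize = symmetrize),
    class = "parenclitic_baseline")
}

#' @export
print.parenclitic_baseline <- function(x, ...) {
  cat("<parenclitic_baseline>\n")
  cat("  features: ", length(x$feature_names), "\n", sep = "")
  cat("  pairs:    ", nrow(x$pairs), " (", sum(x$pairs$degenerate),
      " degenerate)\n", sep = "")
  cat("  n_train:  ", min(x$pairs$n_train), "-", max(x$pairs$n_train),
      " per pair\n", sep = "")
  invisible(x)
}

#' @rdname fit_baseline
#' @param x A `parenclitic_baseline`.
#' @param ... Unused.
#' @export
tidy.parenclitic_baseline <- function(x, ...) x$pairs

#' @rdname fit_baseline
#' @export
glance.parenclitic_baseline <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 n_pairs = nrow(x$pairs),
                 n_degenerate = sum(x$pairs$degenerate),
                 min_n_train = min(x$pairs$n_train),
                 max_n_train = max(x$pairs$n_train))
}

#' Serialize / read a fitted baseline as CSV
#'
#' The on-disk form is the per-pair table `(feature_k, feature_l, alpha,
#' beta, sigma, n_train, degenerate)`; the node order is recovered from the
#' order of first appearance, which matches the fitting order.
#'
#' @param model A `parenclitic_baseline`.
#' @param path File path.
#' @return `write_baseline_csv()` returns `path` invisibly;
#'   `read_baseline_csv()` returns a `parenclitic_baseline`.
#' @export
write_baseline_csv <- function(model, path) {
  stopifnot(inherits(model, "parenclitic_baseline"))
  readr::write_csv(model$pairs, path)
  invisible(path)
}

#' @rdname write_baseline_csv
#' @export
read_baseline_csv <- function(path) {
  pairs <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             feature_k = readr::col_character(),
                             feature_l = readr::col_character(),
                             degenerate = readr::col_logical()))
  # reconstruct node order: first row is pair {1,2}, so feature_k of row 1
  # is the first node; order of first appearance preserves the rest
  feats <- unique(c(pairs$feature_k[1], pairs$feature_l))
  structure(list(feature_names = feats,
                 pairs = tibble::as_tibble(pairs),
                 sigma_tol = 1e-8, var_tol = 1e-12,
                 symmetrize = "alpha_rev" %in% names(pairs)),
            class = "parenclitic_baseline")
}
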