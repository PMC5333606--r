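#' Configure a synthetic cohort with planted pairwise deviations
#'
#' Describes a cohort of `n_controls` survivors and `n_cases` non-survivors
#' over `n_numeric` numeric and `n_binary` binary (0/1) features, built so
#' that the statistical structure assumed by the parenclitic analysis is
#' present by construction: controls follow linear pairwise relations with
#' Gaussian noise, cases deviate from a configurable subset of those
#' relations with a configurable effect size, and optional marginal mean
#' shifts mimic individually prognostic biomarkers such as LDH.
#'
#' By default the numeric features are organised as chains of weakly coupled
#' "lab panel" variables (`f[l] = alpha + beta * f[k] + N(0, noise_sd^2)`
#' along each chain, `|beta|` drawn from 0.35--0.65), four standalone
#' standard-normal features (the first of which carries an LDH-like +0.9
#' marginal shift in cases), and Bernoulli binaries with class-shared rates.
#' The default deviation mechanism adds `effect_size_delta * noise_sd` to the
#' response feature of each perturbed pair with a random sign per case, so
#' case and control marginal means coincide and the class signal lives in
#' the pairwise relations rather than in any single feature.
#'
#' @param n_controls,n_cases Number of surviving / non-surviving subjects.
#' @param n_numeric,n_binary Number of numeric and binary features.
#' @param relation_pairs `"auto"` (default: chain relations drawn from the
#'   seed), `NULL` (no relations), or a data frame with columns
#'   `feature_k`, `feature_l`, `alpha`, `beta` and optionally `noise_sd`.
#'   Each feature may be the response (`feature_l`) of at most one relation.
#' @param noise_sd Residual standard deviation of the relations (used for
#'   any relation pair without its own `noise_sd`). Must be positive.
#' @param perturbed_pairs `"auto"` (a seeded sample of `perturb_fraction`
#'   of the relation pairs), `NULL` (none), or a data frame with columns
#'   `feature_k`, `feature_l`; must be a subset of `relation_pairs`.
#' @param perturb_fraction Fraction of relation pairs perturbed in cases
#'   when `perturbed_pairs = "auto"`.
#' @param effect_size_delta Deviation magnitude in units of the relation's
#'   residual standard deviation.
#' @param deviation Deviation mechanism for cases: `"shift"` (additive shift
#'   of the response by `effect_size_delta * noise_sd`; the default, giving
#'   expected absolute Z-score weights close to `effect_size_delta`),
#'   `"slope"` (the response gains `effect_size_delta * beta * f_k`), or
#'   `"variance"` (extra response noise with sd
#'   `effect_size_delta * noise_sd`).
#' @param deviation_sign `"balanced"` (default; the sign of the shift is
#'   drawn per case, keeping case marginal means equal to controls) or
#'   `"positive"` (all cases shifted upwards). Only used for
#'   `deviation = "shift"`.
#' @param marginal_effect_features `"auto"` (one LDH-like +0.9 shift on the
#'   first standalone numeric feature), `NULL` (none), or a data frame with
#'   columns `feature` and `shift` giving case-vs-control mean shifts.
#' @param binary_rates `"auto"` (class-shared rates drawn uniformly from
#'   0.1--0.5) or a data frame with columns `feature`, `rate_control`,
#'   `rate_case`.
#' @param seed Integer seed; the same configuration and seed always yield a
#'   byte-identical cohort.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()], [ground_truth()]
#' @export
synthetic_config <- function(n_controls = 1000, n_cases = 1000,
                             n_numeric = 80, n_binary = 12,
                             relation_pairs = "auto",
                             noise_sd = 1,
                             perturbed_pairs = "auto",
                             perturb_fraction = 0.1,
                             effect_size_delta = 2,
                             deviation = c("shift", "slope", "variance"),
                             deviation_sign = c("balanced", "positive"),
                             marginal_effect_features = "auto",
                             binary_rates = "auto",
                             seed = 1L) {
  deviation <- match.arg(deviation)
  deviation_sign <- match.arg(deviation_sign)
  if (n_controls < 0 || n_cases < 0) {
    abort("configuration error: n_controls and n_cases must be non-negative")
  }
  if (!is.numeric(noise_sd) || any(noise_sd <= 0)) {
    abort("configuration error: noise_sd must be positive")
  }
  if (n_numeric < 0 || n_binary < 0) {
    abort("configuration error: feature counts must be non-negative")
  }
  if (perturb_fraction < 0 || perturb_fraction > 1) {
    abort("configuration error: perturb_fraction must be in [0, 1]")
  }
  cfg <- structure(
    list(n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
         n_numeric = as.integer(n_numeric), n_binary = as.integer(n_binary),
         relation_pairs = relation_pairs, noise_sd = noise_sd,
         perturbed_pairs = perturbed_pairs,
         perturb_fraction = perturb_fraction,
         effect_size_delta = effect_size_delta,
         deviation = deviation, deviation_sign = deviation_sign,
         marginal_effect_features = marginal_effect_features,
         binary_rates = binary_rates, seed = as.integer(seed)),
    class = "synthetic_config")
  # resolve once to surface configuration errors early
  invisible(withr::with_seed(cfg$seed, .resolve_structure(cfg)))
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  subjects: ", x$n_controls, " controls + ", x$n_cases, " cases\n", sep = "")
  cat("  features: ", x$n_numeric, " numeric + ", x$n_binary, " binary\n", sep = "")
  cat("  deviation: ", x$deviation, " (delta = ", x$effect_size_delta,
      ", sign ", x$deviation_sign, ")\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# Materialize the seeded parts of the design (feature names, relation pairs,
# perturbed subset, binary rates, marginal effects). Caller must have set the
# RNG state; generate_cohort() and ground_truth() both call this first inside
# the same seed so they agree on the resolved structure.
.resolve_structure <- function(config) {
  wid_n <- max(2L, nchar(as.character(max(1L, config$n_numeric))))
  wid_b <- max(2L, nchar(as.character(max(1L, config$n_binary))))
  num_names <- if (config$n_numeric > 0)
    sprintf("num%0*d", wid_n, seq_len(config$n_numeric)) else character()
  bin_names <- if (config$n_binary > 0)
    sprintf("bin%0*d", wid_b, seq_len(config$n_binary)) else character()
  feature_names <- c(num_names, bin_names)

  n_stand <- min(4L, config$n_numeric)
  chainable <- config$n_numeric - n_stand
  standalone <- if (n_stand > 0) num_names[chainable + seq_len(n_stand)] else character()

  rel <- config$relation_pairs
  if (is.character(rel) && identical(rel, "auto")) {
    if (chainable >= 2) {
      n_chains <- max(1L, as.integer(round(chainable / 19)))
      sizes <- rep(chainable %/% n_chains, n_chains) +
        c(rep(1L, chainable %% n_chains), rep(0L, n_chains - chainable %% n_chains))
      starts <- cumsum(c(1L, head(sizes, -1L)))
      kk <- ll <- integer(0)
      for (ci in seq_len(n_chains)) {
        if (sizes[ci] < 2) next
        idx <- starts[ci]:(starts[ci] + sizes[ci] - 1L)
        kk <- c(kk, idx[-length(idx)]); ll <- c(ll, idx[-1L])
      }
      rel <- tibble::tibble(
        feature_k = num_names[kk], feature_l = num_names[ll],
        alpha = stats::runif(length(kk), -0.5, 0.5),
        beta = sample(c(-1, 1), length(kk), replace = TRUE) *
          stats::runif(length(kk), 0.35, 0.65),
        noise_sd = rep(config$noise_sd[1], length(kk)))
    } else {
      rel <- tibble::tibble(feature_k = character(), feature_l = character(),
                            alpha = numeric(), beta = numeric(),
                            noise_sd = numeric())
    }
  } else if (is.null(rel)) {
    rel <- tibble::tibble(feature_k = character(), feature_l = character(),
                          alpha = numeric(), beta = numeric(),
                          noise_sd = numeric())
  } else {
    rel <- tibble::as_tibble(rel)
    if (!all(c("feature_k", "feature_l", "alpha", "beta") %in% names(rel))) {
      abort("configuration error: relation_pairs needs feature_k, feature_l, alpha, beta")
    }
    if (!"noise_sd" %in% names(rel)) rel$noise_sd <- config$noise_sd[1]
    if (any(rel$noise_sd <= 0)) {
      abort("configuration error: noise_sd must be positive")
    }
    bad <- setdiff(c(rel$feature_k, rel$feature_l), feature_names)
    if (length(bad) > 0) {
      abort(paste0("configuration error: unknown feature(s) in relation_pairs: ",
                   paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(rel$feature_l)) {
      abort("configuration error: a feature may be the response of at most one relation")
    }
    if (any(rel$feature_k == rel$feature_l)) {
      abort("configuration error: relation pairs must involve two distinct features")
    }
  }

  pert <- config$perturbed_pairs
  if (is.character(pert) && identical(pert, "auto")) {
    n_pert <- round(config$perturb_fraction * nrow(rel))
    sel <- if (n_pert > 0) sort(sample.int(nrow(rel), n_pert)) else integer()
    pert <- rel[sel, c("feature_k", "feature_l")]
  } else if (is.null(pert)) {
    pert <- tibble::tibble(feature_k = character(), feature_l = character())
  } else {
    pert <- tibble::as_tibble(pert)[, c("feature_k", "feature_l")]
    key_rel <- paste(rel$feature_k, rel$feature_l)
    key_pert <- paste(pert$feature_k, pert$feature_l)
    if (!all(key_pert %in% key_rel)) {
      abort("configuration error: perturbed_pairs must be a subset of relation_pairs")
    }
  }

  rates <- config$binary_rates
  if (is.character(rates) && identical(rates, "auto")) {
    r <- stats::runif(length(bin_names), 0.1, 0.5)
    rates <- tibble::tibble(feature = bin_names, rate_control = r, rate_case = r)
  } else {
    rates <- tibble::as_tibble(rates)
    if (!all(c("feature", "rate_control", "rate_case") %in% names(rates))) {
      abort("configuration error: binary_rates needs feature, rate_control, rate_case")
    }
  }

  marg <- config$marginal_effect_features
  if (is.character(marg) && identical(marg, "auto")) {
    marg <- if (length(standalone) > 0) {
      tibble::tibble(feature = standalone[1], shift = 0.9)
    } else {
      tibble::tibble(feature = character(), shift = numeric())
    }
  } else if (is.null(marg)) {
    marg <- tibble::tibble(feature = character(), shift = numeric())
  } else {
    marg <- tibble::as_tibble(marg)
    if (!all(c("feature", "shift") %in% names(marg))) {
      abort("configuration error: marginal_effect_features needs feature, shift")
    }
  }

  list(feature_names = feature_names, numeric_names = num_names,
       binary_names = bin_names, standalone = standalone,
       relation_pairs = rel, perturbed_pairs = pert,
       binary_rates = rates, marginal_effects = marg)
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort from a [synthetic_config()]: controls satisfy
#' `f_l = alpha + beta * f_k + N(0, noise_sd^2)` for every relation pair,
#' cases additionally deviate on the perturbed pairs, and the configured
#' marginal effects are added to cases. Deviations are applied to the
#' observed feature values after the control-generating process, so a
#' deviated biomarker also disturbs any relation in which it acts as the
#' predictor, as an abnormal measured value would.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `subject_id`, `DEATH` (1 = died) and one
#'   numeric column per feature; controls first. The seed is recorded in the
#'   `"seed"` attribute.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_controls = 50, n_cases = 50,
#'                                            n_numeric = 10, n_binary = 2,
#'                                            seed = 7))
#' dim(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    st <- .resolve_structure(config)
    n <- config$n_controls + config$n_cases
    lab <- rep(c(0L, 1L), c(config$n_controls, config$n_cases))
    n_f <- length(st$feature_names)
    F <- matrix(0, n, n_f, dimnames = list(NULL, st$feature_names))

    responses <- st$relation_pairs$feature_l
    # roots and standalone numerics are standard normal
    for (nm in st$numeric_names) {
      if (!(nm %in% responses)) F[, nm] <- stats::rnorm(n)
    }
    for (i in seq_along(st$binary_names)) {
      nm <- st$binary_names[i]
      if (nm %in% responses) next
      ri <- match(nm, st$binary_rates$feature)
      rate_ctrl <- if (is.na(ri)) 0.3 else st$binary_rates$rate_control[ri]
      rate_case <- if (is.na(ri)) 0.3 else st$binary_rates$rate_case[ri]
      F[, nm] <- stats::rbinom(n, 1, ifelse(lab == 1, rate_case, rate_ctrl))
    }

    # relations in dependency order (each response generated exactly once)
    rel <- st$relation_pairs
    done <- setdiff(st$feature_names, responses)
    remaining <- seq_len(nrow(rel))
    while (length(remaining) > 0) {
      ready <- remaining[rel$feature_k[remaining] %in% done]
      if (length(ready) == 0) {
        abort("configuration error: relation_pairs contain a dependency cycle")
      }
      for (ri in ready) {
        F[, rel$feature_l[ri]] <- rel$alpha[ri] + rel$beta[ri] * F[, rel$feature_k[ri]] +
          stats::rnorm(n, 0, rel$noise_sd[ri])
        done <- c(done, rel$feature_l[ri])
      }
      remaining <- setdiff(remaining, ready)
    }

    # case deviations on perturbed pairs
    cases <- which(lab == 1L)
    if (nrow(st$perturbed_pairs) > 0 && length(cases) > 0) {
      key_rel <- paste(rel$feature_k, rel$feature_l)
      for (pi in seq_len(nrow(st$perturbed_pairs))) {
        ri <- match(paste(st$perturbed_pairs$feature_k[pi],
                          st$perturbed_pairs$feature_l[pi]), key_rel)
        lcol <- rel$feature_l[ri]; kcol <- rel$feature_k[ri]
        sdp <- rel$noise_sd[ri]; delta <- config$effect_size_delta
        if (config$deviation == "shift") {
          sgn <- if (config$deviation_sign == "balanced") {
            sample(c(-1, 1), length(cases), replace = TRUE)
          } else rep(1, length(cases))
          F[cases, lcol] <- F[cases, lcol] + sgn * delta * sdp
        } else if (config$deviation == "slope") {
          F[cases, lcol] <- F[cases, lcol] + delta * rel$beta[ri] * F[cases, kcol]
        } else {
          F[cases, lcol] <- F[cases, lcol] + stats::rnorm(length(cases), 0, delta * sdp)
        }
      }
    }

    if (nrow(st$marginal_effects) > 0 && length(cases) > 0) {
      for (mi in seq_len(nrow(st$marginal_effects))) {
        nm <- st$marginal_effects$feature[mi]
        if (!nm %in% st$feature_names) {
          abort(paste0("configuration error: unknown marginal-effect feature ", nm))
        }
        F[cases, nm] <- F[cases, nm] + st$marginal_effects$shift[mi]
      }
    }

    cohort <- tibble::as_tibble(as.data.frame(F))
    cohort <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%05d", seq_len(n)), DEATH = lab),
      cohort)
    attr(cohort, "seed") <- config$seed
    cohort
  })
}

#' True perturbed pairs of a synthetic configuration
#'
#' Returns the feature pairs whose relation is deviated in cases, resolving
#' any seeded `"auto"` choices exactly as [generate_cohort()] does. Intended
#' for validating recovery of the planted signal.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `feature_k`, `feature_l`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .resolve_structure(config))$perturbed_pairs
}
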