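test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- synthetic_config(n_controls = 60, n_cases = 60, n_numeric = 12,
                          n_binary = 3, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synthetic_config(n_controls = 60, n_cases = 60, n_numeric = 12,
                           n_binary = 3, seed = 12)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("cohort tables respect the configured shape and invariants", {
  cfg <- synthetic_config(n_controls = 80, n_cases = 40, n_numeric = 10,
                          n_binary = 4, seed = 2)
  ch <- generate_cohort(cfg)
  expect_equal(dim(ch), c(120, 2 + 14))
  expect_equal(sum(ch$DEATH == 0), 80)
  expect_equal(sum(ch$DEATH == 1), 40)
  expect_false(anyDuplicated(names(ch)) > 0)
  expect_false(anyDuplicated(ch$subject_id) > 0)
  expect_true(all(is.finite(as.matrix(ch[, -1]))))
  bins <- grep("^bin", names(ch), value = TRUE)
  expect_length(bins, 4)
  expect_true(all(as.matrix(ch[, bins]) %in% c(0, 1)))
})

test_that("controls follow the configured linear relations", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0.7, beta = -1.3, noise_sd = 0.5)
  cfg <- synthetic_config(n_controls = 800, n_cases = 0, n_numeric = 2,
                          n_binary = 0, relation_pairs = rel,
                          perturbed_pairs = NULL,
                          marginal_effect_features = NULL, seed = 4)
  ch <- generate_cohort(cfg)
  fit <- summary(lm(num02 ~ num01, data = ch))
  expect_lt(abs(fit$coefficients["(Intercept)", 1] - 0.7),
            3 * fit$coefficients["(Intercept)", 2])
  expect_lt(abs(fit$coefficients["num01", 1] + 1.3),
            3 * fit$coefficients["num01", 2])
  expect_lt(abs(fit$sigma - 0.5), 0.05)
})

test_that("a zero effect size leaves case and control features exchangeable", {
  cfg <- synthetic_config(n_controls = 400, n_cases = 400, n_numeric = 8,
                          n_binary = 0, effect_size_delta = 0,
                          marginal_effect_features = NULL, seed = 6)
  ch <- generate_cohort(cfg)
  ps <- vapply(grep("^num", names(ch), value = TRUE), function(nm) {
    suppressWarnings(stats::ks.test(ch[[nm]][ch$DEATH == 0],
                                    ch[[nm]][ch$DEATH == 1])$p.value)
  }, numeric(1))
  # no feature should show a significant class difference
  expect_gt(min(ps), 0.01 / length(ps))
})

test_that("a planted deviation of size delta yields |w| near delta on that pair", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0, beta = 1, noise_sd = 1)
  cfg <- synthetic_config(n_controls = 4000, n_cases = 10000, n_numeric = 2,
                          n_binary = 0, relation_pairs = rel,
                          perturbed_pairs = rel[, 1:2],
                          effect_size_delta = 3,
                          marginal_effect_features = NULL, seed = 8)
  ch <- generate_cohort(cfg)
  model <- fit_baseline(dplyr::filter(ch, DEATH == 0))
  W <- parenclitic:::.weights_matrix(
    as.matrix(ch[ch$DEATH == 1, c("num01", "num02")]), model)
  # E|N(+-3, 1)| = 3.0009; Monte-Carlo error ~ 0.01 plus the sigma-hat
  # scale error of the 4000-control baseline (~1.1% of 3); 3 sd ~ 0.11
  expect_lt(abs(mean(abs(W)) - 3), 0.12)
})

test_that("ground_truth returns exactly the perturbed pairs", {
  rel <- tibble::tibble(feature_k = c("num01", "num01", "num02"),
                        feature_l = c("num02", "num03", "num04"),
                        alpha = 0, beta = 1)
  cfg <- synthetic_config(n_numeric = 4, n_binary = 0, relation_pairs = rel,
                          perturbed_pairs = rel[1, 1:2], seed = 1)
  expect_equal(ground_truth(cfg),
               tibble::tibble(feature_k = "num01", feature_l = "num02"))
  cfg0 <- synthetic_config(n_numeric = 4, n_binary = 0, relation_pairs = rel,
                           perturbed_pairs = NULL, seed = 1)
  expect_equal(nrow(ground_truth(cfg0)), 0)
  cfg_auto <- synthetic_config(seed = 3)  # default: 10% of the chain pairs
  gt <- ground_truth(cfg_auto)
  expect_equal(nrow(gt), 7)
  expect_identical(gt, ground_truth(cfg_auto))
})

test_that("invalid configurations fail fast with configuration errors", {
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(n_controls = -5), "non-negative")
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0, beta = 1)
  expect_error(
    synthetic_config(n_numeric = 4, n_binary = 0, relation_pairs = rel,
                     perturbed_pairs = tibble::tibble(feature_k = "num03",
                                                      feature_l = "num04")),
    "subset")
  expect_error(
    synthetic_config(n_numeric = 2, n_binary = 0,
                     relation_pairs = tibble::tibble(
                       feature_k = c("num01", "num02"),
                       feature_l = c("num02", "num02"),
                       alpha = 0, beta = 1)),
    "response")
})

test_that("alternative deviation mechanisms move cases off the relation", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0, beta = 1, noise_sd = 0.5)
  for (dev in c("slope", "variance")) {
    cfg <- synthetic_config(n_controls = 500, n_cases = 500, n_numeric = 2,
                            n_binary = 0, relation_pairs = rel,
                            perturbed_pairs = rel[, 1:2],
                            effect_size_delta = 2, deviation = dev,
                            marginal_effect_features = NULL, seed = 9)
    ch <- generate_cohort(cfg)
    model <- fit_baseline(dplyr::filter(ch, DEATH == 0))
    W <- parenclitic:::.weights_matrix(as.matrix(ch[, c("num01", "num02")]), model)
    expect_gt(mean(abs(W[ch$DEATH == 1, ])), 1.5 * mean(abs(W[ch$DEATH == 0, ])))
  }
})

test_that("a positive-sign shift moves the case marginal, a balanced one does not", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0, beta = 1, noise_sd = 1)
  base <- list(n_controls = 2000, n_cases = 2000, n_numeric = 2, n_binary = 0,
               relation_pairs = rel, perturbed_pairs = rel[, 1:2],
               effect_size_delta = 2, marginal_effect_features = NULL,
               seed = 10)
  pos <- generate_cohort(do.call(synthetic_config,
                                 c(base, deviation_sign = "positive")))
  bal <- generate_cohort(do.call(synthetic_config,
                                 c(base, deviation_sign = "balanced")))
  shift_pos <- mean(pos$num02[pos$DEATH == 1]) - mean(pos$num02[pos$DEATH == 0])
  shift_bal <- mean(bal$num02[bal$DEATH == 1]) - mean(bal$num02[bal$DEATH == 0])
  expect_gt(shift_pos, 1.5)   # delta * noise_sd = 2
  expect_lt(abs(shift_bal), 0.25)
})
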