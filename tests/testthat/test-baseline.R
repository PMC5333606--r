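test_that("the four-point fit matches a hand least-squares computation", {
  controls <- tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(1.1, 1.9, 3.2, 3.8))
  model <- fit_baseline(controls)
  ref <- ols_oracle(controls$f1, controls$f2)
  pr <- model$pairs
  expect_equal(pr$alpha, ref$alpha, tolerance = 1e-12)
  expect_equal(pr$beta, ref$beta, tolerance = 1e-12)
  expect_equal(pr$sigma, ref$sigma, tolerance = 1e-12)
  expect_equal(pr$n_train, 4L)
  expect_false(pr$degenerate)
})

test_that("an exact linear dependence is flagged degenerate", {
  controls <- tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
  pr <- tidy(fit_baseline(controls))
  expect_true(pr$degenerate)
  # constant predictor likewise
  controls2 <- tibble::tibble(f1 = rep(1, 5), f2 = rnorm(5))
  expect_true(tidy(fit_baseline(controls2))$degenerate)
})

test_that("insufficient or non-numeric input is rejected with clear errors", {
  expect_error(fit_baseline(tibble::tibble(f1 = 1:2, f2 = 2:3)),
               "at least 3")
  expect_error(
    fit_baseline(tibble::tibble(f1 = 1:5, f2 = letters[1:5])),
    "'f2' is not numeric")
  expect_error(fit_baseline(tibble::tibble(f1 = 1:5)), "at least 2 features")
})

test_that("fitting generated controls recovers the true parameters", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 0.4, beta = 0.9, noise_sd = 0.6)
  cfg <- synthetic_config(n_controls = 500, n_cases = 0, n_numeric = 2,
                          n_binary = 0, relation_pairs = rel,
                          perturbed_pairs = NULL,
                          marginal_effect_features = NULL, seed = 21)
  ch <- generate_cohort(cfg)
  pr <- tidy(fit_baseline(ch))
  fit <- summary(lm(num02 ~ num01, data = ch))
  expect_lt(abs(pr$alpha - 0.4), 3 * fit$coefficients[1, 2])
  expect_lt(abs(pr$beta - 0.9), 3 * fit$coefficients[2, 2])
  expect_lt(abs(pr$sigma - 0.6), 0.06)
})

test_that("pairs with missing values are fitted on complete observations", {
  set.seed(31)
  controls <- tibble::tibble(f1 = rnorm(40), f2 = rnorm(40), f3 = rnorm(40))
  controls$f2[1:10] <- NA
  pr <- tidy(fit_baseline(controls))
  expect_equal(pr$n_train[pr$feature_k == "f1" & pr$feature_l == "f2"], 30L)
  expect_equal(pr$n_train[pr$feature_k == "f1" & pr$feature_l == "f3"], 40L)
  cc <- !is.na(controls$f2)
  ref <- ols_oracle(controls$f1[cc], controls$f2[cc])
  expect_equal(pr$beta[1], ref$beta, tolerance = 1e-12)
  expect_equal(pr$sigma[1], ref$sigma, tolerance = 1e-12)
})

test_that("network weights follow the printed Z-score formula", {
  model <- manual_baseline(alpha = 0, beta = 2, sigma = 0.5)
  net <- compute_network(c(fk = 2, fl = 10), model)
  expect_equal(net$weight, (10 - (0 + 2 * 2)) / 0.5)  # = 12
})

test_that("a subject on every fitted line has an all-zero network", {
  set.seed(41)
  controls <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30))
  model <- fit_baseline(controls)
  pr <- model$pairs
  subj <- c(f1 = 0.3, f2 = NA, f3 = NA)
  subj["f2"] <- pr$alpha[1] + pr$beta[1] * subj["f1"]
  subj["f3"] <- pr$alpha[2] + pr$beta[2] * subj["f1"]
  # f2-f3 pair will generally not be zero; check the two anchored pairs
  net <- compute_network(subj, model)
  expect_equal(net$weight[1], 0, tolerance = 1e-12)
  expect_equal(net$weight[2], 0, tolerance = 1e-12)
})

test_that("fresh controls have approximately standard normal weights", {
  rel <- tibble::tibble(feature_k = "num01", feature_l = "num02",
                        alpha = 1, beta = 0.8, noise_sd = 0.7)
  cfg <- synthetic_config(n_controls = 6000, n_cases = 0, n_numeric = 2,
                          n_binary = 0, relation_pairs = rel,
                          perturbed_pairs = NULL,
                          marginal_effect_features = NULL, seed = 51)
  ch <- generate_cohort(cfg)
  model <- fit_baseline(ch[1:5000, ])
  W <- parenclitic:::.weights_matrix(as.matrix(ch[5001:6000, c("num01", "num02")]),
                                     model)
  expect_lt(abs(mean(W)), 0.1)
  expect_lt(abs(sd(W) - 1), 0.1)
})

test_that("missing subject values zero the affected pairs with a warning", {
  set.seed(61)
  controls <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30))
  model <- fit_baseline(controls)
  expect_warning(net <- compute_network(c(f1 = NA, f2 = 1, f3 = 1), model),
                 "skipped")
  expect_equal(net$weight[1:2], c(0, 0))  # pairs involving f1
  expect_false(net$weight[3] == 0)
  expect_error(compute_network(c(f1 = 1, f2 = 1), model), "lacks")
})

test_that("degenerate pairs never carry weight or links", {
  controls <- tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8),
                             f3 = c(0.3, 1.2, -0.5, 0.9))
  model <- fit_baseline(controls)
  net <- binarize(compute_network(c(f1 = 10, f2 = -10, f3 = 2), model), 0)
  pr <- model$pairs
  expect_true(pr$degenerate[1])
  expect_equal(net$weight[1], 0)
  expect_false(net$binary[1])
})

test_that("binarization keeps strictly exceeding weights only", {
  nodes <- c("a", "b", "c", "d")
  pr <- parenclitic:::pair_index(4)
  weights <- c(0.5, -0.5, 0.51, -0.7, 0, 0)
  net <- parenclitic:::new_parenclitic_network("S1", nodes, pr$k, pr$l, weights)
  net <- binarize(net, 0.5)
  expect_equal(net$binary, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # threshold zero links every nonzero weight
  net0 <- binarize(net, 0)
  expect_equal(sum(net0$binary), 4)
  expect_error(binarize(net, -1), "non-negative")
})

test_that("raising the threshold never adds links", {
  set.seed(71)
  pr <- parenclitic:::pair_index(8)
  net <- parenclitic:::new_parenclitic_network(
    "S1", sprintf("f%d", 1:8), pr$k, pr$l, rnorm(length(pr$k)))
  counts <- vapply(seq(0, 2.5, by = 0.25),
                   function(th) sum(binarize(net, th)$binary), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline and network agree with a brute-force re-derivation", {
  set.seed(81)
  for (rep in 1:5) {
    n_s <- sample(4:6, 1)
    n_f <- sample(3:4, 1)
    F <- matrix(rnorm(n_s * n_f), n_s, n_f,
                dimnames = list(NULL, sprintf("f%d", 1:n_f)))
    model <- fit_baseline(tibble::as_tibble(as.data.frame(F)))
    subj <- rnorm(n_f)
    names(subj) <- colnames(F)
    net <- compute_network(subj, model)
    pr <- model$pairs
    for (p in seq_len(nrow(pr))) {
      ref <- ols_oracle(F[, pr$feature_k[p]], F[, pr$feature_l[p]])
      expect_lt(abs(pr$alpha[p] - ref$alpha), 1e-10)
      expect_lt(abs(pr$beta[p] - ref$beta), 1e-10)
      expect_lt(abs(pr$sigma[p] - ref$sigma), 1e-10)
      w_ref <- (subj[pr$feature_l[p]] -
                  (ref$alpha + ref$beta * subj[pr$feature_k[p]])) / ref$sigma
      expect_lt(abs(net$weight[p] - w_ref), 1e-10)
    }
  }
})

test_that("case networks are denser than control networks under strong deviations", {
  # deviated features placed mid/late chain so that a representative number
  # of pairs see them as the response; with one regression per pair a
  # deviation surfaces in pairs where the feature is the response, not
  # where it predicts an uncorrelated partner
  pert <- tibble::tibble(feature_k = c("num09", "num15"),
                         feature_l = c("num10", "num16"))
  cfg <- synthetic_config(n_controls = 400, n_cases = 200, n_numeric = 20,
                          n_binary = 0, effect_size_delta = 3,
                          perturbed_pairs = pert,
                          marginal_effect_features = NULL, seed = 91)
  ch <- generate_cohort(cfg)
  model <- fit_baseline(ch[ch$DEATH == 0, ][1:200, ])
  nets <- compute_networks(ch, model, threshold = 0.5)
  feats <- featurize(nets, canonical = FALSE)
  dens <- feats$link_density
  tt <- t.test(dens[ch$DEATH == 1], dens[ch$DEATH == 0], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("baseline CSV serialization round-trips", {
  set.seed(101)
  controls <- tibble::as_tibble(as.data.frame(matrix(rnorm(200), 50, 4)))
  model <- fit_baseline(controls)
  path <- withr::local_tempfile(fileext = ".csv")
  write_baseline_csv(model, path)
  model2 <- read_baseline_csv(path)
  expect_equal(model2$feature_names, model$feature_names)
  expect_equal(model2$pairs$alpha, model$pairs$alpha, tolerance = 1e-12)
  expect_equal(model2$pairs$degenerate, model$pairs$degenerate)
})

test_that("a symmetrized baseline scores each pair by its larger deviation", {
  set.seed(111)
  controls <- tibble::tibble(f1 = rnorm(60), f2 = rnorm(60))
  model <- fit_baseline(controls, symmetrize = TRUE)
  fwd <- ols_oracle(controls$f1, controls$f2)
  rev <- ols_oracle(controls$f2, controls$f1)
  pr <- model$pairs
  expect_equal(pr$beta, fwd$beta, tolerance = 1e-12)
  expect_equal(pr$beta_rev, rev$beta, tolerance = 1e-12)
  subj <- c(f1 = 2.5, f2 = -1)
  w_f <- (subj["f2"] - fwd$alpha - fwd$beta * subj["f1"]) / fwd$sigma
  w_r <- (subj["f1"] - rev$alpha - rev$beta * subj["f2"]) / rev$sigma
  net <- compute_network(subj, model)
  expect_equal(net$weight, unname(if (abs(w_r) > abs(w_f)) w_r else w_f),
               tolerance = 1e-12)
})
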