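test_that("k = 1 fit equals the closed-form Gaussian MLE", {
  withr::with_seed(7, x <- rnorm(200, 0.7, 0.1))
  fit <- fit_gmm(x, k = 1)
  oracle <- oracle_normal_mle(x)
  expect_equal(fit$means, oracle$mean, tolerance = 1e-10)
  expect_equal(fit$sds, oracle$sd, tolerance = 1e-10)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-10)
  expect_equal(fit$weights, 1)
  expect_equal(fit$bic, -2 * oracle$loglik + 2 * log(200))
})

test_that("EM recovers well-separated clusters to per-cluster moments", {
  withr::with_seed(3, {
    lo <- rnorm(50, 0.2, 0.01)
    hi <- rnorm(50, 0.8, 0.01)
  })
  fit <- fit_gmm(c(lo, hi), k = 2, seed = 3)
  expect_true(fit$converged)
  # with essentially no overlap the mixture MLE equals cluster-wise MLE
  expect_equal(fit$means, c(mean(lo), mean(hi)), tolerance = 1e-6)
  expect_equal(fit$sds, c(sd_mle_oracle(lo), sd_mle_oracle(hi)),
               tolerance = 1e-4)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(abs(diff(fit$means)) - 0.6, 0.01)
  # components come back ordered by ascending mean
  expect_true(diff(fit$means) > 0)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  low <- match_low_component()
  for (s in 1:5) {
    smp <- sample_mmp_mixture(400, c(low$mu_low, 0.734),
                              c(low$sd_low, 0.085), c(0.09, 0.91), seed = s)
    fit <- fit_gmm(smp$values, k = 2, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9 * abs(fit$loglik)))
    expect_true(fit$converged)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  }
})

test_that("mixture parameters are recovered across many seeded samples", {
  # separation >= 3 SDs, n = 500: means within 0.02 and weights within
  # 0.05 of truth in at least 90% of 50 replicates
  truth_means <- c(0.3, 0.75)
  truth_sds <- c(0.05, 0.08)
  truth_w <- c(0.35, 0.65)
  ok <- logical(50)
  for (s in 1:50) {
    smp <- sample_mmp_mixture(500, truth_means, truth_sds, truth_w, seed = s)
    fit <- fit_gmm(smp$values, k = 2, seed = s)
    ok[s] <- all(abs(fit$means - truth_means) <= 0.02) &&
      all(abs(fit$weights - truth_w) <= 0.05)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust") # Mclust resolves helpers when attached
  low <- match_low_component()
  smp <- sample_mmp_mixture(800, c(low$mu_low, 0.734), c(low$sd_low, 0.085),
                            c(0.09, 0.91), seed = 4)
  fit <- fit_gmm(smp$values, k = 2, seed = 4)
  mc <- mclust::Mclust(smp$values, G = 2, modelNames = "V", verbose = FALSE)
  # the two EMs stop at slightly different points of the same optimum;
  # ours must never be worse than the reference
  expect_gte(fit$loglik, mc$loglik - 1e-6)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-5)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(sort(fit$sds),
               sort(sqrt(as.numeric(mc$parameters$variance$sigmasq))),
               tolerance = 0.01)
})

test_that("modality assessment separates the two screen shapes", {
  # a single Gaussian the size and shape of the siRNA screen is unimodal
  withr::with_seed(21, x1 <- rnorm(336, 0.710, 0.084))
  a1 <- assess_modality(x1, seed = 21)
  expect_equal(a1$label, "unimodal")

  # the published drug-screen mixture is bimodal
  low <- match_low_component()
  smp <- sample_mmp_mixture(1134, c(low$mu_low, 0.734), c(low$sd_low, 0.085),
                            c(0.09, 0.91), seed = 2)
  a2 <- assess_modality(smp$values, seed = 2)
  expect_equal(a2$label, "bimodal")
  expect_gt(a2$delta_bic, 10)
  expect_gte(a2$min_weight, 0.05)
  expect_gte(a2$separation, 2)

  # 50/50 clusters six SDs apart: brute-force likelihood at the true
  # parameters already beats the single Gaussian by far more than the
  # BIC penalty difference
  smp3 <- sample_mmp_mixture(300, c(0.3, 0.9), c(0.1, 0.1), c(0.5, 0.5),
                             seed = 3)
  a3 <- assess_modality(smp3$values, seed = 3)
  expect_equal(a3$label, "bimodal")
  ll_true <- mixture_loglik(smp3$values, c(0.5, 0.5), c(0.3, 0.9),
                            c(0.1, 0.1))
  ll_one <- oracle_normal_mle(smp3$values)$loglik
  oracle_delta_bic <- (-2 * ll_one + 2 * log(300)) -
    (-2 * ll_true + 5 * log(300))
  expect_gt(oracle_delta_bic, 10)
})

test_that("pooled 2-SD rule matches a brute-force threshold", {
  values <- c(rep(0.70, 98), 0.71, 1.50)
  agg <- tibble::tibble(treatment_id = sprintf("T%03d", 1:100),
                        aggregate = values)
  assessment <- structure(list(label = "unimodal"),
                          class = "modality_assessment")
  res <- call_hits(agg, assessment)
  expect_equal(res$rule, "pooled_sd")
  expect_equal(res$pooled_mean, mean(values))
  expect_equal(round(res$threshold, 3), 0.868)
  expect_equal(res$hits$treatment_id, "T100")
  expect_equal(res$n_hits, 1)
  # brute force: exactly the values at or above mean + 2 sd
  expect_equal(sort(res$hits$value),
               sort(values[values >= mean(values) + 2 * sd(values)]))

  # all values below the threshold: empty hit set
  agg2 <- tibble::tibble(treatment_id = c("A", "B", "C"),
                         aggregate = c(0.7, 0.71, 0.72))
  res2 <- call_hits(agg2, assessment)
  expect_equal(res2$n_hits, 0)
  expect_equal(nrow(res2$hits), 0)
})

test_that("hit threshold arithmetic reproduces the published cutoffs", {
  # pooled rule: sample affinely standardized to mean 0.710 / SD 0.084
  withr::with_seed(9, raw <- rnorm(336))
  x <- (raw - mean(raw)) / sd(raw) * 0.084 + 0.710
  agg <- tibble::tibble(treatment_id = sprintf("g%03d", seq_along(x)),
                        aggregate = x)
  assessment <- structure(list(label = "unimodal"),
                          class = "modality_assessment")
  res <- call_hits(agg, assessment)
  expect_equal(res$threshold, 0.879, tolerance = 0.002)

  # mixture-component rule with the published dominant component:
  # mu + 2 sigma lands on the published 0.903 cutoff
  fit <- structure(list(k = 2L, weights = c(0.09, 0.91),
                        means = c(0.212, 0.734), sds = c(0.106, 0.085),
                        noise_weight = 0, converged = TRUE),
                   class = "mixture_fit")
  small <- tibble::tibble(treatment_id = c("a", "b"),
                          aggregate = c(0.7, 0.75)) # too few members:
  bimodal <- structure(list(label = "bimodal"),    # falls back to fit params
                       class = "modality_assessment")
  res2 <- call_hits(small, bimodal, fit)
  expect_equal(res2$threshold, 0.903, tolerance = 0.002)
  expect_error(call_hits(small, bimodal, fit = NULL),
               class = "mmpscreen_missing_model")
})

test_that("raising a hit's value never removes it from the hit set", {
  g <- gen_drug_screen(seed = 6)
  agg <- aggregate_replicates(normalize_screen(g$dataset))
  assessment <- assess_modality(agg$aggregate, seed = 6)
  res <- call_hits(agg, assessment, assessment$fit2)
  expect_gt(res$n_hits, 0)
  top <- res$hits$treatment_id[1]
  agg2 <- dplyr::mutate(agg, aggregate = ifelse(treatment_id == top,
                                                aggregate + 0.2, aggregate))
  res2 <- call_hits(agg2, assessment, assessment$fit2)
  expect_true(top %in% res2$hits$treatment_id)
})

test_that("screen reports propagate rule, fit and QC fields", {
  g <- gen_sirna_screen(seed = 2)
  pipe <- run_screen_pipeline(g$dataset, seed = 2)
  rep <- screen_report(pipe$result, pipe$qc, pipe$aggregated)
  expect_equal(rep$rule, "pooled_sd")
  expect_equal(rep$n_hits, nrow(rep$hits))
  expect_equal(nrow(rep$scatter), nrow(pipe$aggregated))
  expect_equal(sum(rep$scatter$is_hit), rep$n_hits)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_screen_report(rep, json, csv)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$rule, "pooled_sd")
  expect_equal(parsed$n_hits, rep$n_hits)

  # empty hit list round-trips as an empty table
  agg0 <- tibble::tibble(treatment_id = letters[1:21],
                         aggregate = seq(0.6, 0.8, length.out = 21))
  assessment <- structure(list(label = "unimodal"),
                          class = "modality_assessment")
  res0 <- call_hits(agg0, assessment)
  rep0 <- screen_report(res0, pipe$qc, agg0)
  expect_equal(rep0$n_hits, res0$n_hits)
})
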