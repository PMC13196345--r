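test_that("moment matching of the low component agrees with a Monte-Carlo oracle", {
  low <- match_low_component(mu_pool = 0.687, sd_pool = 0.173,
                             mu_high = 0.734, sd_high = 0.085,
                             w_high = 0.91)
  expect_equal(low$mu_low, (0.687 - 0.91 * 0.734) / 0.09, tolerance = 1e-12)
  # brute-force: a large seeded sample from the assembled mixture must
  # reproduce the pooled moments it was matched to
  n <- 4e5
  smp <- sample_mmp_mixture(n, c(low$mu_low, 0.734), c(low$sd_low, 0.085),
                            c(0.09, 0.91), seed = 77)
  se_mean <- 0.173 / sqrt(n)
  expect_lt(abs(mean(smp$values) - 0.687), 3 * se_mean)
  expect_lt(abs(sd(smp$values) - 0.173), 3 * 0.173 / sqrt(2 * n))
  expect_error(match_low_component(w_high = 1),
               class = "mmpscreen_config_error")
  # incompatible pooled SD: implied low-component variance negative
  expect_error(match_low_component(sd_pool = 0.05),
               class = "mmpscreen_config_error")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_drug_screen(seed = 4), gen_drug_screen(seed = 4))
  expect_identical(gen_sirna_screen(seed = 4), gen_sirna_screen(seed = 4))
  expect_identical(gen_ratio_image(n_cells = 5, seed = 4),
                   gen_ratio_image(n_cells = 5, seed = 4))
  expect_identical(gen_mito_mask(n_objects = 6, seed = 4),
                   gen_mito_mask(n_objects = 6, seed = 4))
  expect_identical(gen_calcium_traces(4, 0.5, 1, 2, seed = 4),
                   gen_calcium_traces(4, 0.5, 1, 2, seed = 4))
  expect_identical(gen_neuron_tree(seed = 4), gen_neuron_tree(seed = 4))
  # different seeds give different data
  expect_false(identical(gen_drug_screen(seed = 4)$dataset$wells$f590,
                         gen_drug_screen(seed = 5)$dataset$wells$f590))
})

test_that("drug screen has the published size, layout and planted truth", {
  g <- gen_drug_screen(seed = 8)
  w <- g$dataset$wells
  expect_equal(length(unique(w$treatment_id[w$role == "treatment"])), 1134)
  expect_equal(length(unique(w$plate_id)), 26) # 13 duplicated plates
  expect_silent(validate_screen(g$dataset))
  expect_equal(sum(g$truth$treatments$class == "planted_hit"), 20)
  expect_true(all(g$truth$treatments$true_value[
    g$truth$treatments$class == "planted_hit"] >= 0.95))
  expect_true(all(g$truth$treatments$true_value[
    g$truth$treatments$class != "planted_hit"] < 0.90))
  # ground truth joins 1:1 to pipeline output
  agg <- aggregate_replicates(normalize_screen(g$dataset))
  expect_setequal(agg$treatment_id, g$truth$treatments$treatment_id)
  joined <- dplyr::inner_join(agg, g$truth$treatments, by = "treatment_id")
  # duplicate aggregation recovers the drawn value exactly by construction
  expect_equal(joined$aggregate, joined$true_value, tolerance = 1e-12)
})

test_that("siRNA screen has the published size and planted truth", {
  g <- gen_sirna_screen(seed = 8)
  w <- g$dataset$wells
  expect_equal(length(unique(w$treatment_id[w$role == "treatment"])), 336)
  expect_silent(validate_screen(g$dataset))
  expect_equal(sum(g$truth$treatments$class == "planted_hit"), 9)
  expect_equal(sum(w$role == "fccp_control"), 0)
})

test_that("uncapped background reproduces the published pooled moments", {
  cfg <- drug_screen_config(n_planted = 0, background_cap = Inf)
  means <- sapply(1:5, function(s) {
    agg <- aggregate_replicates(normalize_screen(gen_drug_screen(cfg,
                                                                 seed = s)$dataset))
    mean(agg$aggregate)
  })
  se <- 0.173 / sqrt(1134)
  expect_lt(abs(mean(means) - 0.687), 3 * se / sqrt(5))

  scfg <- sirna_screen_config(n_planted = 0, tail_fraction = 0,
                              background_cap = Inf)
  smeans <- sapply(1:5, function(s) {
    agg <- aggregate_replicates(normalize_screen(gen_sirna_screen(scfg,
                                                                  seed = s)$dataset))
    mean(agg$aggregate)
  })
  sse <- 0.084 / sqrt(336)
  expect_lt(abs(mean(smeans) - 0.710), 3 * sse / sqrt(5))
})

test_that("infeasible screen configs are rejected", {
  expect_error(drug_screen_config(planted_range = c(0.85, 1.2)),
               class = "mmpscreen_config_error")
  expect_error(drug_screen_config(n_compounds = 10, n_planted = 20),
               class = "mmpscreen_config_error")
})

test_that("ratio-image generator honours planted cells and noise settings", {
  blank <- gen_ratio_image(n_cells = 0, noise_sigma = 0, seed = 1)
  expect_equal(max(blank$image$red), blank$image$red[1, 1]) # flat background
  expect_equal(nrow(blank$truth), 0)
  one <- gen_ratio_image(n_cells = 1, ratios = 2, noise_sigma = 0, seed = 2)
  cs <- per_cell_ratio(one$image, segment_cells(one$image))
  expect_equal(cs$per_cell$ratio, 2)
  # overcrowding raises a placement error
  expect_error(gen_ratio_image(n_cells = 100, size = 64, seed = 1),
               class = "mmpscreen_placement_error")
})

test_that("mito-mask generator produces measurable objects with known axes", {
  g <- gen_mito_mask(n_objects = 10, ars = 1, minor_range = c(6, 9),
                     seed = 5)
  objs <- label_mitochondria(g$mask)
  expect_equal(nrow(objs), 10)
  expect_true(all(objs$aspect_ratio >= 1))
  expect_lte(mean(objs$aspect_ratio), 1.05)
})

test_that("calcium generator oscillation flags drive trace content", {
  g <- gen_calcium_traces(30, p_oscillating = 0, rate_per_min = 2,
                          amplitude_mean = 3, seed = 6)
  expect_true(all(g$truth$n_events == 0))
  g2 <- gen_calcium_traces(30, p_oscillating = 1, rate_per_min = 2,
                           amplitude_mean = 3, seed = 6)
  expect_gt(mean(g2$truth$n_events), 5)
  # planted event spacing respects the refractory interval
  spacings <- unlist(lapply(g2$truth$event_times, diff))
  expect_true(all(spacings >= 12))
  expect_error(gen_calcium_traces(5, 0.5, 1, 2, dt_s = 0),
               class = "mmpscreen_config_error")
})

test_that("neuron-tree generator truth matches its own bookkeeping", {
  g1 <- gen_neuron_tree(depth = 1, segment_length_mean = 100,
                        segment_length_sd = 0, seed = 1)
  expect_equal(g1$truth$total_length, 100)
  expect_equal(g1$truth$n_terminals, 1)
  expect_equal(total_length(g1$tree), 100, tolerance = 1e-12)
  expect_error(gen_neuron_tree(depth = 0), class = "mmpscreen_config_error")
})
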