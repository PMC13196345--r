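test_that("8-connected labeling finds disjoint components", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:10] <- TRUE
  m[25:30, 25:30] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  # diagonal contact joins components (ImageJ convention)
  d <- matrix(FALSE, 10, 10)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(max(label_components(d)), 1)
  expect_equal(max(label_components(matrix(FALSE, 5, 5))), 0)
  # min_area filters small specks
  expect_equal(max(label_components(d, min_area = 3)), 0)
})

test_that("cell segmentation recovers planted discs", {
  g <- gen_ratio_image(n_cells = 12, seed = 3)
  lab <- segment_cells(g$image)
  expect_equal(max(lab), 12)
  blank <- ratio_image(matrix(0, 32, 32), matrix(0, 32, 32))
  expect_warning(lab0 <- segment_cells(blank), "no foreground")
  expect_equal(max(lab0), 0)
})

test_that("per-cell ratio is the ratio of channel means", {
  # uniform red = green: every ratio 1
  g <- gen_ratio_image(n_cells = 3, ratios = 1, noise_sigma = 0, seed = 1)
  cs <- per_cell_ratio(g$image, segment_cells(g$image))
  expect_equal(cs$per_cell$ratio, rep(1, 3))
  expect_equal(cs$image_mean, 1)

  # planted per-cell ratios 1 and 3, noise free: image mean 2 exactly
  g2 <- gen_ratio_image(n_cells = 2, ratios = c(1, 3), noise_sigma = 0,
                        seed = 2)
  cs2 <- per_cell_ratio(g2$image, segment_cells(g2$image))
  expect_equal(sort(cs2$per_cell$ratio), c(1, 3))
  expect_equal(cs2$image_mean, 2)

  # noisy case: recovered ratios within 3% of truth (matched by position)
  g3 <- gen_ratio_image(n_cells = 12, noise_sigma = 0.02, seed = 4)
  lab3 <- segment_cells(g3$image)
  cs3 <- per_cell_ratio(g3$image, lab3)
  expect_equal(cs3$n_cells, 12)
  for (i in seq_len(nrow(g3$truth))) {
    id <- lab3[round(g3$truth$cy[i]), round(g3$truth$cx[i])]
    got <- cs3$per_cell$ratio[cs3$per_cell$label == id]
    expect_equal(got, g3$truth$ratio[i], tolerance = 0.03)
  }
})

test_that("ratio quantification respects channel scaling", {
  g <- gen_ratio_image(n_cells = 4, seed = 5)
  lab <- segment_cells(g$image)
  base <- per_cell_ratio(g$image, lab)
  both <- ratio_image(g$image$red * 3.7, g$image$green * 3.7)
  expect_equal(per_cell_ratio(both, lab)$per_cell$ratio,
               base$per_cell$ratio, tolerance = 1e-12)
  red_only <- ratio_image(g$image$red * 2.5, g$image$green)
  expect_equal(per_cell_ratio(red_only, lab)$per_cell$ratio,
               base$per_cell$ratio * 2.5, tolerance = 1e-12)
})

test_that("AR and FF of canonical rasterized shapes are calibrated", {
  # disc: rotationally symmetric, FF near the circular minimum of 1
  md <- label_mitochondria(disc_mask(20))
  expect_equal(nrow(md), 1)
  expect_gte(md$aspect_ratio, 1.0)
  expect_lte(md$aspect_ratio, 1.05)
  expect_gte(md$form_factor, 0.95)
  expect_lte(md$form_factor, 1.10)

  # axis-aligned ellipse with semi-axes (20, 5): AR close to 4 (thin
  # objects rasterize with about half-pixel edge loss on the minor axis)
  me <- label_mitochondria(ellipse_mask(20, 5))
  expect_equal(me$aspect_ratio, 4.0, tolerance = 0.08)

  # filled 40 x 4 rectangle: FF from the boundary-polygon perimeter
  mr <- label_mitochondria(rect_mask(4, 40))
  expect_equal(mr$form_factor, 3.85, tolerance = 0.4 / 3.85)
  expect_equal(mr$aspect_ratio, 10, tolerance = 0.01)

  # empty mask: empty result
  expect_equal(nrow(label_mitochondria(matrix(FALSE, 10, 10))), 0)
})

test_that("moments agree with an independent image-feature oracle", {
  shapes <- list(disc_mask(15), ellipse_mask(18, 6), ellipse_mask(12, 8),
                 ellipse_mask(16, 5, theta = pi / 5))
  for (m in shapes) {
    mine <- label_mitochondria(m)
    ft <- EBImage::computeFeatures.moment(m * 1)
    expect_equal(mine$major_axis, unname(ft[1, "m.majoraxis"]),
                 tolerance = 0.01)
    ecc <- unname(ft[1, "m.eccentricity"])
    oracle_ar <- 1 / sqrt(1 - ecc^2)
    expect_equal(mine$aspect_ratio, oracle_ar, tolerance = 0.02)
    expect_equal(mine$area, sum(m > 0))
  }
})

test_that("AR and FF are invariant to translation and 90-degree rotation", {
  m <- ellipse_mask(16, 5, theta = pi / 7)
  base <- label_mitochondria(m)
  shifted <- matrix(FALSE, nrow(m) + 10, ncol(m) + 10)
  shifted[6:(nrow(m) + 5), 9:(ncol(m) + 8)] <- m
  tr <- label_mitochondria(shifted)
  expect_equal(tr$aspect_ratio, base$aspect_ratio, tolerance = 1e-12)
  expect_equal(tr$form_factor, base$form_factor, tolerance = 1e-12)
  rot <- label_mitochondria(t(m)[ncol(m):1, ]) # 90-degree rotation
  expect_equal(rot$aspect_ratio, base$aspect_ratio, tolerance = 0.05)
  expect_equal(rot$form_factor, base$form_factor, tolerance = 0.05)
})

test_that("computed AR increases strictly with true elongation", {
  ars <- sapply(c(1.5, 2, 3, 4, 5), function(k) {
    label_mitochondria(ellipse_mask(6 * k, 6))$aspect_ratio
  })
  expect_true(all(diff(ars) > 0))
})

test_that("the disc minimizes FF among equal-area shapes", {
  disc <- label_mitochondria(disc_mask(12))
  # elongated ellipse of (nearly) equal area
  ell <- label_mitochondria(ellipse_mask(24, 6))
  expect_lte(disc$form_factor, ell$form_factor + 0.05)
})

test_that("morphology summaries average object shape metrics", {
  m <- gen_mito_mask(n_objects = 8, ars = c(2, 4), seed = 7)
  objs <- label_mitochondria(m$mask)
  expect_equal(nrow(objs), 8)
  s <- morphology_summary(objs)
  expect_equal(s$n_objects, 8)
  expect_equal(s$mean_ar, mean(objs$aspect_ratio))
  # measured ARs within 8% of the generator truth (matched by centroid)
  expect_equal(s$mean_ar, 3, tolerance = 0.08)

  one <- label_mitochondria(disc_mask(10))
  s1 <- morphology_summary(one)
  expect_equal(s1$mean_ar, one$aspect_ratio)
  expect_error(morphology_summary(one[0, ]),
               class = "mmpscreen_undefined_summary")

  # fragmentation direction: less elongated population has lower mean AR
  frag <- label_mitochondria(gen_mito_mask(12, ar_mean = 1.3, ar_sd = 0.1,
                                           seed = 8)$mask)
  tub <- label_mitochondria(gen_mito_mask(12, ar_mean = 3.5, ar_sd = 0.3,
                                          seed = 8)$mask)
  expect_lt(mean(frag$aspect_ratio), mean(tub$aspect_ratio))
})

test_that("two-page TIFF round trip preserves ratiometric content", {
  g <- gen_ratio_image(n_cells = 4, seed = 9, size = 96)
  path <- withr::local_tempfile(fileext = ".tif")
  write_ratio_tiff(g$image, path)
  img2 <- read_ratio_tiff(path)
  lab <- segment_cells(g$image)
  expect_equal(per_cell_ratio(img2, lab)$per_cell$ratio,
               per_cell_ratio(g$image, lab)$per_cell$ratio,
               tolerance = 1e-5)
})
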