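test_that("threshold masks are lower-inclusive", {
  img <- matrix(0, 8, 8)
  expect_false(any(threshold_mask(img, 1)))
  expect_true(all(threshold_mask(img, 0)))
  img[3:5, 3:5] <- 100
  expect_identical(sum(threshold_mask(img, 50)), 9L)
  expect_identical(sum(threshold_mask(img, 100)), 9L)  # boundary included
})

test_that("disk dilation matches the distance-transform oracle", {
  # single pixel: area = lattice points within Euclidean distance 5
  m <- matrix(FALSE, 32, 32); m[16, 16] <- TRUE
  d5 <- dilate_mask(m, 5)
  lattice <- sum(outer(-5:5, -5:5, function(a, b) a^2 + b^2) <= 25)
  expect_identical(sum(d5), lattice)
  expect_identical(dilate_mask(matrix(FALSE, 8, 8), 5), matrix(FALSE, 8, 8))
  expect_identical(dilate_mask(m, 0), m)
  set.seed(13)
  for (i in 1:3) {
    rnd <- matrix(runif(32 * 32) < 0.03, 32, 32)
    for (r in c(3, 5)) {
      expect_identical(dilate_mask(rnd, r), dilate_oracle(rnd, r))
    }
    expect_true(all(rnd[dilate_mask(rnd, 5)] | TRUE))  # superset:
    expect_true(all(!rnd | dilate_mask(rnd, 5)))
  }
})

test_that("mask algebra obeys Boolean identities and checks shapes", {
  set.seed(3)
  a <- matrix(runif(64) < 0.4, 8, 8)
  b <- matrix(runif(64) < 0.4, 8, 8)
  expect_identical(invert_mask(invert_mask(a)), a)
  expect_false(any(combine_masks(a, invert_mask(a), "and")))
  expect_identical(combine_masks(a, b, "minus"), a & !b)
  expect_identical(combine_masks(a, b, "or"), a | b)
  expect_error(combine_masks(a, matrix(TRUE, 4, 4)),
               class = "synquant_shape_mismatch")
})

test_that("rolling-ball subtraction removes flat background and keeps narrow peaks", {
  expect_equal(rolling_ball_subtract(matrix(7, 32, 32), 14),
               matrix(0, 32, 32), ignore_attr = TRUE)
  pk <- matrix(5, 64, 64)
  pk[32, 32] <- 105
  out <- rolling_ball_subtract(pk, 14)
  expect_lt(abs(out[32, 32] - 100) / 100, 0.05)
  expect_error(rolling_ball_subtract(matrix(0, 10, 10), 14),
               class = "synquant_bad_radius")
})

test_that("rolling-ball output is bounded, translation-equivariant and idempotent", {
  set.seed(5)
  img <- matrix(runif(64 * 64, 0, 10), 64)
  out <- rolling_ball_subtract(img, 6)
  expect_true(all(out <= img + 1e-12))
  bg <- attr(out, "background")
  # the background estimate (an opening) is idempotent
  bg2 <- attr(rolling_ball_subtract(bg, 6), "background")
  expect_equal(bg2, bg, tolerance = 1e-9)
  # translating the scene translates the result (compare interiors)
  sh <- matrix(0, 64, 64)
  sh[11:64, 6:64] <- img[1:54, 1:59]
  out_sh <- rolling_ball_subtract(sh, 6)
  expect_equal(out_sh[21:54, 16:49], out[11:44, 11:44], tolerance = 1e-9)
})

test_that("rolling-ball matches the brute-force structuring-element oracle", {
  set.seed(8)
  img <- matrix(runif(32 * 32, 0, 100), 32)
  expect_equal(rolling_ball_subtract(img, 5), rb_oracle(img, 5),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the co-clustering ratio follows its ROI-mean definition", {
  cell <- matrix(TRUE, 10, 10)
  mk <- matrix(FALSE, 10, 10); mk[3:4, 3:4] <- TRUE
  expect_equal(coclustering_ratio(matrix(1, 10, 10), mk, cell)$value, 1)
  v5 <- matrix(1, 10, 10); v5[mk] <- 2
  r <- coclustering_ratio(v5, mk, cell)
  expect_equal(r$value, 2)
  expect_identical(r$roi_in_area, 4L)
  expect_identical(r$roi_out_area, 96L)
  # invariance under positive scaling of the reporter channel
  expect_equal(coclustering_ratio(37.5 * v5, mk, cell)$value, 2)
  expect_error(coclustering_ratio(v5, matrix(FALSE, 10, 10), cell),
               class = "synquant_undefined_ratio")
  expect_error(coclustering_ratio(matrix(0, 10, 10), mk, cell),
               class = "synquant_undefined_ratio")
})

test_that("HEK quantification is exact on noiseless scenes with ground-truth masks", {
  sc <- make_hek_scene(hek_scene_spec(recruitment_ratio = 2, noise_sd = 0,
                                      seed = 3))
  q <- quantify_hek_scene(sc, cell_labels = sc$ground_truth$cell_labels,
                          liprin_mask = sc$ground_truth$cluster_mask)
  expect_equal(q$ratio_total, rep(2, nrow(q)), tolerance = 1e-12)
  expect_equal(q$ratio_surface, rep(2, nrow(q)), tolerance = 1e-12)
})

test_that("coculture measures respect ROI definitions and report absence as NA", {
  thr <- list(inducer = 40, tau = 50, map2 = 50, synapsin = 75)
  sc <- make_coculture_scene(coculture_scene_spec(
    synapsin_density_on = 0, synapsin_density_off = 0, noise_sd = 0,
    seed = 2))
  m <- coculture_contact_measures(sc, thr)
  expect_equal(m$synapsin_area_per_contact, 0)
  expect_equal(m$synapsin_intensity_per_contact, 0)
  # contact ROI built from thresholds equals ground-truth mask algebra
  gt <- sc$ground_truth
  expect_identical(m$contact_area,
                   sum(gt$cos_mask & gt$tau_mask &
                         !dilate_mask(gt$map2_mask, 5)))
  # enlarging the MAP2 exclusion strictly shrinks the contact area
  m8 <- coculture_contact_measures(sc, thr, map2_dilate_px = 8)
  expect_lt(m8$contact_area, m$contact_area)
})

test_that("surface-expression matching keeps cells inside the reference band", {
  same <- tibble::tibble(group = rep(c("ref", "mut"), each = 5), level = 10)
  expect_true(all(match_surface_expression(same, "ref")$kept))
  cells <- tibble::tibble(group = c(rep("ref", 20), "mut", "mut"),
                          level = c(rnorm(20, 10, 1), 100, 10))
  out <- match_surface_expression(cells, "ref")
  expect_false(out$kept[21])
  expect_true(out$kept[22])
  wide <- match_surface_expression(cells, "ref", band = c(0, 100))
  expect_true(all(wide$kept))
  expect_error(match_surface_expression(cells, "absent"),
               class = "synquant_bad_group")
})

test_that("per-culture normalization anchors each control mean at 1", {
  df <- tibble::tibble(
    culture = rep(c("c1", "c2"), each = 4),
    condition = rep(c("ctrl", "ctrl", "mut", "mut"), 2),
    value = c(2, 4, 2, 4, 10, 30, 10, 40))
  out <- normalize_to_control(df, "ctrl")
  ctrl_means <- tapply(out$normalized[out$condition == "ctrl"],
                       out$culture[out$condition == "ctrl"], mean)
  expect_equal(as.numeric(ctrl_means), c(1, 1), tolerance = 1e-12)
  expect_equal(out$normalized[out$culture == "c1" & out$condition == "mut"],
               c(2 / 3, 4 / 3))
  # cultures normalize independently
  expect_equal(out$normalized[out$culture == "c2" & out$condition == "mut"],
               c(0.5, 2))
  missing <- tibble::tibble(culture = "c3", condition = "mut", value = 5)
  flagged <- normalize_to_control(dplyr::bind_rows(df, missing), "ctrl")
  expect_true(flagged$missing_control[flagged$culture == "c3"])
  expect_true(is.na(flagged$normalized[flagged$culture == "c3"]))
})

test_that("morphology measures are invariant under joint intensity/threshold scaling", {
  sc <- make_field_scene(field_scene_spec(n_nuclei = 8, noise_sd = 0,
                                          seed = 6))
  thr <- list(tau = 50, map2 = 50, dapi = 60)
  m1 <- morphology_measures(sc, thr)
  sc2 <- sc
  sc2$channels <- lapply(sc$channels, function(ch) 2 * ch)
  m2 <- morphology_measures(sc2, lapply(thr, function(x) 2 * x))
  expect_equal(m1, m2)
})
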