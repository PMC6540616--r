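make_control_plate <- function(ratios = c(X = 0.65), noise_sd = 0,
                               seed = 1, dmso_rate = 0.5, ...) {
  strains <- data.frame(
    strain_id = c("PC", "NC", names(ratios)),
    role = c("positive_control", "negative_control",
             rep("sample", length(ratios))),
    dmso_rate = dmso_rate,
    mtx_rate = dmso_rate * c(1, 0.3, unname(ratios)))
  simulate_plate(plate_spec(strains, duration_h = 30, seed = seed,
                            params = growth_params(noise_sd = noise_sd),
                            ...))
}

test_that("blanking and log2 transform hit exact anchor values and drop sub-blank points", {
  gc <- tibble::tibble(well = "A01", time_h = 0:2,
                       od600 = 0.08 + c(0.125, 0.25, -0.01))
  ser <- blank_and_log(gc, 0.08)
  expect_equal(ser$log2_od, c(-3, -2))
  expect_identical(attr(ser, "n_dropped"), 1L)
  flat <- tibble::tibble(well = "A01", time_h = 0:2, od600 = rep(0.08, 3))
  expect_error(blank_and_log(flat, 0.08), class = "synquant_empty_series")
})

test_that("QC flags abrupt drops but tolerates small jitter", {
  gc <- simulate_growth_curve(growth_params(noise_sd = 0), seq(0, 20, 1 / 6),
                              well_id = "W1")
  expect_false(qc_wells(gc)$flagged)
  dropped <- inject_artifact(gc, 10, 0.5)
  dropped$well <- "W2"
  rep <- qc_wells(dplyr::bind_rows(gc, dropped), drop_threshold = 0.2)
  expect_identical(rep$flagged[rep$well == "W2"], TRUE)
  expect_identical(rep$flagged[rep$well == "W1"], FALSE)
  jitter <- gc
  jitter$od600 <- jitter$od600 * rep_len(c(1, 0.99), nrow(jitter))
  expect_false(qc_wells(jitter, drop_threshold = 0.2)$flagged)
})

test_that("the windowed slope fit recovers exact lines and rejects empty windows", {
  ser <- tibble::tibble(time_h = seq(0, 10, 0.25))
  ser$log2_od <- 0.4 * ser$time_h - 5
  est <- fit_linear_slope(ser)
  expect_equal(est$slope, 0.4, tolerance = 1e-12)
  expect_identical(est$n_points,
                   sum(ser$log2_od >= -3 & ser$log2_od <= -2))
  flat <- tibble::tibble(time_h = 0:10, log2_od = rep(-4, 11))
  expect_error(fit_linear_slope(flat, well_id = "F1"),
               class = "synquant_insufficient_window")
})

test_that("the slope fit agrees with the normal-equations oracle on random windows", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    ser <- tibble::tibble(time_h = sort(runif(n, 0, 20)),
                          log2_od = runif(n, -4, -1))
    lo <- runif(1, -4, -2.5)
    win <- c(lo, lo + runif(1, 0.8, 2))
    keep <- ser$log2_od >= win[1] & ser$log2_od <= win[2]
    if (sum(keep) < 3) next
    est <- fit_linear_slope(ser, window = win)
    expect_equal(est$slope,
                 slope_oracle(ser$time_h[keep], ser$log2_od[keep]),
                 tolerance = 1e-10)
  }
})

test_that("MTX/DMSO ratios follow their defining arithmetic", {
  slopes <- tibble::tibble(
    well = paste0("W", 1:6),
    strain = "X", role = "sample",
    media = c("MTX", "MTX", "MTX", "DMSO", "DMSO", "DMSO"),
    slope = c(0.2, 0.25, 0.15, 0.35, 0.4, 0.45),
    flagged = FALSE)
  r <- mtx_dmso_ratio(slopes, "X")
  expect_equal(sort(r$ratio), sort(c(0.5, 0.625, 0.375)))
  no_dmso <- slopes[slopes$media == "MTX", ]
  expect_error(mtx_dmso_ratio(no_dmso, "X"),
               class = "synquant_ratio_undefined")
})

test_that("the interaction score anchors controls at 0 and 1 and is affine-invariant", {
  expect_equal(interaction_score(0.9, 0.1, 0.9), 1)
  expect_equal(interaction_score(0.1, 0.1, 0.9), 0)
  expect_equal(interaction_score(0.5, 0.1, 0.9), 0.5)
  expect_error(interaction_score(0.5, 0.4, 0.4 + 1e-9),
               class = "synquant_controls_degenerate")
  set.seed(7)
  for (i in 1:25) {
    r <- sort(runif(3))
    a <- runif(1, 0.1, 5); b <- runif(1, -1, 1)
    expect_equal(interaction_score(a * r[2] + b, a * r[1] + b, a * r[3] + b),
                 interaction_score(r[2], r[1], r[3]), tolerance = 1e-12)
  }
})

test_that("clipping maps out-of-range scores to the display range only", {
  expect_equal(clip_score(1.02), 1)
  expect_equal(clip_score(-0.11), 0)
  expect_equal(clip_score(0.5), 0.5)
})

test_that("score aggregation pools replicates with mean and SEM", {
  s <- tibble::tibble(strain = "A", role = "sample",
                      score = c(0.2, 0.4))
  agg <- aggregate_scores(s)
  expect_equal(agg$mean, 0.3)
  expect_equal(agg$sem, 0.1)
  one <- aggregate_scores(tibble::tibble(strain = "B", role = "sample",
                                         score = 0.4))
  expect_true(is.na(one$sem))
  same <- aggregate_scores(tibble::tibble(strain = "C", role = "sample",
                                          score = rep(0.4, 3)))
  expect_equal(same$mean, 0.4)
  expect_equal(same$sem, 0)
})

test_that("two experiments of three replicates pool to n = 6 per strain", {
  s1 <- score_plate(make_control_plate(seed = 21), experiment_id = "e1")
  s2 <- score_plate(make_control_plate(seed = 22), experiment_id = "e2")
  agg <- aggregate_scores(dplyr::bind_rows(s1, s2))
  expect_true(all(agg$n == 6L))
})

test_that("specificity calls follow the three-ligand threshold rule", {
  qfg <- tibble::tibble(mutant = "QFG",
                        ligand = c("liprin-a2", "caskin1", "trio", "PTPs"),
                        score = c(0.37, 0.85, 0.80, 0.88))
  egfid <- tibble::tibble(mutant = "EGFID",
                          ligand = c("caskin1", "liprin-a2", "trio", "PTPs"),
                          score = c(-0.11, 0.73, 0.90, 1.02))
  broad <- tibble::tibble(mutant = "broad",
                          ligand = c("l1", "l2", "l3", "l4"),
                          score = c(0.1, 0.1, 0.1, 0.9))
  calls <- classify_specificity(dplyr::bind_rows(qfg, egfid, broad))
  expect_identical(calls$nonspecific[calls$mutant == "QFG"], FALSE)
  expect_identical(calls$nonspecific[calls$mutant == "EGFID"], FALSE)
  expect_identical(calls$nonspecific[calls$mutant == "broad"], TRUE)
  # strict inequality at the boundary: 0.3 does not count as "below"
  edge <- tibble::tibble(mutant = "edge", ligand = c("l1", "l2", "l3"),
                         score = rep(0.3, 3))
  expect_identical(classify_specificity(edge)$nonspecific, FALSE)
})

test_that("heatmap bins are lower-inclusive and reject unclipped input", {
  expect_identical(as.character(bin_for_heatmap(0.37)), "0.2-0.4")
  expect_identical(as.character(bin_for_heatmap(0)), "<0.2")
  expect_identical(as.character(bin_for_heatmap(0.8)), ">0.8")
  expect_identical(as.character(bin_for_heatmap(1)), ">0.8")
  expect_error(bin_for_heatmap(1.2), class = "synquant_unclipped")
})

test_that("a noiseless simulated rate ratio is recovered by the slope pipeline", {
  plate <- make_control_plate(ratios = c(X = 0.5), seed = 5)
  slopes <- fit_plate_slopes(plate)
  r <- mtx_dmso_ratio(slopes, "X")
  expect_true(all(abs(r$ratio - 0.5) < 0.01))
})

test_that("excluding a flagged well never changes other wells' slopes", {
  plate <- make_control_plate(seed = 9)
  bad_well <- unique(plate$well[plate$strain == "X" & plate$media == "MTX"])[1]
  tampered <- dplyr::bind_rows(
    dplyr::filter(plate, well != bad_well),
    inject_artifact(dplyr::filter(plate, well == bad_well), 12, 0.6))
  s_clean <- fit_plate_slopes(plate)
  s_tamp <- fit_plate_slopes(tampered)
  expect_true(s_tamp$flagged[s_tamp$well == bad_well])
  others <- s_clean$well != bad_well
  expect_equal(s_tamp$slope[match(s_clean$well[others], s_tamp$well)],
               s_clean$slope[others], tolerance = 1e-12)
})

test_that("score_plate anchors the controls exactly on a noiseless plate", {
  agg <- aggregate_scores(score_plate(make_control_plate(seed = 2)))
  expect_equal(agg$mean[agg$strain == "PC"], 1, tolerance = 1e-12)
  expect_equal(agg$mean[agg$strain == "NC"], 0, tolerance = 1e-12)
})
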