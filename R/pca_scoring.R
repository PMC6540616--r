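#' Estimate the media blank for a plate
#'
#' Mean of all blank-well readings taken within the first hour of the run.
#' When the plate has no blank wells the global minimum reading is used as
#' a fallback.
#'
#' @param curves Long curve tibble (see [simulate_plate()]).
#' @return A single blank OD600 value.
#' @export
estimate_blank <- function(curves) {
  bl <- curves[curves$role == "blank", ]
  if (nrow(bl) > 0) {
    early <- bl[bl$time_h <= min(bl$time_h) + 1, ]
    mean(early$od600)
  } else {
    min(curves$od600)
  }
}

#' Blank-subtract and log2-transform one well
#'
#' Readings at or below the blank cannot be log-transformed and are dropped
#' (their count is recorded in attribute `"n_dropped"`).
#'
#' @param curve Single-well curve tibble.
#' @param blank Blank OD600 (>= 0).
#' @return Tibble with columns `time_h`, `log2_od`.
#' @examples
#' gc <- tibble::tibble(well = "A01", time_h = 0:1,
#'                      od600 = 0.08 + c(0.125, 0.25))
#' blank_and_log(gc, 0.08)$log2_od  # -3, -2
#' @export
blank_and_log <- function(curve, blank) {
  stopifnot(is.numeric(blank), blank >= 0)
  keep <- curve$od600 > blank
  if (!any(keep)) {
    abort(paste0("All readings of well ", curve$well[1],
                 " are at or below the blank."),
          class = "synquant_empty_series")
  }
  out <- tibble(time_h = curve$time_h[keep],
                log2_od = log2(curve$od600[keep] - blank))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Flag wells with abrupt OD drops
#'
#' Automated stand-in for visual inspection: a well is flagged when any
#' consecutive-reading decrease exceeds `drop_threshold` of the prior
#' reading. Flags are advisory — they are reported here and excluded by the
#' scoring pipeline, never silently applied to the data.
#'
#' @param curves Long curve tibble.
#' @param drop_threshold Relative drop that triggers a flag, in (0, 1);
#'   default 0.2.
#' @return Tibble with one row per well: `well`, `flagged`, `max_rel_drop`,
#'   `reason`.
#' @export
qc_wells <- function(curves, drop_threshold = 0.2) {
  stopifnot(drop_threshold > 0, drop_threshold < 1)
  if (nrow(curves) == 0) {
    return(tibble(well = character(), flagged = logical(),
                  max_rel_drop = numeric(), reason = character()))
  }
  curves |>
    dplyr::arrange(.data$well, .data$time_h) |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      max_rel_drop = {
        od <- .data$od600
        prev <- od[-length(od)]
        drops <- (prev - od[-1]) / ifelse(prev > 0, prev, NA_real_)
        if (all(is.na(drops)) || length(drops) == 0) 0 else
          max(c(0, drops), na.rm = TRUE)
      },
      .groups = "drop") |>
    dplyr::mutate(
      flagged = .data$max_rel_drop > drop_threshold,
      reason = ifelse(.data$flagged,
                      sprintf("abrupt drop of %.0f%% between consecutive readings",
                              100 * .data$max_rel_drop), "")) |>
    dplyr::select("well", "flagged", "max_rel_drop", "reason")
}

#' Fit the log-linear growth slope in a log2(OD600) window
#'
#' Ordinary least-squares slope of log2(OD600) against time over all points
#' whose log2 value lies inside the closed window, by default \[-3, -2\]
#' (the alternative \[-3, -2.2\] window is selected by passing
#' `window = c(-3, -2.2)`).
#'
#' @param series Tibble with `time_h` and `log2_od` (from
#'   [blank_and_log()]).
#' @param window Closed log2-OD bounds `c(lo, hi)`, default `c(-3, -2)`.
#' @param min_points Minimum points required in the window (default 3).
#' @param well_id Label used in error messages.
#' @return A one-row tibble: `well`, `slope` (log2-OD/h), `window_lo`,
#'   `window_hi`, `n_points`, `fit_residual` (RMS, log2-OD units).
#' @examples
#' s <- tibble::tibble(time_h = seq(0, 10, 0.25))
#' s$log2_od <- 0.4 * s$time_h - 5
#' fit_linear_slope(s)$slope  # 0.4
#' @export
fit_linear_slope <- function(series, window = c(-3, -2), min_points = 3,
                             well_id = "well") {
  stopifnot(length(window) == 2, window[1] < window[2], min_points >= 2)
  if (nrow(series) == 0) {
    abort("Empty series.", class = "synquant_insufficient_window")
  }
  inw <- series$log2_od >= window[1] & series$log2_od <= window[2]
  if (sum(inw) < min_points) {
    abort(sprintf(
      "Well %s: only %d point(s) in log2-OD window [%g, %g] (need %d).",
      well_id, sum(inw), window[1], window[2], min_points),
      class = "synquant_insufficient_window")
  }
  fit <- lm(log2_od ~ time_h, data = series[inw, ])
  tibble(well = well_id,
         slope = unname(coef(fit)[2]),
         window_lo = window[1], window_hi = window[2],
         n_points = sum(inw),
         fit_residual = sqrt(mean(fit$residuals^2)))
}

#' Fit growth slopes for every well of a plate
#'
#' Runs the per-well pipeline: blank estimation ([estimate_blank()] unless
#' `blank` is given), QC flagging ([qc_wells()]), blank-subtraction and
#' log2 transform, and windowed slope fitting. Wells that are QC-flagged or
#' lack enough points in the window get `NA` slopes with the reason
#' recorded; they are never silently removed.
#'
#' @inheritParams fit_linear_slope
#' @param curves Long curve tibble.
#' @param blank Blank OD600; `NULL` (default) estimates it from the plate.
#' @param drop_threshold QC threshold passed to [qc_wells()].
#' @return Tibble with one row per non-blank well: annotations, `slope`,
#'   `n_points`, `fit_residual`, `flagged`, `reason`.
#' @export
fit_plate_slopes <- function(curves, blank = NULL, window = c(-3, -2),
                             min_points = 3, drop_threshold = 0.2) {
  if (is.null(blank)) blank <- estimate_blank(curves)
  qc <- qc_wells(curves, drop_threshold)
  wells <- unique(curves[curves$role != "blank",
                         c("well", "strain", "media", "role")])
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells$well[i]
    base <- wells[i, ]
    fl <- qc[qc$well == w, ]
    if (nrow(fl) == 1 && fl$flagged) {
      return(cbind(base, tibble(slope = NA_real_, n_points = NA_integer_,
                                fit_residual = NA_real_, flagged = TRUE,
                                reason = fl$reason)))
    }
    res <- tryCatch({
      ser <- blank_and_log(curves[curves$well == w, ], blank)
      est <- fit_linear_slope(ser, window, min_points, well_id = w)
      cbind(base, tibble(slope = est$slope, n_points = est$n_points,
                         fit_residual = est$fit_residual, flagged = FALSE,
                         reason = ""))
    },
    synquant_insufficient_window = function(e)
      cbind(base, tibble(slope = NA_real_, n_points = NA_integer_,
                         fit_residual = NA_real_, flagged = TRUE,
                         reason = conditionMessage(e))),
    synquant_empty_series = function(e)
      cbind(base, tibble(slope = NA_real_, n_points = NA_integer_,
                         fit_residual = NA_real_, flagged = TRUE,
                         reason = conditionMessage(e))))
    res
  })
  out <- as_tibble(dplyr::bind_rows(rows))
  attr(out, "blank") <- blank
  out
}

#' Per-MTX-well MTX/DMSO slope ratios for one strain
#'
#' For each MTX-containing well of the strain, the ratio between that
#' well's slope and the mean slope of the strain's DMSO-only wells from the
#' same experiment. Flagged wells (NA slopes) are excluded.
#'
#' @param slopes Slope tibble from [fit_plate_slopes()] (one experiment).
#' @param strain_id Strain to compute ratios for.
#' @param experiment_id Experiment label attached to the output.
#' @return Tibble with one row per MTX well: `experiment`, `strain`,
#'   `role`, `well`, `ratio`.
#' @export
mtx_dmso_ratio <- function(slopes, strain_id, experiment_id = "exp1") {
  s <- slopes[slopes$strain == strain_id & !slopes$flagged &
                !is.na(slopes$slope), ]
  mtx <- s[s$media == "MTX", ]
  dmso <- s[s$media == "DMSO", ]
  if (nrow(mtx) == 0 || nrow(dmso) == 0) {
    abort(sprintf("Strain %s: need at least one unflagged MTX and one DMSO well.",
                  strain_id),
          class = "synquant_ratio_undefined")
  }
  denom <- mean(dmso$slope)
  if (denom <= 0) {
    abort(sprintf("Strain %s: mean DMSO slope is not positive.", strain_id),
          class = "synquant_ratio_undefined")
  }
  tibble(experiment = experiment_id, strain = strain_id,
         role = mtx$role, well = mtx$well, ratio = mtx$slope / denom)
}

#' The normalized DHFR interaction score
#'
#' `(ratio_x - ratio_nc) / (ratio_pc - ratio_nc)`: 0 means growth
#' equivalent to the negative-control strain, 1 means wild-type
#' (positive-control) growth. The raw, unclipped value is returned;
#' clipping to \[0, 1\] is a display-only step ([clip_score()]).
#'
#' @param ratio_x MTX/DMSO ratio(s) of the strain of interest (vectorized).
#' @param ratio_nc,ratio_pc Negative- and positive-control ratios.
#' @param tol Degeneracy tolerance: `|ratio_pc - ratio_nc|` below it is an
#'   error for the whole experiment.
#' @return Numeric score(s).
#' @examples
#' interaction_score(0.5, ratio_nc = 0.1, ratio_pc = 0.9)  # 0.5
#' @export
interaction_score <- function(ratio_x, ratio_nc, ratio_pc, tol = 1e-6) {
  stopifnot(length(ratio_nc) == 1, length(ratio_pc) == 1)
  if (abs(ratio_pc - ratio_nc) < tol) {
    abort("Degenerate controls: ratio_PC and ratio_NC are indistinguishable.",
          class = "synquant_controls_degenerate")
  }
  (ratio_x - ratio_nc) / (ratio_pc - ratio_nc)
}

#' Clip a score to the displayable range
#'
#' Display values above 1 or below 0 are clipped to 1 and 0. Applied only
#' for heatmaps and reporting; raw scores are kept unclipped.
#'
#' @param score Numeric score(s).
#' @return `pmin(1, pmax(0, score))`.
#' @examples
#' clip_score(c(1.02, -0.11, 0.5))
#' @export
clip_score <- function(score) pmin(1, pmax(0, score))

#' Score every strain of an experiment
#'
#' Full pipeline from curves to per-MTX-well interaction scores: slopes
#' ([fit_plate_slopes()]), per-well MTX/DMSO ratios ([mtx_dmso_ratio()]),
#' control anchoring ([interaction_score()]). The control ratios
#' `ratio_NC` and `ratio_PC` are the mean per-well ratios of the chosen
#' control strains from the same experiment (same plate).
#'
#' @inheritParams fit_plate_slopes
#' @param experiment_id Label recorded on every output row.
#' @param nc_strain,pc_strain Control strain ids. Defaults: the first
#'   strain with role `negative_control` (i.e. NC1 when two negative
#'   controls are present) and the first `positive_control`.
#' @param tol Control-degeneracy tolerance (see [interaction_score()]).
#' @return Tibble with one row per unflagged MTX well: `experiment`,
#'   `strain`, `role`, `well`, `ratio`, `ratio_nc`, `ratio_pc`, `score`,
#'   `score_clipped`.
#' @export
score_plate <- function(curves, experiment_id = "exp1", nc_strain = NULL,
                        pc_strain = NULL, blank = NULL, window = c(-3, -2),
                        min_points = 3, drop_threshold = 0.2, tol = 1e-6) {
  slopes <- fit_plate_slopes(curves, blank = blank, window = window,
                             min_points = min_points,
                             drop_threshold = drop_threshold)
  if (is.null(nc_strain)) {
    nc_strain <- slopes$strain[slopes$role == "negative_control"][1]
  }
  if (is.null(pc_strain)) {
    pc_strain <- slopes$strain[slopes$role == "positive_control"][1]
  }
  if (is.na(nc_strain) || is.na(pc_strain)) {
    abort("Plate lacks a positive- or negative-control strain.",
          class = "synquant_bad_spec")
  }
  strains <- unique(slopes$strain)
  ratios <- dplyr::bind_rows(lapply(
    strains, function(s) mtx_dmso_ratio(slopes, s, experiment_id)))
  ratio_nc <- mean(ratios$ratio[ratios$strain == nc_strain])
  ratio_pc <- mean(ratios$ratio[ratios$strain == pc_strain])
  ratios$ratio_nc <- ratio_nc
  ratios$ratio_pc <- ratio_pc
  ratios$score <- interaction_score(ratios$ratio, ratio_nc, ratio_pc, tol)
  ratios$score_clipped <- clip_score(ratios$score)
  attr(ratios, "slopes") <- slopes
  ratios
}

#' Aggregate per-well scores into per-strain summaries
#'
#' Per-well scores are pooled across experiments and summarized as mean and
#' SEM (sample SD / sqrt(n)); with a single replicate the SEM is reported
#' as `NA`, never 0.
#'
#' @param per_well_scores Tibble from [score_plate()] (rows from several
#'   experiments may be concatenated).
#' @return Tibble with one row per strain: `strain`, `role`, `n`, `mean`,
#'   `sem`, `mean_clipped`.
#' @export
aggregate_scores <- function(per_well_scores) {
  per_well_scores |>
    dplyr::group_by(.data$strain, .data$role) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      sem = if (dplyr::n() > 1) sd(.data$score) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(mean_clipped = clip_score(.data$mean))
}

#' Classify mutants as specific or nonspecific binders
#'
#' A mutant is called nonspecific when its interaction score falls below
#' `threshold` for at least `min_ligands` ligands (strict inequality at the
#' boundary), the rule used to gray out broadly disruptive mutations.
#'
#' @param scores Tibble with columns `mutant`, `ligand`, `score` (raw,
#'   unclipped scores).
#' @param threshold Score below which a ligand counts as lost (default 0.3).
#' @param min_ligands Number of lost ligands that makes the call (default 3).
#' @return Tibble with one row per mutant: `mutant`, `n_ligands`,
#'   `n_below`, `nonspecific`.
#' @examples
#' classify_specificity(tibble::tibble(
#'   mutant = "QFG", ligand = c("liprin-a2", "caskin1", "trio", "PTPs"),
#'   score = c(0.37, 0.85, 0.80, 0.88)))
#' @export
classify_specificity <- function(scores, threshold = 0.3, min_ligands = 3) {
  stopifnot(all(c("mutant", "ligand", "score") %in% names(scores)),
            nrow(scores) > 0)
  scores |>
    dplyr::group_by(.data$mutant) |>
    dplyr::summarise(n_ligands = dplyr::n(),
                     n_below = sum(.data$score < threshold),
                     .groups = "drop") |>
    dplyr::mutate(nonspecific = .data$n_below >= min_ligands)
}

#' Bin a clipped score for the five-color heatmap
#'
#' Lower-inclusive half-open bins \[0, 0.2), \[0.2, 0.4), \[0.4, 0.6),
#' \[0.6, 0.8), \[0.8, 1\], labeled `<0.2`, `0.2-0.4`, `0.4-0.6`,
#' `0.6-0.8`, `>0.8`. Inputs must already be clipped to \[0, 1\].
#'
#' @param score_clipped Clipped score(s) in \[0, 1\].
#' @return Factor of bin labels.
#' @examples
#' bin_for_heatmap(c(0.37, 0, 0.8))
#' @export
bin_for_heatmap <- function(score_clipped) {
  if (any(is.na(score_clipped)) ||
      any(score_clipped < 0 | score_clipped > 1)) {
    abort("Scores must lie in [0, 1]; apply `clip_score()` first.",
          class = "synquant_unclipped")
  }
  cut(score_clipped, breaks = seq(0, 1, 0.2),
      labels = c("<0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", ">0.8"),
      right = FALSE, include.lowest = TRUE)
}

#' The five-bin heatmap palette
#'
#' Purple, blue, teal, green, yellow for the bins of [bin_for_heatmap()].
#' @return Named character vector of colors.
#' @export
heatmap_palette <- function() {
  c("<0.2" = "#7B3294", "0.2-0.4" = "#2C7BB6", "0.4-0.6" = "#1B9E9E",
    "0.6-0.8" = "#41AB5D", ">0.8" = "#FFD92F")
}
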