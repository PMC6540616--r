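#' Co-clustering (recruitment) ratio
#'
#' Mean reporter intensity over the marker-positive region of a cell
#' divided by the mean over the marker-negative remainder:
#' `mean(v5[cell & marker]) / mean(v5[cell & !marker])`. The reporter
#' channel is never thresholded. Values above 1 indicate recruitment of
#' the reporter into the marker puncta.
#'
#' @param v5 Reporter intensity matrix (total or surface channel).
#' @param liprin_mask Marker (cluster) mask.
#' @param cell_mask Cell-fill mask.
#' @return A one-row tibble: `value`, `roi_in_area`, `roi_out_area`.
#' @examples
#' v5 <- matrix(1, 10, 10); v5[3:4, 3:4] <- 2
#' mk <- matrix(FALSE, 10, 10); mk[3:4, 3:4] <- TRUE
#' coclustering_ratio(v5, mk, matrix(TRUE, 10, 10))$value  # 2
#' @export
coclustering_ratio <- function(v5, liprin_mask, cell_mask) {
  roi_in <- combine_masks(cell_mask, liprin_mask, "and")
  roi_out <- combine_masks(cell_mask, liprin_mask, "minus")
  if (!any(roi_in) || !any(roi_out)) {
    abort("Empty ROI: both marker-positive and marker-negative cell regions are required.",
          class = "synquant_undefined_ratio")
  }
  denom <- mean(v5[roi_out])
  if (denom <= 0) {
    abort("Marker-negative mean intensity is zero; ratio undefined.",
          class = "synquant_undefined_ratio")
  }
  tibble(value = mean(v5[roi_in]) / denom,
         roi_in_area = sum(roi_in), roi_out_area = sum(roi_out))
}

#' Quantify a HEK co-clustering scene
#'
#' Reproduces the co-clustering measurement: rolling-ball background
#' subtraction (radius 14) on the liprin channel, threshold ROIs from the
#' cell-fill and background-subtracted liprin channels, then the
#' recruitment ratio of each unthresholded V5 channel within each cell.
#' The cell mask is eroded by a couple of pixels before measuring so that
#' membrane-edge partial-volume pixels do not dilute the outside-cluster
#' mean.
#'
#' Ground-truth masks (or any externally segmented masks) can be supplied
#' through `cell_labels` and `liprin_mask`, bypassing segmentation.
#'
#' @param sc A [scene()] with channels `cfp_fill`, `liprin`, `v5_total`,
#'   `v5_surface`.
#' @param cell_labels Optional integer label matrix of cells.
#' @param liprin_mask Optional cluster mask.
#' @param rolling_ball_radius Radius for [rolling_ball_subtract()]
#'   (default 14).
#' @param cell_threshold Absolute threshold for the cell fill; `NULL`
#'   (default) uses Otsu.
#' @param liprin_threshold_frac Per-cell liprin threshold as a fraction of
#'   that cell's maximum background-subtracted liprin signal (default 0.5).
#' @param cell_erode_px Erosion applied to segmented cell masks
#'   (default 2; not applied to supplied masks).
#' @param cluster_guard_px Guard zone around the cluster mask excluded
#'   from the outside-cluster ROI (default 2), so partial-volume pixels at
#'   punctum edges do not contaminate the denominator.
#' @param min_cell_area Minimum cell size in pixels (default 200).
#' @return Tibble with one row per cell: `cell`, `ratio_total`,
#'   `ratio_surface`, `surface_level` (mean surface-V5 over the cell),
#'   `cell_area`, `cluster_area`.
#' @export
quantify_hek_scene <- function(sc, cell_labels = NULL, liprin_mask = NULL,
                               rolling_ball_radius = 14,
                               cell_threshold = NULL,
                               liprin_threshold_frac = 0.5,
                               cell_erode_px = 2, cluster_guard_px = 2,
                               min_cell_area = 200) {
  stopifnot(inherits(sc, "scene"))
  ch <- sc$channels
  segmented <- is.null(cell_labels)
  if (segmented) {
    thr <- if (is.null(cell_threshold)) otsu_threshold(ch$cfp_fill) else
      cell_threshold
    cmask <- threshold_mask(ch$cfp_fill, thr)
    if (cell_erode_px > 0) cmask <- erode_mask(cmask, cell_erode_px)
    cell_labels <- label_components(cmask, min_area = min_cell_area)
  }
  n_cells <- max(cell_labels)
  if (n_cells == 0) {
    return(tibble(cell = integer(), ratio_total = numeric(),
                  ratio_surface = numeric(), surface_level = numeric(),
                  cell_area = integer(), cluster_area = integer()))
  }
  lip_bs <- if (is.null(liprin_mask)) {
    rolling_ball_subtract(ch$liprin, rolling_ball_radius)
  } else NULL
  rows <- lapply(seq_len(n_cells), function(i) {
    cm <- cell_labels == i
    lm <- if (is.null(liprin_mask)) {
      threshold_mask(lip_bs, liprin_threshold_frac * max(lip_bs[cm])) & cm
    } else liprin_mask & cm
    # outside ROI excludes a guard ring around the clusters
    cm_out <- cm & !dilate_mask(lm, cluster_guard_px)
    ratio <- function(v5) {
      if (!any(lm & cm) || !any(cm_out)) return(NULL)
      den <- mean(v5[cm_out])
      if (den <= 0) return(NULL)
      mean(v5[lm & cm]) / den
    }
    rt <- ratio(ch$v5_total)
    if (is.null(rt)) return(NULL)
    tibble(cell = i, ratio_total = rt,
           ratio_surface = ratio(ch$v5_surface),
           surface_level = mean(ch$v5_surface[cm]),
           cell_area = sum(cm), cluster_area = sum(lm))
  })
  dplyr::bind_rows(rows)
}

#' Coculture contact-area measures
#'
#' Builds the assay ROIs — contact ROI = COS AND axon AND NOT
#' (MAP2 dilated by `map2_dilate_px`); COS ROI = COS AND NOT dilated MAP2 —
#' and measures punctate synapsin over each. The synapsin threshold is
#' chosen to include only punctate signal; both the thresholded-area and
#' the integrated-intensity variants are reported, per pixel of ROI.
#'
#' @param sc A [scene()] with channels `synapsin`, `tau`, `map2`,
#'   `inducer` (and optionally `v5_surface`).
#' @param thresholds Named list of absolute thresholds for `inducer`,
#'   `tau`, `map2`, `synapsin`.
#' @param map2_dilate_px Dilation of the MAP2 ROI before exclusion
#'   (default 5).
#' @param punctum_area Optional length-2 vector `c(min, max)` of punctum
#'   component sizes kept (default no size filter).
#' @param masks Optional named list of precomputed masks (`cos`, `tau`,
#'   `map2`) overriding thresholding, e.g. ground truth.
#' @return One-row tibble: `contact_area`, `cos_area`,
#'   `synapsin_area_per_contact`, `synapsin_intensity_per_contact`,
#'   `synapsin_area_per_cos`, `synapsin_intensity_per_cos`,
#'   `inducer_surface_intensity`. Measures over an empty contact ROI are
#'   `NA` (reported absent, not zero).
#' @export
coculture_contact_measures <- function(sc, thresholds, map2_dilate_px = 5,
                                       punctum_area = NULL, masks = NULL) {
  stopifnot(inherits(sc, "scene"))
  ch <- sc$channels
  cos_mask <- if (!is.null(masks$cos)) masks$cos else
    threshold_mask(ch$inducer, thresholds$inducer)
  tau_mask <- if (!is.null(masks$tau)) masks$tau else
    threshold_mask(ch$tau, thresholds$tau)
  map2_mask <- if (!is.null(masks$map2)) masks$map2 else
    threshold_mask(ch$map2, thresholds$map2)
  if (!any(cos_mask)) {
    abort("Inducer (COS) mask is empty.", class = "synquant_empty_roi")
  }
  map2_dil <- dilate_mask(map2_mask, map2_dilate_px)
  contact <- cos_mask & tau_mask & !map2_dil
  cos_roi <- cos_mask & !map2_dil
  punct <- threshold_mask(ch$synapsin, thresholds$synapsin)
  if (!is.null(punctum_area)) {
    lab <- label_components(punct, min_area = punctum_area[1])
    if (is.finite(punctum_area[2]) && attr(lab, "n") > 0) {
      sizes <- tabulate(lab[lab > 0])
      lab[lab %in% which(sizes > punctum_area[2])] <- 0L
    }
    punct <- lab > 0
  }
  per_roi <- function(roi) {
    if (!any(roi)) return(c(NA_real_, NA_real_))
    c(sum(punct & roi) / sum(roi), sum(ch$synapsin[punct & roi]) / sum(roi))
  }
  on <- per_roi(contact)
  cos_m <- per_roi(cos_roi)
  tibble(contact_area = sum(contact), cos_area = sum(cos_roi),
         synapsin_area_per_contact = on[1],
         synapsin_intensity_per_contact = on[2],
         synapsin_area_per_cos = cos_m[1],
         synapsin_intensity_per_cos = cos_m[2],
         inducer_surface_intensity = if (any(cos_roi))
           mean(ch$inducer[cos_roi]) else NA_real_)
}

#' Punctum density from punctate area coverage
#'
#' Converts a punctate-area-per-ROI-area measure into an estimate of the
#' underlying punctum density (puncta per pixel). Independently placed
#' puncta overlap, so coverage saturates as `1 - exp(-density * a)` with
#' `a` the single-punctum footprint (Boolean model); this inverts that
#' relation. At low coverage it reduces to `coverage / a`.
#'
#' @param coverage Punctate area fraction(s) in \[0, 1).
#' @param punctum_radius_px Punctum radius in pixels; the footprint is the
#'   lattice disk area of that radius.
#' @return Estimated density in puncta per pixel.
#' @export
density_from_coverage <- function(coverage, punctum_radius_px) {
  stopifnot(all(coverage >= 0), all(coverage < 1), punctum_radius_px >= 1)
  r <- punctum_radius_px
  a <- sum(outer(-floor(r):floor(r), -floor(r):floor(r),
                 function(x, y) x^2 + y^2) <= r^2)
  -log(1 - coverage) / a
}

#' Match surface-expression levels across cells
#'
#' Cells showing high or low surface reporter (V5) levels relative to a
#' reference group are excluded before downstream measures: a cell is kept
#' iff its level lies within the `[band[1], band[2]]` percentile band of
#' the reference group's levels. Band endpoints at 0 or 100 are treated as
#' unbounded.
#'
#' @param cells Tibble with columns `group` and `level` (one row per
#'   cell); other columns pass through.
#' @param reference_group Group label whose levels define the band.
#' @param band Percentile pair, default `c(10, 90)`.
#' @return Input tibble with a logical `kept` column; band bounds attached
#'   as attribute `"band_levels"`.
#' @export
match_surface_expression <- function(cells, reference_group,
                                     band = c(10, 90)) {
  stopifnot(all(c("group", "level") %in% names(cells)),
            length(band) == 2, band[1] <= band[2])
  ref <- cells$level[cells$group == reference_group]
  if (length(ref) == 0) {
    abort("Reference group is empty.", class = "synquant_bad_group")
  }
  lo <- if (band[1] <= 0) -Inf else quantile(ref, band[1] / 100, names = FALSE)
  hi <- if (band[2] >= 100) Inf else quantile(ref, band[2] / 100, names = FALSE)
  cells$kept <- cells$level >= lo & cells$level <= hi
  attr(cells, "band_levels") <- c(lo, hi)
  cells
}

#' Normalize per-cell measures to a within-culture control condition
#'
#' Each value is divided by the mean value of the control condition from
#' the same culture, so the control group's normalized mean is 1 by
#' construction within every culture. Cultures lacking the control
#' condition are flagged (`normalized` set to `NA`), never silently
#' dropped.
#'
#' @param values Tibble with columns `value`, `culture`, `condition`.
#' @param control_condition Condition label used as the normalizer.
#' @return Input tibble with `normalized` and `missing_control` columns.
#' @export
normalize_to_control <- function(values, control_condition) {
  stopifnot(all(c("value", "culture", "condition") %in% names(values)))
  values |>
    dplyr::group_by(.data$culture) |>
    dplyr::mutate(
      .ctrl = mean(.data$value[.data$condition == control_condition]),
      missing_control = !any(.data$condition == control_condition),
      normalized = ifelse(.data$missing_control, NA_real_,
                          .data$value / .data$.ctrl)) |>
    dplyr::ungroup() |>
    dplyr::select(-".ctrl")
}

#' Field morphology measures
#'
#' Total Tau- and MAP2-positive area per field normalized to the number of
#' DAPI-stained nuclei, and the Tau/MAP2 area ratio. Nuclei are counted as
#' connected components of the thresholded DAPI mask above a minimum size.
#'
#' @param sc A [scene()] with channels `tau`, `map2`, `dapi`.
#' @param thresholds Named list of absolute thresholds for `tau`, `map2`,
#'   `dapi`.
#' @param min_nucleus_area Minimum nucleus component size in pixels
#'   (default 30).
#' @return One-row tibble: `n_nuclei`, `tau_area`, `map2_area`,
#'   `tau_area_per_nucleus`, `map2_area_per_nucleus`, `tau_map2_ratio`.
#'   Per-nucleus measures are `NA` when no nucleus is detected; the ratio
#'   is `NA` when the MAP2 area is zero.
#' @export
morphology_measures <- function(sc, thresholds, min_nucleus_area = 30) {
  stopifnot(inherits(sc, "scene"))
  ch <- sc$channels
  tau_a <- sum(threshold_mask(ch$tau, thresholds$tau))
  map2_a <- sum(threshold_mask(ch$map2, thresholds$map2))
  lab <- label_components(threshold_mask(ch$dapi, thresholds$dapi),
                          min_area = min_nucleus_area)
  n <- attr(lab, "n")
  tibble(n_nuclei = n, tau_area = tau_a, map2_area = map2_a,
         tau_area_per_nucleus = if (n > 0) tau_a / n else NA_real_,
         map2_area_per_nucleus = if (n > 0) map2_a / n else NA_real_,
         tau_map2_ratio = if (map2_a > 0) tau_a / map2_a else NA_real_)
}
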