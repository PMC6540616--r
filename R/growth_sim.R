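#' Growth-model parameters for one simulated well
#'
#' Parameters of the logistic growth model used by the plate simulator.
#' Rates are expressed in log2(OD600) units per hour (doublings per hour),
#' the same unit in which growth slopes are later fitted, so a simulated
#' rate is directly comparable to a fitted slope.
#'
#' @param initial_od Blank-subtracted OD600 at inoculation (> 0); the
#'   default matches the assay's inoculation density of 0.05.
#' @param carrying_capacity Blank-subtracted OD600 plateau; must exceed
#'   `initial_od`.
#' @param rate Specific growth rate, log2-OD units per hour (>= 0).
#' @param lag_h Lag before growth starts, hours.
#' @param noise_sd Standard deviation of additive Gaussian reader noise, OD
#'   units (>= 0).
#' @param blank_od Media-only absorbance added to every reading.
#'
#' @return A `growth_params` list.
#' @examples
#' growth_params(rate = 0.5, noise_sd = 0)
#' @export
growth_params <- function(initial_od = 0.05, carrying_capacity = 1.2,
                          rate = 0.35, lag_h = 2, noise_sd = 0.002,
                          blank_od = 0.08) {
  stopifnot(is.numeric(initial_od), initial_od > 0,
            is.numeric(carrying_capacity),
            is.numeric(rate), length(rate) == 1, rate >= 0,
            is.numeric(lag_h), is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(blank_od), blank_od >= 0)
  if (initial_od >= carrying_capacity) {
    abort("`initial_od` must be smaller than `carrying_capacity`.",
          class = "synquant_bad_params")
  }
  structure(list(initial_od = initial_od,
                 carrying_capacity = carrying_capacity,
                 rate = rate, lag_h = lag_h, noise_sd = noise_sd,
                 blank_od = blank_od),
            class = "growth_params")
}

# Noise-free blank-subtracted logistic OD at times t (hours). Growth starts
# after the lag; before it the culture sits at initial_od.
logistic_od <- function(params, times_h) {
  t_eff <- pmax(times_h - params$lag_h, 0)
  n0 <- params$initial_od
  k <- params$carrying_capacity
  r <- params$rate * log(2)
  n0 * k / (n0 + (k - n0) * exp(-r * t_eff))
}

#' Simulate one well's OD600 time series
#'
#' Logistic growth in linear OD space plus media blank and additive Gaussian
#' reader noise truncated at zero. Deterministic for a given `seed`.
#'
#' @param params A [growth_params()] object.
#' @param times_h Strictly increasing read times, hours.
#' @param well_id,strain_id,media,role Annotations carried on the curve.
#'   `media` is `"MTX"` or `"DMSO"`; `role` is one of `"sample"`,
#'   `"positive_control"`, `"negative_control"`, `"blank"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return A tibble with columns `well`, `strain`, `media`, `role`,
#'   `time_h`, `od600` (one row per reading).
#' @examples
#' gc <- simulate_growth_curve(growth_params(noise_sd = 0), seq(0, 20, 1/6))
#' nrow(gc)
#' @export
simulate_growth_curve <- function(params, times_h, well_id = "A01",
                                  strain_id = "strain", media = "MTX",
                                  role = "sample", seed = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (length(times_h) == 0 || any(diff(times_h) <= 0)) {
    abort("`times_h` must be nonempty and strictly increasing.",
          class = "synquant_bad_times")
  }
  media <- match.arg(media, c("MTX", "DMSO"))
  role <- match.arg(role, c("sample", "positive_control",
                            "negative_control", "blank"))
  draw <- function() {
    od <- params$blank_od + logistic_od(params, times_h)
    if (params$noise_sd > 0) od <- od + rnorm(length(od), 0, params$noise_sd)
    pmax(od, 0)
  }
  od <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(well = well_id, strain = strain_id, media = media, role = role,
         time_h = as.numeric(times_h), od600 = od)
}

#' Specify a simulated DHFR-assay plate
#'
#' A plate carries every strain in both media (DMSO-only and DMSO + MTX)
#' with `replicates_per_condition` wells each, mirroring the assay design of
#' three replicate wells per strain per media, plus media-only blank wells.
#'
#' @param strains Data frame with columns `strain_id`, `role` (`"sample"`,
#'   `"positive_control"` or `"negative_control"`), `dmso_rate`, `mtx_rate`
#'   (log2-OD units/h). At least one positive and one negative control are
#'   required.
#' @param replicates_per_condition Wells per strain per media (default 3).
#' @param read_interval_min Minutes between reads (default 10).
#' @param duration_h Total kinetic run length, hours (default 24).
#' @param n_blanks Number of media-only blank wells (default 4).
#' @param params Template [growth_params()]; per-well `rate` is taken from
#'   `strains`, everything else from the template.
#' @param seed Integer seed for the whole plate.
#'
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(strains, replicates_per_condition = 3,
                       read_interval_min = 10, duration_h = 24,
                       n_blanks = 4, params = growth_params(), seed = 1) {
  strains <- as_tibble(strains)
  need <- c("strain_id", "role", "dmso_rate", "mtx_rate")
  if (!all(need %in% names(strains))) {
    abort(paste("`strains` needs columns:", paste(need, collapse = ", ")),
          class = "synquant_bad_spec")
  }
  if (!any(strains$role == "positive_control") ||
      !any(strains$role == "negative_control")) {
    abort("Plate must contain at least one positive- and one negative-control strain.",
          class = "synquant_bad_spec")
  }
  stopifnot(replicates_per_condition >= 1, read_interval_min > 0,
            duration_h > 0, n_blanks >= 0)
  structure(list(strains = strains,
                 replicates_per_condition = replicates_per_condition,
                 read_interval_min = read_interval_min,
                 duration_h = duration_h, n_blanks = n_blanks,
                 params = params, seed = seed),
            class = "plate_spec")
}

# 96-well ids in row-major order: A01..H12.
well_ids <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  if (n > length(ids)) ids <- c(ids, sprintf("X%03d", seq_len(n - length(ids))))
  ids[seq_len(n)]
}

#' Simulate a full DHFR-assay plate
#'
#' One growth curve per strain x media x replicate (MTX wells use
#' `mtx_rate`, DMSO wells `dmso_rate`) plus `n_blanks` media-only wells.
#' Reproducible from `spec$seed`.
#'
#' @param spec A [plate_spec()].
#' @return A long tibble of curves (columns as in
#'   [simulate_growth_curve()]), with the spec attached as attribute
#'   `"spec"`.
#' @examples
#' sp <- plate_spec(data.frame(
#'   strain_id = c("PC", "NC"),
#'   role = c("positive_control", "negative_control"),
#'   dmso_rate = c(0.5, 0.5), mtx_rate = c(0.5, 0.05)))
#' plate <- simulate_plate(sp)
#' length(unique(plate$well))
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  times <- seq(0, spec$duration_h, by = spec$read_interval_min / 60)
  layout <- expand.grid(rep = seq_len(spec$replicates_per_condition),
                        media = c("DMSO", "MTX"),
                        idx = seq_len(nrow(spec$strains)),
                        stringsAsFactors = FALSE)
  n_wells <- nrow(layout) + spec$n_blanks
  ids <- well_ids(n_wells)
  withr::with_seed(spec$seed, {
    curves <- vector("list", n_wells)
    for (i in seq_len(nrow(layout))) {
      st <- spec$strains[layout$idx[i], ]
      p <- spec$params
      p$rate <- if (layout$media[i] == "MTX") st$mtx_rate else st$dmso_rate
      curves[[i]] <- simulate_growth_curve(
        p, times, well_id = ids[i], strain_id = st$strain_id,
        media = layout$media[i], role = st$role)
    }
    if (spec$n_blanks > 0) {
      pb <- spec$params
      for (j in seq_len(spec$n_blanks)) {
        i <- nrow(layout) + j
        od <- pmax(pb$blank_od + if (pb$noise_sd > 0)
          rnorm(length(times), 0, pb$noise_sd) else 0, 0)
        curves[[i]] <- tibble(well = ids[i], strain = "blank",
                              media = "DMSO", role = "blank",
                              time_h = as.numeric(times), od600 = od)
      }
    }
    out <- dplyr::bind_rows(curves)
  })
  attr(out, "spec") <- spec
  out
}

#' Inject an abrupt-drop artifact into a growth curve
#'
#' Emulates the reading anomalies (e.g. condensation, bubbles) that cause
#' abrupt OD600 drops: all readings at or after `at_h` are multiplied by
#' `1 - drop_fraction`.
#'
#' @param curve A single-well curve tibble.
#' @param at_h Time of the drop; must lie within the curve's time range.
#' @param drop_fraction Fraction lost, in \[0, 1\].
#' @return The modified curve.
#' @export
inject_artifact <- function(curve, at_h, drop_fraction) {
  stopifnot(is.numeric(drop_fraction), drop_fraction >= 0, drop_fraction <= 1)
  if (length(unique(curve$well)) != 1) {
    abort("`inject_artifact()` expects a single-well curve.",
          class = "synquant_bad_curve")
  }
  if (at_h < min(curve$time_h) || at_h > max(curve$time_h)) {
    abort("`at_h` lies outside the curve's time range.",
          class = "synquant_bad_times")
  }
  curve$od600 <- ifelse(curve$time_h >= at_h,
                        curve$od600 * (1 - drop_fraction), curve$od600)
  curve
}

#' Write / read a simulated plate as plain text
#'
#' The kinetic table is tab-delimited long format (well, strain, media,
#' role, time_h, od600); the plate layout (one row per well) is a YAML
#' side-file. [read_plate()] round-trips the table.
#'
#' @param plate Long curve tibble as from [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @return `write_plate()` returns the paths invisibly; `read_plate()`
#'   returns the curve tibble.
#' @export
write_plate <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- file.path(dir, "plate_od600.tsv")
  lay <- file.path(dir, "plate_layout.yaml")
  write.table(as.data.frame(plate), tab, sep = "\t", quote = FALSE,
              row.names = FALSE)
  layout <- unique(plate[, c("well", "strain", "media", "role")])
  yaml::write_yaml(lapply(seq_len(nrow(layout)), function(i)
    as.list(layout[i, ])), lay)
  invisible(c(table = tab, layout = lay))
}

#' @rdname write_plate
#' @export
read_plate <- function(dir) {
  tab <- read.delim(file.path(dir, "plate_od600.tsv"),
                    stringsAsFactors = FALSE)
  as_tibble(tab)
}
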