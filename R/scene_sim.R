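#' Multi-channel synthetic microscopy scenes
#'
#' A `scene` is a named list of co-registered 2D intensity channels plus
#' optional pixel-size metadata and a ground-truth record (the masks,
#' ratios, densities and counts used to generate it). Ground truth is
#' always sufficient to compute every downstream measure analytically.
#'
#' @param channels Named list of numeric matrices, all the same shape,
#'   all nonnegative.
#' @param pixel_size Physical length per pixel (metadata only).
#' @param ground_truth Optional list of generation parameters and masks.
#' @return A `scene` object.
#' @export
scene <- function(channels, pixel_size = 1, ground_truth = NULL) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All channels must share the same shape.",
          class = "synquant_shape_mismatch")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    abort("Channel intensities must be nonnegative.",
          class = "synquant_bad_scene")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 ground_truth = ground_truth), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<scene> %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

# --- drawing helpers --------------------------------------------------------

# logical matrix with disks of `radius` stamped at integer centers
# (n x 2 matrix of row, col)
stamp_disks <- function(shape, centers, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (is.null(centers) || nrow(centers) == 0) return(m)
  off <- disk_offsets(radius)
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1] + off$dx
    c <- centers[i, 2] + off$dy
    ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
    m[cbind(r[ok], c[ok])] <- TRUE
  }
  m
}

blur_matrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  # FFT convolution leaves ~1e-16 negative ringing; clamp it
  pmax(as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x),
                                                   sigma))), 0)
}

# rejection-sample `n` disk centers with pairwise distance > min_dist,
# uniform over the pixels of `allowed`; NULL on failure
place_centers <- function(allowed, n, min_dist, max_tries = 2000) {
  idx <- which(allowed, arr.ind = TRUE)
  if (n == 0) return(matrix(integer(0), 0, 2))
  if (nrow(idx) == 0) return(NULL)
  centers <- matrix(0L, 0, 2)
  tries <- 0
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- idx[sample.int(nrow(idx), 1), ]
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
            min_dist^2)) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n) NULL else unname(centers)
}

# ribbon mask: random-walk path stamped with disks of `halfwidth`
random_ribbon <- function(shape, halfwidth, step_sd = 0.25, seed_side = NULL) {
  # start on a random border, head inward
  side <- if (is.null(seed_side)) sample.int(4, 1) else seed_side
  pos <- switch(side,
                c(1, runif(1, 1, shape[2])),
                c(shape[1], runif(1, 1, shape[2])),
                c(runif(1, 1, shape[1]), 1),
                c(runif(1, 1, shape[1]), shape[2]))
  ang <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.5, 0.5)
  n_steps <- 3 * max(shape)
  pts <- matrix(0L, 0, 2)
  for (s in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, step_sd)
    pos <- pos + c(sin(ang), cos(ang))
    if (pos[1] < 1 || pos[1] > shape[1] || pos[2] < 1 || pos[2] > shape[2])
      break
    pts <- rbind(pts, round(pos))
  }
  stamp_disks(shape, pts, halfwidth)
}

# wobbly blob mask centered at `center` with mean radius `radius`
blob_mask <- function(shape, center, radius, wobble = 0.12) {
  amp <- radius * wobble * runif(3, 0.5, 1)
  ph <- runif(3, 0, 2 * pi)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) -
    center[2]
  theta <- atan2(rr, cc)
  rad <- radius + amp[1] * sin(2 * theta + ph[1]) +
    amp[2] * sin(3 * theta + ph[2]) + amp[3] * sin(5 * theta + ph[3])
  sqrt(rr^2 + cc^2) <= rad
}

add_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  pmax(x + rnorm(length(x), 0, sd), 0)
}

# --- HEK co-clustering scene ------------------------------------------------

#' Specify a synthetic HEK co-clustering scene
#'
#' Emulates the co-clustering assay: cells filled with CFP, liprin puncta
#' inside them, and a V5 reporter channel whose true mean intensity inside
#' the puncta divided by that in the rest of the cell equals
#' `recruitment_ratio` exactly (before noise). Per-cell lognormal
#' brightness factors scale both compartments, so the per-cell ratio is
#' unaffected but surface levels vary across cells, which exercises
#' surface-expression matching.
#'
#' @param image_shape Image dimensions in pixels.
#' @param n_cells,cell_radius_px Number and radius of cells.
#' @param clusters_per_cell,cluster_radius_px Liprin puncta per cell and
#'   their radius; puncta are hard disks with Gaussian-blurred edges
#'   (sigma = radius / 3).
#' @param recruitment_ratio True inside/outside V5 mean-intensity ratio
#'   (>= 0).
#' @param v5_base,liprin_intensity,cfp_intensity Channel amplitudes.
#' @param surface_fraction Surface V5 as a fraction of total V5.
#' @param cell_level_sdlog SD (log scale) of per-cell brightness factors.
#' @param background_level Constant offset added to the liprin channel.
#' @param background_gradient Amplitude of a linear left-to-right ramp
#'   added to the liprin channel (exercises rolling-ball subtraction).
#' @param noise_sd Additive Gaussian noise SD (all channels), truncated
#'   at 0.
#' @param seed Integer seed.
#' @return A `hek_scene_spec` list.
#' @export
hek_scene_spec <- function(image_shape = c(192, 192), n_cells = 3,
                           cell_radius_px = 28, clusters_per_cell = 6,
                           cluster_radius_px = 4, recruitment_ratio = 2,
                           v5_base = 100, liprin_intensity = 100,
                           cfp_intensity = 100, surface_fraction = 0.6,
                           cell_level_sdlog = 0.15, background_level = 0,
                           background_gradient = 0, noise_sd = 0,
                           seed = 1) {
  stopifnot(recruitment_ratio >= 0, cluster_radius_px >= 1, n_cells >= 0,
            noise_sd >= 0, surface_fraction > 0, surface_fraction <= 1)
  structure(as.list(environment()), class = "hek_scene_spec")
}

#' Generate a synthetic HEK co-clustering scene
#'
#' @param spec A [hek_scene_spec()].
#' @return A [scene()] with channels `cfp_fill`, `liprin`, `v5_total`,
#'   `v5_surface`; ground truth holds the cell/cluster masks, cell label
#'   matrix, per-cell factors and the true recruitment ratio.
#' @examples
#' sc <- make_hek_scene(hek_scene_spec(n_cells = 2, seed = 7))
#' names(sc$channels)
#' @export
make_hek_scene <- function(spec) {
  stopifnot(inherits(spec, "hek_scene_spec"))
  sh <- spec$image_shape
  if (spec$n_cells == 0) {
    zero <- matrix(0, sh[1], sh[2])
    return(scene(list(cfp_fill = zero, liprin = zero, v5_total = zero,
                      v5_surface = zero),
                 ground_truth = list()))
  }
  withr::with_seed(spec$seed, {
    margin <- spec$cell_radius_px + 4
    interior <- matrix(FALSE, sh[1], sh[2])
    interior[margin:(sh[1] - margin), margin:(sh[2] - margin)] <- TRUE
    cc <- place_centers(interior, spec$n_cells,
                        2 * spec$cell_radius_px + 4)
    if (is.null(cc)) {
      abort("Could not place the requested cells without overlap.",
            class = "synquant_placement")
    }
    labels <- matrix(0L, sh[1], sh[2])
    cluster_mask <- matrix(FALSE, sh[1], sh[2])
    factors <- rlnorm(spec$n_cells, 0, spec$cell_level_sdlog)
    for (i in seq_len(spec$n_cells)) {
      cm <- stamp_disks(sh, cc[i, , drop = FALSE], spec$cell_radius_px)
      labels[cm] <- i
      inner <- stamp_disks(sh, cc[i, , drop = FALSE],
                           spec$cell_radius_px - spec$cluster_radius_px - 3)
      kc <- place_centers(inner, spec$clusters_per_cell,
                          2 * spec$cluster_radius_px + 2)
      if (is.null(kc)) {
        abort("Could not place clusters without overlap.",
              class = "synquant_placement")
      }
      cluster_mask <- cluster_mask | stamp_disks(sh, kc,
                                                 spec$cluster_radius_px)
    }
    cell_mask <- labels > 0
    fac <- matrix(0, sh[1], sh[2])
    fac[cell_mask] <- factors[labels[cell_mask]]
    v5 <- fac * spec$v5_base
    v5[cluster_mask] <- v5[cluster_mask] * spec$recruitment_ratio
    ramp <- spec$background_gradient *
      matrix(seq_len(sh[2]) - 1, sh[1], sh[2], byrow = TRUE) / (sh[2] - 1)
    liprin <- spec$liprin_intensity *
      blur_matrix(cluster_mask * 1, spec$cluster_radius_px / 3) +
      spec$background_level + ramp
    ch <- list(
      cfp_fill = add_noise(spec$cfp_intensity *
                             blur_matrix(cell_mask * 1, 2), spec$noise_sd),
      liprin = add_noise(liprin, spec$noise_sd),
      v5_total = add_noise(v5, spec$noise_sd),
      v5_surface = add_noise(spec$surface_fraction * v5, spec$noise_sd))
    scene(ch, ground_truth = list(
      cell_mask = cell_mask, cluster_mask = cluster_mask,
      cell_labels = labels, cell_factors = factors,
      recruitment_ratio = spec$recruitment_ratio,
      v5_base = spec$v5_base, surface_fraction = spec$surface_fraction))
  })
}

# --- coculture scene --------------------------------------------------------

#' Specify a synthetic neuron-fibroblast coculture scene
#'
#' Emulates the coculture recruitment assay: a single inducer-expressing
#' COS cell (wobbly blob), Tau-positive axons and thicker MAP2-positive
#' dendrites as random-walk ribbons, and synapsin puncta placed by Poisson
#' sampling — at `synapsin_density_on` per pixel of the contact ROI
#' (COS AND axon AND NOT 5-px-dilated MAP2) and `synapsin_density_off`
#' per pixel of the remaining axon area. Punctum counts scale with the
#' full ROI area while centers are confined to the ROI interior (eroded by
#' the punctum footprint) so each punctum lies wholly within its ROI class
#' and the expected punctate area per ROI area is analytic
#' (density x pi r^2). Structural channels (inducer, tau, map2,
#' v5_surface) are rendered crisp so threshold ROIs reproduce the
#' ground-truth masks exactly; only puncta have blurred edges.
#'
#' @param image_shape Image dimensions.
#' @param cos_radius_px Mean COS-cell radius (blob wobble ~12%).
#' @param n_axons,axon_halfwidth_px Axon ribbon count and half-width.
#' @param n_dendrites,dendrite_halfwidth_px Dendrite ribbon count and
#'   half-width.
#' @param synapsin_density_on,synapsin_density_off Puncta per pixel on/off
#'   the contact ROI (>= 0).
#' @param punctum_radius_px,punctum_intensity Punctum geometry and
#'   amplitude (blur sigma = radius / 3).
#' @param tau_intensity,map2_intensity,inducer_intensity,v5_intensity
#'   Channel amplitudes.
#' @param map2_dilate_px MAP2 dilation radius used for the ground-truth
#'   contact ROI (default 5).
#' @param noise_sd Additive Gaussian noise SD, truncated at 0.
#' @param seed Integer seed.
#' @return A `coculture_scene_spec` list.
#' @export
coculture_scene_spec <- function(image_shape = c(256, 256),
                                 cos_radius_px = 70, n_axons = 8,
                                 axon_halfwidth_px = 6, n_dendrites = 3,
                                 dendrite_halfwidth_px = 8,
                                 synapsin_density_on = 0.02,
                                 synapsin_density_off = 0.002,
                                 punctum_radius_px = 2,
                                 punctum_intensity = 150,
                                 tau_intensity = 100, map2_intensity = 100,
                                 inducer_intensity = 80, v5_intensity = 60,
                                 map2_dilate_px = 5, noise_sd = 0,
                                 seed = 1) {
  stopifnot(synapsin_density_on >= 0, synapsin_density_off >= 0,
            punctum_radius_px >= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "coculture_scene_spec")
}

# Poisson puncta for one ROI class: count ~ Pois(density * area(roi)),
# centers uniform over the interior (roi eroded by `margin`).
sample_puncta <- function(roi, density, margin, shape) {
  n <- rpois(1, density * sum(roi))
  if (n == 0) return(matrix(integer(0), 0, 2))
  interior <- erode_mask(roi, margin)
  if (!any(interior)) interior <- roi
  idx <- which(interior, arr.ind = TRUE)
  unname(idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE])
}

#' Generate a synthetic coculture scene
#'
#' @param spec A [coculture_scene_spec()].
#' @return A [scene()] with channels `synapsin`, `tau`, `map2`, `inducer`,
#'   `v5_surface`; ground truth holds all masks, densities and realized
#'   punctum counts.
#' @export
make_coculture_scene <- function(spec) {
  stopifnot(inherits(spec, "coculture_scene_spec"))
  sh <- spec$image_shape
  withr::with_seed(spec$seed, {
    cos_mask <- blob_mask(sh, sh / 2, spec$cos_radius_px)
    tau_mask <- matrix(FALSE, sh[1], sh[2])
    for (i in seq_len(spec$n_axons)) {
      tau_mask <- tau_mask | random_ribbon(sh, spec$axon_halfwidth_px)
    }
    map2_mask <- matrix(FALSE, sh[1], sh[2])
    for (i in seq_len(spec$n_dendrites)) {
      map2_mask <- map2_mask | random_ribbon(sh, spec$dendrite_halfwidth_px)
    }
    map2_dil <- dilate_mask(map2_mask, spec$map2_dilate_px)
    contact <- cos_mask & tau_mask & !map2_dil
    off_axon <- tau_mask & !contact & !map2_dil
    margin <- spec$punctum_radius_px + 2
    on_centers <- sample_puncta(contact, spec$synapsin_density_on,
                                margin, sh)
    # off-class puncta lie wholly inside the off-axon area and clear of
    # the contact ROI, so class leakage cannot occur
    off_allowed <- erode_mask(off_axon, margin) &
      !dilate_mask(contact, margin)
    if (!any(off_allowed)) {
      off_allowed <- off_axon & !dilate_mask(contact, margin)
    }
    n_off <- rpois(1, spec$synapsin_density_off * sum(off_axon))
    off_centers <- if (n_off > 0 && any(off_allowed)) {
      idx <- which(off_allowed, arr.ind = TRUE)
      unname(idx[sample.int(nrow(idx), n_off, replace = TRUE), ,
                 drop = FALSE])
    } else matrix(integer(0), 0, 2)
    punct_mask <- stamp_disks(sh, rbind(on_centers, off_centers),
                              spec$punctum_radius_px)
    synapsin <- spec$punctum_intensity *
      blur_matrix(punct_mask * 1, spec$punctum_radius_px / 3)
    ch <- list(
      synapsin = add_noise(synapsin, spec$noise_sd),
      tau = add_noise(spec$tau_intensity * tau_mask, spec$noise_sd),
      map2 = add_noise(spec$map2_intensity * map2_mask, spec$noise_sd),
      inducer = add_noise(spec$inducer_intensity * cos_mask, spec$noise_sd),
      v5_surface = add_noise(spec$v5_intensity * cos_mask, spec$noise_sd))
    scene(ch, ground_truth = list(
      cos_mask = cos_mask, tau_mask = tau_mask, map2_mask = map2_mask,
      contact_mask = contact, off_axon_mask = off_axon,
      punct_mask = punct_mask,
      density_on = spec$synapsin_density_on,
      density_off = spec$synapsin_density_off,
      n_on = nrow(on_centers), n_off = nrow(off_centers),
      punctum_radius_px = spec$punctum_radius_px))
  })
}

# --- low-magnification field scene ------------------------------------------

#' Specify a synthetic low-magnification field scene
#'
#' Emulates morphology fields stained for Tau (axons), MAP2 (dendrites)
#' and DAPI (nuclei): exactly `n_nuclei` disjoint nuclei, and Tau/MAP2
#' foreground masks carved from independent smoothed random fields by
#' order-statistic thresholding, so the realized area fractions match the
#' requested ones to within a pixel.
#'
#' @param image_shape Image dimensions.
#' @param n_nuclei,nucleus_radius_px Nucleus count and radius.
#' @param tau_area_fraction,map2_area_fraction Target foreground fractions
#'   in \[0, 1\].
#' @param tau_intensity,map2_intensity,dapi_intensity Channel amplitudes.
#' @param noise_sd Additive Gaussian noise SD, truncated at 0.
#' @param seed Integer seed.
#' @return A `field_scene_spec` list.
#' @export
field_scene_spec <- function(image_shape = c(256, 256), n_nuclei = 30,
                             nucleus_radius_px = 5,
                             tau_area_fraction = 0.2,
                             map2_area_fraction = 0.3,
                             tau_intensity = 100, map2_intensity = 100,
                             dapi_intensity = 120, noise_sd = 0,
                             seed = 1) {
  stopifnot(tau_area_fraction >= 0, tau_area_fraction <= 1,
            map2_area_fraction >= 0, map2_area_fraction <= 1,
            n_nuclei >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "field_scene_spec")
}

# smoothed-noise mask with an exact target pixel count
fraction_mask <- function(shape, fraction, smooth_sigma = 6) {
  if (fraction == 0) return(matrix(FALSE, shape[1], shape[2]))
  field <- blur_matrix(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                       smooth_sigma)
  k <- max(1, round(fraction * prod(shape)))
  thr <- sort(field, decreasing = TRUE)[k]
  field >= thr
}

#' Generate a synthetic field scene
#'
#' @param spec A [field_scene_spec()].
#' @return A [scene()] with channels `tau`, `map2`, `dapi`; ground truth
#'   holds the masks and nucleus centers.
#' @export
make_field_scene <- function(spec) {
  stopifnot(inherits(spec, "field_scene_spec"))
  sh <- spec$image_shape
  withr::with_seed(spec$seed, {
    margin <- spec$nucleus_radius_px + 2
    interior <- matrix(FALSE, sh[1], sh[2])
    interior[margin:(sh[1] - margin), margin:(sh[2] - margin)] <- TRUE
    nc <- place_centers(interior, spec$n_nuclei,
                        2 * spec$nucleus_radius_px + 3)
    if (is.null(nc)) {
      abort("Could not place the requested nuclei disjointly.",
            class = "synquant_placement")
    }
    nuc_mask <- stamp_disks(sh, nc, spec$nucleus_radius_px)
    tau_mask <- fraction_mask(sh, spec$tau_area_fraction)
    map2_mask <- fraction_mask(sh, spec$map2_area_fraction)
    ch <- list(
      tau = add_noise(spec$tau_intensity * tau_mask, spec$noise_sd),
      map2 = add_noise(spec$map2_intensity * map2_mask, spec$noise_sd),
      dapi = add_noise(spec$dapi_intensity * nuc_mask, spec$noise_sd))
    scene(ch, ground_truth = list(
      nuclei_centers = nc, n_nuclei = spec$n_nuclei,
      nuc_mask = nuc_mask, tau_mask = tau_mask, map2_mask = map2_mask,
      tau_area_fraction = spec$tau_area_fraction,
      map2_area_fraction = spec$map2_area_fraction))
  })
}
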