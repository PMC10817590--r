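#' Volume configuration
#'
#' Geometry and reflectivity statistics of synthetic segmented OCT macular
#' volumes. The en-face grid is `n_bscan` B-scans (superior to inferior) by
#' `n_ascan` A-scans (temporal to nasal for a right eye); each A-scan has
#' `n_depth` voxels. Seven ordered interface surfaces delimit up to six
#' neuroretinal layers; a radial Gaussian foveal depression thins the inner
#' layers towards zero at the grid centre.
#'
#' Per-layer reflectivity texture is a stationary smoothed-white-noise field:
#' white noise convolved with a Gaussian kernel of width
#' `texture_corr_length` (in B-scan pixel units; the A-scan axis is sampled
#' `n_ascan / n_bscan` times finer and the kernel is scaled accordingly, so
#' texture is isotropic in physical units), rescaled to standard deviation
#' `texture_sd`. The field is en-face (constant in depth within a layer) and
#' is added to `intensity_base`; independent Gaussian voxel noise of sd
#' `noise_sd` is added on top. Voxel values are rounded and clipped to
#' `[0, 255]` (8-bit reflectivity).
#'
#' @param n_bscan,n_ascan,n_depth Grid dimensions (default 128 x 512 x 64).
#' @param layers Character vector naming the simulated layers, a subset of
#'   `RNFL, GCL, IPL, INL, OPL, ONL` in that order.
#' @param layer_mean_thickness Mean thickness per layer in voxels, named or
#'   in `layers` order.
#' @param top_margin Mean depth of the vitreoretinal interface (voxels).
#' @param interface_smoothness Correlation length (B-scan pixels) of the
#'   smooth perturbations applied to the interface surfaces.
#' @param interface_sd Standard deviation (voxels) of the perturbation of the
#'   top surface.
#' @param thickness_sd Standard deviation (voxels) of smooth per-layer
#'   thickness perturbations.
#' @param foveal_dip_depth Total inner-layer thinning at the foveal centre
#'   (voxels). The default, the summed mean thickness of the simulated inner
#'   layers (all but ONL), collapses them to zero thickness at the centre.
#' @param foveal_dip_radius Gaussian radius of the depression (B-scan pixels).
#' @param intensity_base Mean reflectivity per layer (0-255), named or in
#'   `layers` order.
#' @param texture_corr_length,texture_sd Texture field parameters per layer.
#' @param noise_sd Independent voxel noise sd (reflectivity units).
#' @param background Reflectivity outside the retina (vitreous/choroid side).
#' @return An object of class `volume_config`.
#' @export
volume_config <- function(n_bscan = 128L, n_ascan = 512L, n_depth = 64L,
                          layers = NEURORETINA_LAYERS,
                          layer_mean_thickness = c(RNFL = 6, GCL = 7, IPL = 6,
                                                   INL = 5, OPL = 5, ONL = 10),
                          top_margin = 4,
                          interface_smoothness = 20,
                          interface_sd = 1,
                          thickness_sd = 0.4,
                          foveal_dip_depth = NULL,
                          foveal_dip_radius = 14,
                          intensity_base = c(RNFL = 170, GCL = 110, IPL = 130,
                                             INL = 100, OPL = 125, ONL = 90),
                          texture_corr_length = c(RNFL = 2.5, GCL = 2.5,
                                                  IPL = 2.5, INL = 2.5,
                                                  OPL = 2.5, ONL = 2.5),
                          texture_sd = c(RNFL = 10, GCL = 10, IPL = 10,
                                         INL = 10, OPL = 10, ONL = 10),
                          noise_sd = 15,
                          background = 10) {
  if (!all(layers %in% NEURORETINA_LAYERS)) {
    stop("`layers` must be a subset of ", paste(NEURORETINA_LAYERS, collapse = ", "),
         call. = FALSE)
  }
  layers <- NEURORETINA_LAYERS[NEURORETINA_LAYERS %in% layers]
  pick <- function(x, what) {
    if (!is.null(names(x)) && all(layers %in% names(x))) x <- x[layers]
    if (length(x) == 1) x <- rep(x, length(layers))
    if (length(x) != length(layers)) {
      stop(sprintf("`%s` must have one value per layer", what), call. = FALSE)
    }
    stats::setNames(as.numeric(x), layers)
  }
  thick <- pick(layer_mean_thickness, "layer_mean_thickness")
  if (any(thick < 1)) stop("layer thickness must be >= 1 voxel", call. = FALSE)
  sds <- pick(texture_sd, "texture_sd")
  if (any(sds < 0) || noise_sd < 0 || interface_sd < 0 || thickness_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  inner <- setdiff(layers, "ONL")
  if (is.null(foveal_dip_depth)) {
    foveal_dip_depth <- sum(thick[inner])
  }
  cfg <- structure(
    list(n_bscan = as.integer(n_bscan), n_ascan = as.integer(n_ascan),
         n_depth = as.integer(n_depth), layers = layers,
         layer_mean_thickness = thick, top_margin = top_margin,
         interface_smoothness = interface_smoothness,
         interface_sd = interface_sd, thickness_sd = thickness_sd,
         foveal_dip_depth = foveal_dip_depth,
         foveal_dip_radius = foveal_dip_radius,
         intensity_base = pick(intensity_base, "intensity_base"),
         texture_corr_length = pick(texture_corr_length, "texture_corr_length"),
         texture_sd = sds, noise_sd = noise_sd, background = background),
    class = "volume_config"
  )
  # worst-case fit check: mean geometry must leave head-room for perturbations
  if (cfg$top_margin + sum(thick) + 6 * (interface_sd + thickness_sd) > n_depth) {
    stop("layers do not fit within `n_depth`; reduce thicknesses or margins",
         call. = FALSE)
  }
  cfg
}

#' Interocular texture effect specification
#'
#' Describes an injected right-vs-left texture asymmetry: for eyes of the
#' target sex/eye, the texture field of one layer is regenerated with
#' modified parameters inside the en-face footprint of one quadrant
#' (quadrants are defined on the orientation-standardised image, so the
#' footprint is mirrored for left eyes). Zero deltas are a no-op.
#'
#' @param sex Target group, `"female"` or `"male"`.
#' @param eye Target eye, `"OD"` or `"OS"`.
#' @param layer Target layer name.
#' @param quadrant Target quadrant, `"Q1"`..`"Q4"`.
#' @param delta_corr_length Additive change to the texture correlation
#'   length (pixels).
#' @param delta_sd Additive change to the texture standard deviation
#'   (reflectivity units).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(sex, eye, layer, quadrant,
                        delta_corr_length = 0, delta_sd = 0) {
  sex <- match.arg(sex, c("female", "male"))
  eye <- match.arg(eye, EYES)
  quadrant <- match.arg(quadrant, QUADRANTS)
  if (!layer %in% NEURORETINA_LAYERS) {
    stop(sprintf("unknown layer '%s'", layer), call. = FALSE)
  }
  structure(list(sex = sex, eye = eye, layer = layer, quadrant = quadrant,
                 delta_corr_length = as.numeric(delta_corr_length),
                 delta_sd = as.numeric(delta_sd)),
            class = "effect_spec")
}

#' Generate layer interface surfaces
#'
#' Draws seven (or `n_layers + 1`) ordered surfaces `z_0 <= ... <= z_n` over
#' the en-face grid: a smoothly perturbed top surface, smoothly perturbed
#' per-layer thicknesses, and a radial Gaussian foveal depression that
#' shrinks the inner layers (all but ONL) multiplicatively, down to zero
#' thickness at the centre when `foveal_dip_depth` reaches the local
#' inner-layer sum. Depths are fractional voxels in `[0, n_depth]`.
#' Consumes the current RNG stream.
#'
#' @param vconfig A [volume_config()].
#' @return An object of class `layer_interfaces`: list with `z` (array
#'   `n_bscan x n_ascan x (n_layers + 1)`) and `layers`.
#' @export
generate_interfaces <- function(vconfig) {
  stopifnot(inherits(vconfig, "volume_config"))
  nb <- vconfig$n_bscan; na <- vconfig$n_ascan
  L <- length(vconfig$layers)
  aspect <- na / nb

  z0 <- vconfig$top_margin +
    smooth_noise_field_coarse(nb, na, vconfig$interface_smoothness,
                              vconfig$interface_sd, aspect)
  z0[z0 < 0] <- 0

  thick <- array(0, dim = c(nb, na, L))
  for (k in seq_len(L)) {
    thick[, , k] <- pmax(1, vconfig$layer_mean_thickness[k] +
                              smooth_noise_field_coarse(nb, na,
                                                        vconfig$interface_smoothness,
                                                        vconfig$thickness_sd,
                                                        aspect))
  }

  # radial foveal depression, isotropic in physical units
  r0 <- (nb + 1) / 2; c0 <- (na + 1) / 2
  rows <- seq_len(nb) - r0
  cols <- (seq_len(na) - c0) / aspect
  r2 <- outer(rows^2, cols^2, `+`)
  dip <- vconfig$foveal_dip_depth * exp(-r2 / (2 * vconfig$foveal_dip_radius^2))

  inner <- which(vconfig$layers != "ONL")
  if (length(inner) > 0 && vconfig$foveal_dip_depth > 0) {
    inner_sum <- Reduce(`+`, lapply(inner, function(k) thick[, , k]))
    shrink <- pmax(0, 1 - dip / inner_sum)
    for (k in inner) thick[, , k] <- thick[, , k] * shrink
  }

  z <- array(0, dim = c(nb, na, L + 1))
  z[, , 1] <- z0
  for (k in seq_len(L)) z[, , k + 1] <- z[, , k] + thick[, , k]
  # rare tail realizations of the perturbation fields may overshoot the
  # scan depth; clip (preserves surface ordering), mimicking a truncated
  # acquisition window. Configurations whose mean geometry cannot fit are
  # rejected at construction time by volume_config().
  if (max(z[, , L + 1]) > vconfig$n_depth) {
    z <- pmin(z, vconfig$n_depth)
  }
  structure(list(z = z, layers = vconfig$layers), class = "layer_interfaces")
}

# En-face footprint (volume coordinates) of a quadrant of the
# orientation-standardised image. Quadrants live on the downsampled 128x128
# post-flip grid as 3x3 tile groups of the 7x7/18px block grid; this maps
# their pixel ranges back to the native n_bscan x n_ascan grid of the given
# eye (columns mirrored for OS, whose MVF is flipped downstream).
quadrant_footprint <- function(quadrant, eye, n_bscan, n_ascan) {
  quadrant <- match.arg(quadrant, QUADRANTS)
  eye <- match.arg(eye, EYES)
  tile <- 18L
  low <- 1:(3 * tile)            # tiles 1..3 on the 128 grid
  high <- (4 * tile + 1):(7 * tile)  # tiles 5..7
  rows128 <- if (quadrant %in% c("Q1", "Q2")) low else high
  cols128 <- if (quadrant %in% c("Q1", "Q3")) low else high
  row_scale <- n_bscan / 128
  col_scale <- n_ascan / 128
  rows <- ((min(rows128) - 1) * row_scale + 1):(max(rows128) * row_scale)
  cols <- ((min(cols128) - 1) * col_scale + 1):(max(cols128) * col_scale)
  if (eye == "OS") cols <- sort(n_ascan + 1 - cols)
  list(rows = as.integer(rows), cols = as.integer(cols))
}

#' Generate one synthetic eye volume
#'
#' Builds the segmented OCT-like intensity volume of one eye of one
#' participant: interface surfaces, per-layer texture fields, matching
#' injected effects, voxel noise, rounding and clipping to 0-255. All
#' randomness comes from a substream keyed by
#' `(seed, participant_id, eye)` (see [substream_seed()]), so adding
#' participants to a cohort never changes existing volumes. The caller's
#' RNG state is preserved.
#'
#' @param participant One-row data frame (or list) with `participant_id` and
#'   `sex`.
#' @param eye `"OD"` or `"OS"`.
#' @param vconfig A [volume_config()].
#' @param effects List of [effect_spec()] objects; only those matching this
#'   participant's sex and this eye are applied.
#' @param seed Base integer seed of the dataset.
#' @return List with `volume` (class `oct_volume`: `intensity` array
#'   `n_bscan x n_depth x n_ascan`, `eye`, `participant_id`) and
#'   `interfaces` (class `layer_interfaces`).
#' @export
generate_eye_volume <- function(participant, eye, vconfig, effects = list(),
                                seed = 1L) {
  stopifnot(inherits(vconfig, "volume_config"))
  eye <- match.arg(eye, EYES)
  pid <- participant$participant_id
  sex <- participant$sex
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop("`effects` must be effect_spec objects",
                                           call. = FALSE)
    if (!ef$layer %in% vconfig$layers) {
      stop(sprintf("effect targets layer '%s' absent from this volume", ef$layer),
           call. = FALSE)
    }
  }
  sub <- substream_seed(seed, pid, eye)
  with_preserved_rng(sub, {
    interfaces <- generate_interfaces(vconfig)
    nb <- vconfig$n_bscan; na <- vconfig$n_ascan
    L <- length(vconfig$layers)
    aspect <- na / nb

    fields <- matrix(0, nb * na, L)
    for (k in seq_len(L)) {
      f <- smooth_noise_field(nb, na, vconfig$texture_corr_length[k],
                              vconfig$texture_sd[k], aspect)
      fields[, k] <- as.vector(f)
    }
    for (ef in effects) {
      if (ef$sex != sex || ef$eye != eye) next
      if (ef$delta_corr_length == 0 && ef$delta_sd == 0) next
      k <- match_layer(ef$layer, vconfig$layers)
      fp <- quadrant_footprint(ef$quadrant, eye, nb, na)
      # effect fields come from their own substream so that voxels outside
      # the footprint stay bit-identical to the no-effect volume
      g <- with_preserved_rng(
        substream_seed(seed, pid, eye, "effect", ef$layer, ef$quadrant),
        smooth_noise_field(nb, na,
                           vconfig$texture_corr_length[k] + ef$delta_corr_length,
                           vconfig$texture_sd[k] + ef$delta_sd, aspect)
      )
      f <- matrix(fields[, k], nb, na)
      f[fp$rows, fp$cols] <- g[fp$rows, fp$cols]
      fields[, k] <- as.vector(f)
    }

    tops <- matrix(0L, nb * na, L + 1)
    for (s in seq_len(L + 1)) tops[, s] <- as.integer(ceiling(interfaces$z[, , s]))

    vol <- assemble_volume_cpp(tops, fields, unname(vconfig$intensity_base),
                               vconfig$background, vconfig$noise_sd,
                               nb, vconfig$n_depth, na)
    dim(vol) <- c(nb, vconfig$n_depth, na)
    volume <- structure(list(intensity = vol, eye = eye, participant_id = pid),
                        class = "oct_volume")
    list(volume = volume, interfaces = interfaces)
  })
}
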