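#' Compute a mean value fundus (MVF) image for one layer
#'
#' Each en-face pixel is the depth-wise average of the A-scan voxels lying
#' between the two interfaces that delineate the layer. Fractional interface
#' depths `z_top`, `z_bottom` are rounded to the integer voxel span
#' `[ceil(z_top), ceil(z_bottom))` (0-based); pixels with an empty span
#' (zero layer thickness, e.g. at the foveal pit) are masked invalid and
#' carry `NA`, never a silent zero.
#'
#' @param volume An `oct_volume` (see [generate_eye_volume()]).
#' @param interfaces A `layer_interfaces` object on the same en-face grid.
#' @param layer Layer name, one of `interfaces$layers`.
#' @return An object of class `mvf_image`: list with `values`
#'   (`n_bscan x n_ascan` matrix, `NA` where invalid), `mask` (logical
#'   matrix, `TRUE` = valid), `layer`, `eye`, `participant_id`, `flipped`.
#' @export
compute_mvf <- function(volume, interfaces, layer) {
  stopifnot(inherits(volume, "oct_volume"), inherits(interfaces, "layer_interfaces"))
  k <- match_layer(layer, interfaces$layers)
  dims <- dim(volume$intensity)
  nb <- dims[1]; nd <- dims[2]; na_ <- dims[3]
  if (!all(dim(interfaces$z)[1:2] == c(nb, na_))) {
    stop("volume and interfaces do not share the en-face grid", call. = FALSE)
  }
  z_top <- interfaces$z[, , k]
  z_bot <- interfaces$z[, , k + 1]
  if (min(z_top) < 0 || max(z_bot) > nd) {
    stop("interfaces exceed the volume depth range", call. = FALSE)
  }
  top <- as.integer(ceiling(z_top))
  bot <- as.integer(ceiling(z_bot))
  out <- mvf_project_cpp(volume$intensity, top, bot, nb, nd, na_)
  npix <- nb * na_
  values <- matrix(out[seq_len(npix)], nb, na_)
  mask <- matrix(out[npix + seq_len(npix)] > 0, nb, na_)
  structure(list(values = values, mask = mask, layer = layer,
                 eye = volume$eye, participant_id = volume$participant_id,
                 flipped = FALSE),
            class = "mvf_image")
}

#' Standardise MVF orientation across eyes
#'
#' Left-eye (OS) images are mirrored along the A-scan (column) axis so that
#' the temporal retina sits on the low-column side for every eye and
#' right/left features are positionally comparable; right-eye (OD) images
#' are returned unchanged. Applying the flip twice restores the original.
#'
#' @param mvf An `mvf_image`.
#' @return The orientation-standardised `mvf_image` (`flipped` toggled for
#'   OS input).
#' @export
standardise_orientation <- function(mvf) {
  stopifnot(inherits(mvf, "mvf_image"))
  if (mvf$eye == "OD") return(mvf)
  nc <- ncol(mvf$values)
  mvf$values <- mvf$values[, nc:1, drop = FALSE]
  mvf$mask <- mvf$mask[, nc:1, drop = FALSE]
  mvf$flipped <- !mvf$flipped
  mvf
}
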