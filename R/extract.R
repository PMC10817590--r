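#' Texture features of one segmented eye scan
#'
#' Projects every layer to its MVF image, standardises orientation (left
#' eyes are flipped), and runs the texture chain, yielding
#' `21 features x n_layers x 4 quadrants` rows (504 for the full six-layer
#' protocol).
#'
#' @param volume An `oct_volume`.
#' @param interfaces Matching `layer_interfaces`.
#' @param participant List or one-row data frame with `participant_id`,
#'   `sex`, `age`.
#' @param config A [glcm_config()].
#' @return Feature table rows: `participant_id`, `sex`, `age`, `eye`,
#'   `layer`, `quadrant`, `feature`, `value`.
#' @export
scan_features <- function(volume, interfaces, participant,
                          config = glcm_config()) {
  per_layer <- lapply(interfaces$layers, function(layer) {
    mvf <- compute_mvf(volume, interfaces, layer)
    mvf <- standardise_orientation(mvf)
    mvf_texture_features(mvf, config)
  })
  out <- do.call(rbind, per_layer)
  data.frame(participant_id = participant$participant_id,
             sex = participant$sex, age = participant$age,
             eye = volume$eye, out, stringsAsFactors = FALSE)
}

#' Extract the feature table for a whole synthetic cohort
#'
#' Generates each eye volume in turn (constant memory) and extracts its
#' texture features. Fully deterministic given `cconfig$seed`; per-scan RNG
#' substreams mean the result for a participant does not depend on which
#' other participants are present.
#'
#' @param cconfig A [cohort_config()].
#' @param vconfig A [volume_config()].
#' @param effects List of [effect_spec()] objects.
#' @param config A [glcm_config()].
#' @return The tidy feature table (one row per participant, eye, layer,
#'   quadrant, feature).
#' @export
extract_features_cohort <- function(cconfig, vconfig, effects = list(),
                                    config = glcm_config()) {
  cohort <- generate_cohort(cconfig)
  rows <- vector("list", nrow(cohort) * 2L)
  k <- 0L
  for (p in seq_len(nrow(cohort))) {
    for (eye in EYES) {
      scan <- generate_eye_volume(cohort[p, ], eye, vconfig, effects,
                                  seed = cconfig$seed)
      k <- k + 1L
      rows[[k]] <- scan_features(scan$volume, scan$interfaces, cohort[p, ],
                                 config)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the feature table from a dataset on disk
#'
#' Streams the scans listed in a dataset manifest (see [write_dataset()] /
#' [simulate_dataset()]) and extracts texture features scan by scan.
#'
#' @param manifest Path to `manifest.json` or the dataset directory.
#' @param config A [glcm_config()].
#' @return The tidy feature table; an empty manifest gives an empty table.
#' @export
extract_features <- function(manifest, config = glcm_config()) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  m <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  if (length(m$scans) == 0) {
    return(data.frame(participant_id = character(), sex = character(),
                      age = numeric(), eye = character(), layer = character(),
                      quadrant = character(), feature = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  missing <- character()
  for (s in m$scans) {
    for (f in c(s$volume, s$interfaces)) {
      if (!file.exists(file.path(base, f))) missing <- c(missing, f)
    }
  }
  if (length(missing) > 0) {
    stop("missing scan files: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(m$scans, function(s) {
    vol <- read_volume_tiff(file.path(base, s$volume), eye = s$eye,
                            participant_id = s$participant_id)
    ifc <- read_interfaces_csv(file.path(base, s$interfaces))
    scan_features(vol, ifc, list(participant_id = s$participant_id,
                                 sex = s$sex, age = s$age), config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
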