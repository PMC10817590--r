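#' Write a synthetic dataset to disk
#'
#' Volumes are written as multi-page 8-bit TIFF (one page per B-scan; page
#' rows = depth, columns = A-scans; voxel values 0-255 are stored exactly),
#' interfaces as CSV (`bscan`, `ascan`, `z_0` .. `z_L` in fractional
#' voxels), the cohort as CSV (`participant_id`, `sex`, `age`), plus a JSON
#' manifest listing every scan with its participant and eye.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param scans List of scans, each a list with `volume` (`oct_volume`) and
#'   `interfaces` (`layer_interfaces`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
write_dataset <- function(cohort, scans, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  entries <- vector("list", length(scans))
  for (s in seq_along(scans)) {
    vol <- scans[[s]]$volume
    ifc <- scans[[s]]$interfaces
    stem <- sprintf("%s_%s", vol$participant_id, vol$eye)
    tiff_file <- paste0(stem, ".tiff")
    csv_file <- paste0(stem, "_interfaces.csv")
    write_volume_tiff(vol, file.path(out_dir, tiff_file))
    write_interfaces_csv(ifc, file.path(out_dir, csv_file))
    row <- cohort[cohort$participant_id == vol$participant_id, , drop = FALSE]
    entries[[s]] <- list(participant_id = vol$participant_id,
                         sex = if (nrow(row)) row$sex[1] else NA_character_,
                         age = if (nrow(row)) row$age[1] else NA_real_,
                         eye = vol$eye, volume = tiff_file,
                         interfaces = csv_file)
  }
  manifest <- list(format = "oculotex-dataset", version = 1L,
                   cohort = "cohort.csv", scans = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param volume An `oct_volume`.
#' @param path Output file path.
#' @export
write_volume_tiff <- function(volume, path) {
  v <- volume$intensity
  pages <- lapply(seq_len(dim(v)[1]), function(b) v[b, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF file path.
#' @param eye,participant_id Labels to attach (usually from the manifest).
#' @return An `oct_volume`.
#' @export
read_volume_tiff <- function(path, eye = "OD", participant_id = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- length(pages)
  nd <- nrow(pages[[1]]); na_ <- ncol(pages[[1]])
  v <- array(0, dim = c(nb, nd, na_))
  for (b in seq_len(nb)) v[b, , ] <- round(pages[[b]] * 255)
  structure(list(intensity = v, eye = eye, participant_id = participant_id),
            class = "oct_volume")
}

write_interfaces_csv <- function(interfaces, path) {
  z <- interfaces$z
  nb <- dim(z)[1]; na_ <- dim(z)[2]; ns <- dim(z)[3]
  df <- data.frame(bscan = rep(seq_len(nb), times = na_),
                   ascan = rep(seq_len(na_), each = nb))
  for (s in seq_len(ns)) df[[paste0("z_", s - 1L)]] <- as.vector(z[, , s])
  attr_line <- paste0("# layers: ", paste(interfaces$layers, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an interface table written by the dataset writer
#'
#' @param path CSV file path (with the `# layers:` header comment).
#' @return A `layer_interfaces` object.
#' @export
read_interfaces_csv <- function(path) {
  first <- readLines(path, n = 1)
  layers <- if (startsWith(first, "# layers:")) {
    strsplit(sub("^# layers: *", "", first), ",")[[1]]
  } else NEURORETINA_LAYERS
  df <- utils::read.csv(path, comment.char = "#")
  nb <- max(df$bscan); na_ <- max(df$ascan)
  zcols <- grep("^z_", names(df), value = TRUE)
  zcols <- zcols[order(as.integer(sub("z_", "", zcols)))]
  z <- array(0, dim = c(nb, na_, length(zcols)))
  ord <- order(df$ascan, df$bscan)
  for (s in seq_along(zcols)) z[, , s] <- df[[zcols[s]]][ord]
  structure(list(z = z, layers = layers), class = "layer_interfaces")
}

#' Simulate a cohort dataset and write it to disk
#'
#' Streams over participants and eyes: each scan is generated (see
#' [generate_eye_volume()]) and written before the next one is created, so
#' memory stays at one volume. Deterministic given the configs.
#'
#' @param cconfig A [cohort_config()].
#' @param vconfig A [volume_config()].
#' @param effects List of [effect_spec()] objects.
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
simulate_dataset <- function(cconfig, vconfig, effects = list(), out_dir) {
  cohort <- generate_cohort(cconfig)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  entries <- list()
  for (p in seq_len(nrow(cohort))) {
    for (eye in EYES) {
      scan <- generate_eye_volume(cohort[p, ], eye, vconfig, effects,
                                  seed = cconfig$seed)
      stem <- sprintf("%s_%s", cohort$participant_id[p], eye)
      write_volume_tiff(scan$volume, file.path(out_dir, paste0(stem, ".tiff")))
      write_interfaces_csv(scan$interfaces,
                           file.path(out_dir, paste0(stem, "_interfaces.csv")))
      entries[[length(entries) + 1L]] <-
        list(participant_id = cohort$participant_id[p], sex = cohort$sex[p],
             age = cohort$age[p], eye = eye,
             volume = paste0(stem, ".tiff"),
             interfaces = paste0(stem, "_interfaces.csv"))
    }
  }
  manifest <- list(format = "oculotex-dataset", version = 1L,
                   cohort = "cohort.csv", scans = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
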