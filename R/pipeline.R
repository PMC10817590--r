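#' Full-run configuration
#'
#' Collects every stage's parameters in one object so a complete run is
#' reproducible from a single config (and a config hash can stamp every
#' output).
#'
#' @param cohort A [cohort_config()].
#' @param volume A [volume_config()].
#' @param effects List of [effect_spec()] objects.
#' @param glcm A [glcm_config()].
#' @param alpha,sw_level,r_threshold,lambda Statistical parameters (see
#'   [run_group_analysis()]).
#' @param recompute_after_discard Selection traversal variant.
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param keep_volumes Also write the raw TIFF/CSV dataset (slow and large;
#'   default `FALSE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), volume = volume_config(),
                       effects = list(), glcm = glcm_config(),
                       alpha = 0.05, sw_level = 0.10, r_threshold = 0.5,
                       lambda = 0.5, recompute_after_discard = FALSE,
                       out_dir = NULL, keep_volumes = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(volume, "volume_config"),
            inherits(glcm, "glcm_config"))
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("`r_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(cohort = cohort, volume = volume, effects = effects,
                 glcm = glcm, alpha = alpha, sw_level = sw_level,
                 r_threshold = r_threshold, lambda = lambda,
                 recompute_after_discard = recompute_after_discard,
                 out_dir = out_dir, keep_volumes = keep_volumes),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a nested YAML file whose top-level keys mirror the arguments of
#' [run_config()] (`cohort:`, `volume:`, `glcm:`, `effects:` as a list of
#' effect entries, plus the scalar statistical parameters).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$volume)) args$volume <- do.call(volume_config, y$volume)
  if (!is.null(y$glcm)) args$glcm <- do.call(glcm_config, y$glcm)
  if (!is.null(y$effects)) {
    args$effects <- lapply(y$effects, function(e) do.call(effect_spec, e))
  }
  for (k in c("alpha", "sw_level", "r_threshold", "lambda",
              "recompute_after_discard", "out_dir", "keep_volumes")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

#' Run the complete pipeline
#'
#' simulate -> project -> extract -> analyse: generates the synthetic
#' cohort, extracts the texture feature table, runs the interocular
#' analysis for both sex groups, and (when `out_dir` is set) writes the
#' feature CSV, per-group selection/test/correction CSVs, the state-grid
#' TSV, and a JSON run report. Fully deterministic given the config.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return An object of class `run_report`: list with `config_hash`,
#'   `features`, per-group `analyses`, `counts`, and `files` (written
#'   artifact paths, if any).
#' @export
run_all <- function(config = run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config[setdiff(names(config), c("out_dir", "keep_volumes"))])
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]

  say("[simulate/extract] cohort of 2 x %d participants", config$cohort$n_per_group)
  features <- extract_features_cohort(config$cohort, config$volume,
                                      config$effects, config$glcm)
  say("[extract] %d feature rows (%.1fs)", nrow(features), proc.time()[3] - t0)

  analyses <- lapply(c(female = "female", male = "male"), function(g) {
    run_group_analysis(features, g, alpha = config$alpha,
                       sw_level = config$sw_level,
                       r_threshold = config$r_threshold,
                       lambda = config$lambda,
                       recompute_after_discard = config$recompute_after_discard)
  })
  say("[analyse] done (%.1fs)", proc.time()[3] - t0)

  counts <- lapply(analyses, `[[`, "counts")
  files <- character()
  if (!is.null(config$out_dir)) {
    files <- write_run_artifacts(config, features, analyses, counts, hash)
  }
  structure(list(config_hash = hash, features = features, analyses = analyses,
                 counts = counts, files = files,
                 elapsed_s = unname(proc.time()[3] - t0)),
            class = "run_report")
}

write_run_artifacts <- function(config, features, analyses, counts, hash) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name, tsv = FALSE) {
    path <- file.path(out, name)
    if (tsv) utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                quote = FALSE)
    else utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  w(features, "features.csv")
  for (g in names(analyses)) {
    a <- analyses[[g]]
    w(a$correlations[a$correlations$correlated, , drop = FALSE],
      sprintf("correlated_pairs_%s.csv", g))
    sel <- data.frame(feature = c(a$selection$kept, a$selection$discarded$feature),
                      status = c(rep("kept", length(a$selection$kept)),
                                 rep("discarded", nrow(a$selection$discarded))),
                      removed_by = c(rep(NA_character_, length(a$selection$kept)),
                                     a$selection$discarded$removed_by),
                      stringsAsFactors = FALSE)
    w(sel, sprintf("selection_%s.csv", g))
    w(a$tests, sprintf("tests_%s.csv", g))
    adj <- data.frame(feature = names(a$corrections$bonferroni$p),
                      p = unname(a$corrections$bonferroni$p),
                      bonferroni = unname(a$corrections$bonferroni$adjusted),
                      bh = unname(a$corrections$benjamini_hochberg$adjusted),
                      q_storey = unname(a$corrections$storey$adjusted),
                      stringsAsFactors = FALSE)
    w(adj, sprintf("corrections_%s.csv", g))
    w(a$grid, sprintf("grid_%s.tsv", g), tsv = TRUE)
  }
  report <- list(package = "oculotex",
                 version = as.character(utils::packageVersion("oculotex")),
                 config_hash = hash, counts = counts,
                 files = basename(files))
  path <- file.path(out, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (isTRUE(config$keep_volumes)) {
    simulate_dataset(config$cohort, config$volume, config$effects,
                     file.path(out, "dataset"))
    files <- c(files, file.path(out, "dataset", "manifest.json"))
  }
  c(files, path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("oculotex run %s (%.1fs)\n", x$config_hash, x$elapsed_s))
  for (g in names(x$counts)) {
    ct <- x$counts[[g]]
    cat(sprintf("  %-6s kept %d/%d | sig: %d uncorrected, %d bonferroni, %d BH, %d storey | FDR %.1f%%\n",
                g, ct$n_kept, ct$n_features, ct$uncorrected, ct$bonferroni,
                ct$benjamini_hochberg, ct$storey, 100 * ct$fdr_estimate))
  }
  invisible(x)
}

#' Render the per-feature state grid
#'
#' Draws the feature x (layer, quadrant) state matrix of a group analysis
#' (the overview of which features were decorrelated away, tested, and
#' significant before/after correction) and writes it as an image plus a
#' TSV that reproduces the states exactly.
#'
#' @param analysis A `group_analysis` (or its `grid` data frame).
#' @param file Image output path (extension selects the device, e.g.
#'   `.pdf` or `.png`); `NULL` for no image.
#' @param tsv TSV output path, or `NULL`.
#' @return The ggplot object, invisibly.
#' @export
render_grid <- function(analysis, file = NULL, tsv = NULL) {
  grid <- if (inherits(analysis, "group_analysis")) analysis$grid else analysis
  grid$column <- paste(grid$layer, grid$quadrant, sep = "/")
  grid$column <- factor(grid$column,
                        levels = unique(grid$column[order(match(grid$layer, NEURORETINA_LAYERS),
                                                          grid$quadrant)]))
  grid$feature <- factor(grid$feature, levels = rev(glcm_feature_names()))
  states <- c("correlated-out" = "grey70", "non-significant" = "white",
              "significant-uncorrected" = "steelblue2",
              "significant-corrected" = "orangered3")
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = column, y = feature,
                                          fill = state)) +
    ggplot2::geom_tile(colour = "grey40", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = states, drop = FALSE) +
    ggplot2::labs(x = "layer/quadrant", y = NULL, fill = "state") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(tsv)) {
    utils::write.table(grid[, c("feature_id", "feature", "layer", "quadrant",
                                "state", "corrected_by")],
                       tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4.5)
  }
  invisible(p)
}
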