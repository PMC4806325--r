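#' Configuration for a full reproducibility run
#'
#' @param mode `"synthetic"` (generate a phantom cohort) or `"manifest"`
#'   (ingest an existing cohort directory).
#' @param n_subjects Cohort size in synthetic mode.
#' @param cohort_dir Cohort directory; required in manifest mode, created
#'   under `out_dir` in synthetic mode.
#' @param out_dir Output directory for CSV reports and metadata.
#' @param seed Master seed; all stage seeds are derived from it (cohort
#'   seed = `seed`, bootstrap seed = `seed + 500`).
#' @param outlier_policy `"none"` or `"dixon-screen"` (see [ccc_matrix()]).
#' @param cutoffs Ascending CCC cut-offs for the summary table.
#' @param spec_ranges Phantom parameter ranges (see [generate_cohort()]).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "manifest"), n_subjects = 30L,
                       cohort_dir = NULL, out_dir = tempfile("radrepro_"),
                       seed = 1L, outlier_policy = "none",
                       cutoffs = c(0.85, 0.90, 0.95),
                       spec_ranges = cohort_defaults()) {
  mode <- match.arg(mode)
  if (mode == "manifest" && is.null(cohort_dir))
    stop("manifest mode needs `cohort_dir`", call. = FALSE)
  stopifnot(!is.unsorted(cutoffs))
  structure(list(mode = mode, n_subjects = as.integer(n_subjects),
                 cohort_dir = cohort_dir, out_dir = out_dir,
                 seed = as.integer(seed), outlier_policy = outlier_policy,
                 cutoffs = cutoffs, spec_ranges = spec_ranges),
            class = "run_config")
}

registry_version <- function() "1.0"

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), c("out_dir", "cohort_dir"))]
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full reproducibility pipeline
#'
#' Phantom generation (or manifest ingestion), 89-feature extraction for
#' every (subject, scan, setting), per-feature concordance over the 6
#' identical-setting and 3 cross-kernel pairs, cut-off summaries and
#' heat-map export. Writes `features.csv`, `ccc.csv`, `summary.csv`,
#' `heatmap.csv` and `metadata.json` into the output directory; numeric
#' CSV cells use a fixed 10-significant-digit format and each CSV carries
#' the registry version and config hash as a leading comment line, so
#' re-running an identical configuration reproduces every file
#' byte-identically.
#'
#' @param config A [run_config()].
#' @param progress Print stage progress to stderr.
#' @return A `radiomics_run` object: tables `features`, `ccc`, `summary`,
#'   `heatmap`, the `manifest` and the output paths.
#' @export
run_radiomics <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message("[radrepro] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta_line <- sprintf("# radrepro registry %s config %s",
                       registry_version(), hash)

  stage <- "cohort"
  res <- tryCatch({
    if (config$mode == "synthetic") {
      say("generating synthetic cohort (n = ", config$n_subjects, ")")
      cohort_dir <- config$cohort_dir %||% file.path(config$out_dir, "cohort")
      manifest <- generate_cohort(config$n_subjects, cohort_dir,
                                  seed = config$seed,
                                  spec_ranges = config$spec_ranges)
    } else {
      manifest <- load_manifest(config$cohort_dir)
    }

    stage <- "features"
    say("extracting features for ", nrow(manifest), " volumes")
    features <- extract_cohort_features(manifest)
    write_numeric_csv(features[, c("subject_id", "scan", "setting",
                                   "feature", "class", "value")],
                      file.path(config$out_dir, "features.csv"),
                      meta = meta_line)

    stage <- "concordance"
    say("computing concordance records")
    records <- ccc_matrix(features, setting_pairs("all"),
                          outlier_policy = config$outlier_policy)
    write_numeric_csv(records, file.path(config$out_dir, "ccc.csv"),
                      meta = meta_line)
    summary <- summarize_cutoffs(records, config$cutoffs)
    write_numeric_csv(summary, file.path(config$out_dir, "summary.csv"),
                      meta = meta_line)
    heat <- export_heatmap(records)
    write_numeric_csv(heat, file.path(config$out_dir, "heatmap.csv"),
                      meta = meta_line)

    jsonlite::write_json(
      list(registry_version = registry_version(), config_hash = hash,
           seed = config$seed, mode = config$mode,
           n_subjects = config$n_subjects,
           outlier_policy = config$outlier_policy, cutoffs = config$cutoffs,
           derived_seeds = list(cohort = config$seed,
                                bootstrap = config$seed + 500L)),
      file.path(config$out_dir, "metadata.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    structure(list(features = features, ccc = records, summary = summary,
                   heatmap = heat, manifest = manifest,
                   out_dir = config$out_dir, config = config, hash = hash),
              class = "radiomics_run")
  }, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
  say("done: ", config$out_dir)
  res
}

#' @export
print.radiomics_run <- function(x, ...) {
  cat("<radiomics_run>\n")
  cat("  subjects:", dplyr::n_distinct(x$features$subject_id),
      " settings:", dplyr::n_distinct(x$features$setting),
      " features:", dplyr::n_distinct(x$features$feature), "\n")
  cat("  output:", x$out_dir, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the concordance records of a run
#'
#' @param x A `radiomics_run`.
#' @param ... Unused.
#' @return The `ccc_records` tibble.
#' @method tidy radiomics_run
#' @export
tidy.radiomics_run <- function(x, ...) x$ccc

#' One-row summary of a run
#'
#' @param x A `radiomics_run`.
#' @param cutoff Reproducibility threshold.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, feature count, mean CCC over
#'   identical-setting and cross-kernel pairs, and the count of
#'   reproducible features at `cutoff` for the best identical setting.
#' @method glance radiomics_run
#' @export
glance.radiomics_run <- function(x, cutoff = 0.85, ...) {
  rec <- x$ccc
  tibble::tibble(
    n_subjects = dplyr::n_distinct(x$features$subject_id),
    n_features = dplyr::n_distinct(rec$feature),
    mean_ccc_identical = mean(rec$ccc[rec$type == "identical"], na.rm = TRUE),
    mean_ccc_cross = mean(rec$ccc[rec$type == "cross"], na.rm = TRUE),
    max_reproducible = max(vapply(
      split(rec, rec$pair),
      function(s) sum(!is.na(s$ccc) & s$ccc >= cutoff), numeric(1))))
}

#' Heat-map plot of concordance records
#'
#' Features (registry order, grouped by class) against comparison pairs;
#' brighter red means higher CCC. Undefined CCCs render grey.
#'
#' @param object A `ccc_records` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccc_records
#' @export
autoplot.ccc_records <- function(object, ...) {
  reg <- feature_registry()
  df <- object
  df$feature <- factor(df$feature, levels = rev(reg$feature))
  df$pair <- factor(df$pair, levels = setting_pairs("all")$pair)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$feature,
                                   fill = .data$ccc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "red",
                                 limits = c(0, 1), na.value = "grey70",
                                 oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CCC") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# clamp out-of-range CCCs (negative values) into the displayed scale
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
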