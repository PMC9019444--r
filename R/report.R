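#' STA deviation summary per group
#'
#' Reports, per group, the range of pre (STA1) and post (STA2) scores and the
#' sample standard deviation (ddof 1) of the paired pre-minus-post
#' differences. Groups with fewer than 2 records are omitted with a warning.
#'
#' @param records data frame with columns subject_id, group, sta1, sta2.
#' @return data frame with one row per group: group, n, sta1_min, sta1_max,
#'   sta2_min, sta2_max, sd_diff, mean_diff.
#' @export
sta_deviation <- function(records) {
  rows <- lapply(unique(records$group), function(g) {
    r <- records[records$group == g, ]
    if (nrow(r) < 2) {
      warning(sprintf("group '%s' has fewer than 2 records; omitted", g))
      return(NULL)
    }
    d <- r$sta1 - r$sta2
    data.frame(group = g, n = nrow(r),
               sta1_min = min(r$sta1), sta1_max = max(r$sta1),
               sta2_min = min(r$sta2), sta2_max = max(r$sta2),
               mean_diff = mean(d), sd_diff = stats::sd(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no group with at least 2 records")
  rownames(out) <- NULL
  out
}

# Collapse channels that share subset/intervention/band and identical metrics
# into one display row (Table-style presentation only).
collapse_channels <- function(tab) {
  if (nrow(tab) == 0) return(tab)
  key <- interaction(tab$subset, tab$intervention, tab$band,
                     round(tab$accuracy, 2), round(tab$sensitivity, 2),
                     round(tab$specificity, 2), drop = TRUE)
  rows <- lapply(split(tab, key), function(grp) {
    grp <- grp[order(grp$channel), ]
    out <- grp[1, , drop = FALSE]
    out$channel <- paste(grp$channel, collapse = ", ")
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subset, out$intervention, -out$accuracy), ]
  rownames(out) <- NULL
  out
}

#' Build the classification + STA report
#'
#' Produces (i) a filtered table keeping only cells whose accuracy, rounded
#' to 2 decimals, is at or above the acceptability threshold, with channels
#' sharing a band and identical metrics collapsed into one row; (ii) the full
#' unfiltered sweep; (iii) the STA deviation summary; and optionally (iv)
#' per-region box plots of the activity feature. Files are written when
#' `out_dir` is given.
#'
#' @param sweep sweep table from [channel_band_sweep()].
#' @param sta STA summary from [sta_deviation()], or `NULL`.
#' @param threshold acceptability threshold in percent.
#' @param out_dir optional output directory.
#' @param features optional feature table; enables the regional activity
#'   box plots (requires ggplot2).
#' @return list with `filtered`, `full`, `sta` (and `plot_file` if plotted).
#' @export
make_report <- function(sweep, sta = NULL, threshold = 70, out_dir = NULL,
                        features = NULL) {
  if (nrow(sweep) == 0) stopf("sweep table is empty")
  ok <- !is.na(sweep$accuracy) & round(sweep$accuracy, 2) >= threshold
  filtered <- collapse_channels(sweep[ok, , drop = FALSE])
  out <- list(filtered = filtered, full = sweep, sta = sta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(filtered, file.path(out_dir, "report_filtered.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(sweep, file.path(out_dir, "report_full.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sta))
      utils::write.table(sta, file.path(out_dir, "sta_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(features) && requireNamespace("ggplot2", quietly = TRUE)) {
      out$plot_file <- file.path(out_dir, "activity_by_region.pdf")
      region_of <- rep(names(EEG_REGIONS), lengths(EEG_REGIONS))
      names(region_of) <- unlist(EEG_REGIONS)
      pf <- features
      pf$region <- region_of[pf$channel]
      p <- ggplot2::ggplot(pf, ggplot2::aes(x = .data$condition,
                                            y = .data$activity)) +
        ggplot2::geom_boxplot(outlier.size = 0.4) +
        ggplot2::facet_grid(region ~ group, scales = "free_y") +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = NULL, y = "Hjorth activity (µV², log scale)")
      ggplot2::ggsave(out$plot_file, p, width = 8, height = 9)
    }
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the stage configurations; every stage's randomness is derived
#' deterministically from the global seed.
#'
#' @param simulation a [simulation_config()] (used when simulating), or `NULL`
#'   with `input_dir` pointing at an existing cohort.
#' @param input_dir directory with a cohort written by [write_cohort()]
#'   (ignored when `simulation` is given).
#' @param filter a [filter_spec()].
#' @param wavelet,levels decomposition settings.
#' @param window_s feature window, seconds.
#' @param alpha Wilcoxon retention level.
#' @param classifier a [classifier_spec()].
#' @param subsets,interventions cells to sweep.
#' @param threshold report acceptability threshold, percent.
#' @param seed global seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(simulation = simulation_config(), input_dir = NULL,
                            filter = filter_spec(), wavelet = "db7", levels = 5,
                            window_s = 30, alpha = 0.05,
                            classifier = classifier_spec(),
                            subsets = SUBSET_NAMES,
                            interventions = c("MI-1", "MI-2", "MI-3", "MI-4"),
                            threshold = 70, seed = 1L) {
  if (is.null(simulation) && is.null(input_dir))
    stopf("either a simulation config or an input directory is required")
  if (!is.null(simulation)) {
    simulation$seed <- derive_seed(seed, "simulate")
    simulation <- validate_simulation_config(simulation)
  }
  classifier$seed <- derive_seed(seed, "classify")
  structure(list(simulation = simulation, input_dir = input_dir,
                 filter = filter, wavelet = wavelet, levels = levels,
                 window_s = window_s, alpha = alpha, classifier = classifier,
                 subsets = subsets, interventions = interventions,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  derive_seed(0L, paste(deparse(config), collapse = ""))
}

#' Run the full pipeline
#'
#' simulate (or ingest) -> preprocess -> decompose -> features -> sweep ->
#' report. Intermediates and a manifest (package version, config hash, seed)
#' are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory.
#' @param verbose log per-stage timing to stderr.
#' @return list with `features`, `sweep`, `report`, `sta`, `out_dir`,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("stresswave_run_"),
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, t0) {
    if (verbose)
      message(sprintf("[%s] %s (%.1f s)", format(Sys.time(), "%H:%M:%S"),
                      stage, as.numeric(Sys.time()) - t0))
  }
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    say("simulate", t0)
  } else {
    cohort <- read_cohort(config$input_dir)
    say("ingest", t0)
  }
  t0 <- as.numeric(Sys.time())
  features <- extract_cohort_features(cohort$recordings, config$filter,
                                      config$window_s, config$wavelet,
                                      config$levels)
  write_feature_table(features, file.path(out_dir, "features.tsv"))
  say("features", t0)
  t0 <- as.numeric(Sys.time())
  sweep <- channel_band_sweep(features, config$subsets, config$interventions,
                              config$classifier, config$alpha)
  say("classify", t0)
  t0 <- as.numeric(Sys.time())
  sta <- sta_deviation(cohort$sta)
  report <- make_report(sweep, sta, config$threshold, out_dir,
                        features = features)
  manifest <- list(package = "stresswave",
                   version = as.character(utils::packageVersion("stresswave")),
                   r_version = R.version.string,
                   seed = config$seed, config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("report", t0)
  invisible(list(features = features, sweep = sweep, report = report,
                 sta = sta, out_dir = out_dir))
}
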