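# End-to-end workflow: segment -> ROI -> quantify -> (optionally) evaluate,
# with a machine-readable run manifest for reproducibility.

#' Configuration for an end-to-end pipeline run
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param model A trained [build_unet()] model, or a checkpoint path.
#' @param cohort In-memory cohort: list of subjects, each a list with
#'   `$series` (a [dixon_series()]) and optionally `$truth` (phantom ground
#'   truth) or `$mask` (reference mask) for evaluation.
#' @param series_dirs Alternatively, character vector of series directories
#'   readable by [read_dixon_series()].
#' @param threshold Binarization threshold (default 0.5).
#' @param scope Evaluation scope, see [confusion_counts()].
#' @param min_area_px,match_radius_px ROI extraction parameters, see
#'   [extract_components()] and [assign_vertebra_labels()].
#' @param seed Seed recorded in the manifest (the inference path is
#'   deterministic; the seed matters only if training is requested).
#' @param write_plots Write Bland-Altman / ROC / PR PNGs when ground truth is
#'   available (default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, model = NULL, cohort = NULL,
                            series_dirs = NULL, threshold = 0.5,
                            scope = c("vertebra_slices_only", "all_slices"),
                            min_area_px = 20L, match_radius_px = 15,
                            seed = 1L, write_plots = TRUE) {
  scope <- match.arg(scope)
  if (is.null(cohort) && is.null(series_dirs))
    stopf("pipeline_config needs a cohort or series_dirs")
  structure(list(output_dir = output_dir, model = model, cohort = cohort,
                 series_dirs = series_dirs, threshold = threshold,
                 scope = scope, min_area_px = as.integer(min_area_px),
                 match_radius_px = match_radius_px, seed = as.integer(seed),
                 write_plots = isTRUE(write_plots)),
            class = "pipeline_config")
}

resolve_model <- function(config) {
  m <- config$model
  if (is.null(m)) stopf("validation failure: no model configured")
  if (is.character(m)) {
    if (!file.exists(m))
      stopf("validation failure: model checkpoint '%s' not found", m)
    m <- load_unet(m)
  }
  if (!inherits(m, "unet")) stopf("validation failure: not a unet model")
  m
}

#' Run the automatic segmentation and BMF quantification pipeline
#'
#' For each subject: predict the probability map, binarize, extract/assign/
#' filter ROIs, quantify BMF; when ground truth is available, compute the
#' full agreement battery and a Bland-Altman comparison of ground-truth vs
#' automatic per-vertebra BMF. All tabular outputs are CSV; the evaluation
#' summary is JSON; a run manifest ties outputs to the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `bmf` (combined per-vertebra table),
#'   `evaluation` (list or NULL), `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- resolve_model(config)   # fail fast before any computation
  if (!is.null(config$cohort)) {
    subjects <- lapply(config$cohort, function(x) {
      if (is.null(x$series)) stopf("validation failure: cohort item without series")
      x
    })
  } else {
    subjects <- lapply(config$series_dirs, function(d)
      list(series = read_dixon_series(d)))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_bmf <- list(); all_truth_bmf <- list(); agreements <- list()
  stage <- function(what, sid, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed for subject %s: %s", what, sid,
            conditionMessage(e)))
  }
  for (sub in subjects) {
    series <- sub$series
    sid <- series$subject_id
    prob <- stage("segment", sid, predict(model, series, type = "prob"))
    mask <- stage("binarize", sid, binarize(prob, config$threshold))
    roiset <- stage("roi", sid, {
      rs <- extract_components(mask, config$min_area_px)
      rs <- suppressWarnings(assign_vertebra_labels(
        rs, match_radius_px = config$match_radius_px))
      filter_rois_by_area(rs)
    })
    report <- stage("quantify", sid, quantify_bmf(series, roiset))
    utils::write.csv(report$summary,
                     file.path(out_dir, sprintf("bmf_%s.csv", sid)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(roiset),
                     file.path(out_dir, sprintf("roi_%s.csv", sid)),
                     row.names = FALSE)
    all_bmf[[sid]] <- report$summary
    truth <- sub$truth
    if (!is.null(truth)) {
      agreements[[sid]] <- stage("evaluate", sid, {
        rep_t <- quantify_bmf(series, roiset_from_truth(truth))
        all_truth_bmf[[sid]] <- rep_t$summary
        agreement_report(mask, truth$mask, prob = prob,
                         scope = config$scope)
      })
    } else if (!is.null(sub$mask)) {
      agreements[[sid]] <- stage("evaluate", sid,
                                 agreement_report(mask, sub$mask,
                                                  prob = prob,
                                                  scope = config$scope))
    }
  }
  bmf <- do.call(rbind, c(all_bmf, list(make.row.names = FALSE)))
  utils::write.csv(bmf, file.path(out_dir, "bmf_all.csv"),
                   row.names = FALSE)
  evaluation <- NULL
  if (length(agreements) > 0) {
    num <- function(field) vapply(agreements, function(a)
      a[[field]] %||% NA_real_, numeric(1))
    evaluation <- list(
      per_subject = lapply(agreements, function(a)
        a[setdiff(names(a), "counts")]),
      mean_dsc = mean(num("dsc")), sd_dsc = sd(num("dsc")),
      mean_iou = mean(num("iou")), mean_kappa = mean(num("kappa")))
    if (length(all_truth_bmf) > 0) {
      tb <- do.call(rbind, c(all_truth_bmf, list(make.row.names = FALSE)))
      key <- paste(bmf$subject, bmf$level)
      tkey <- paste(tb$subject, tb$level)
      common <- intersect(key, tkey)
      manual <- tb$mean_bmf_pct[match(common, tkey)]
      auto <- bmf$mean_bmf_pct[match(common, key)]
      if (length(common) >= 3) {
        ba <- bland_altman(manual, auto)
        evaluation$bland_altman <- list(
          n = ba$n, bias = ba$bias, bias_ci = ba$bias_ci,
          loa_low = ba$loa_low, loa_high = ba$loa_high,
          pct_outside = ba$pct_outside)
        if (config$write_plots) {
          grDevices::png(file.path(out_dir, "bland_altman.png"),
                         width = 600, height = 480)
          plot(ba, main = "manual - automatic BMF agreement")
          grDevices::dev.off()
        }
      }
    }
    if (config$write_plots && !is.null(config$cohort)) {
      first_truth <- config$cohort[[1]]$truth
      if (!is.null(first_truth)) {
        s1 <- subjects[[1]]$series
        prob1 <- predict(model, s1, type = "prob")
        sc <- scoped_pixels(prob1, first_truth$mask, config$scope)
        lb <- scoped_pixels(first_truth$mask, first_truth$mask,
                            config$scope)
        if (length(unique(lb)) == 2)
          plot_roc_pr_png(sc, lb, file.path(out_dir, "roc_pr.png"))
      }
    }
    jsonlite::write_json(evaluation[setdiff(names(evaluation),
                                            "per_subject")],
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("spinefat")),
    seed = config$seed, threshold = config$threshold, scope = config$scope,
    min_area_px = config$min_area_px,
    match_radius_px = config$match_radius_px,
    n_subjects = length(subjects),
    subjects = vapply(subjects, function(s) s$series$subject_id,
                      character(1)),
    model_params = n_params(model),
    config_hash = config_hash(list(config$threshold, config$scope,
                                   config$min_area_px,
                                   config$match_radius_px, config$seed)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(bmf = bmf, evaluation = evaluation, manifest = manifest,
                 output_dir = out_dir))
}
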