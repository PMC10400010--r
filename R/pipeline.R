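#' Pipeline configuration
#'
#' Bundles every stage's parameters into one serializable object:
#' cohort generation (or an input directory of recordings), optics,
#' preprocessing band/trim/window, threshold range and density
#' convention, random-reference count, statistics level, and SVM
#' settings. Round-trips through YAML unchanged via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort a [cohort_spec()] (ignored when `input_dir` is given).
#' @param input_dir optional directory of recorded subjects to analyse
#'   instead of simulating.
#' @param band band-pass edges (Hz).
#' @param trim,window,window_strategy see [trim_and_window()].
#' @param car apply common average referencing.
#' @param threshold_range,threshold_step sparsity-threshold grid.
#' @param density_convention see [proportional_binarize()].
#' @param n_rand random reference networks per threshold.
#' @param path_policy disconnected-pair policy.
#' @param le_normalization local-efficiency prefactor.
#' @param alpha significance level.
#' @param fdr_family FDR family, see [threshold_wise_comparison()].
#' @param select_on AUC-feature selection rule.
#' @param svm_cost,svm_kernel,svm_grid classifier settings.
#' @param positive positive class label.
#' @param seed master seed (defaults to the cohort spec's).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_dir = NULL,
                            band = c(0.01, 0.1), trim = 3, window = 180,
                            window_strategy = "min_variance", car = TRUE,
                            threshold_range = c(0.30, 0.80),
                            threshold_step = 0.01,
                            density_convention = "one_minus_theta",
                            n_rand = 100L,
                            path_policy = "exclude",
                            le_normalization = "standard",
                            alpha = 0.05, fdr_family = "per_metric",
                            select_on = "raw",
                            svm_cost = 3, svm_kernel = "linear",
                            svm_grid = NULL, positive = "A",
                            seed = NULL) {
  structure(list(cohort = cohort, input_dir = input_dir, band = band,
                 trim = trim, window = window,
                 window_strategy = window_strategy, car = car,
                 threshold_range = threshold_range,
                 threshold_step = threshold_step,
                 density_convention = density_convention,
                 n_rand = as.integer(n_rand), path_policy = path_policy,
                 le_normalization = le_normalization, alpha = alpha,
                 fdr_family = fdr_family, select_on = select_on,
                 svm_cost = svm_cost, svm_kernel = svm_kernel,
                 svm_grid = svm_grid, positive = positive,
                 seed = as.integer(seed %||% cohort$seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass_deep(config)), f)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the reconstructed
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  cohort <- cohort_spec(
    n_group_a = co$n_group_a, n_group_b = co$n_group_b,
    n_channels = co$n_channels, fs = co$fs, duration = co$duration,
    seed = co$seed,
    topology_a = do.call(topology_params, co$topology_a),
    topology_b = do.call(topology_params, co$topology_b),
    coupling = co$coupling, base_correlation = co$base_correlation,
    signal_band = unlist(co$signal_band),
    nuisance = do.call(nuisance_config, co$nuisance[
      setdiff(names(co$nuisance), character())]),
    optics = optics_config(wavelengths = unlist(co$optics$wavelengths),
                           ext_hb = unlist(co$optics$ext_hb),
                           ext_hbo2 = unlist(co$optics$ext_hbo2),
                           dpf = unlist(co$optics$dpf),
                           distance = co$optics$distance))
  pipeline_config(cohort = cohort, input_dir = raw$input_dir,
                  band = unlist(raw$band), trim = raw$trim,
                  window = raw$window, window_strategy = raw$window_strategy,
                  car = raw$car, threshold_range = unlist(raw$threshold_range),
                  threshold_step = raw$threshold_step,
                  density_convention = raw$density_convention,
                  n_rand = raw$n_rand, path_policy = raw$path_policy,
                  le_normalization = raw$le_normalization, alpha = raw$alpha,
                  fdr_family = raw$fdr_family, select_on = raw$select_on,
                  svm_cost = raw$svm_cost, svm_kernel = raw$svm_kernel,
                  svm_grid = raw$svm_grid, positive = raw$positive,
                  seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> connectivity ->
#' graph metrics -> group statistics -> classification, returning a
#' consolidated report. When `out_dir` is given, stage outputs (cohort
#' files, metric curves, AUC features, report JSON) are written there
#' together with the configuration hash; a re-run with the same
#' configuration reuses the stored metric curves (the expensive stage)
#' instead of recomputing them, and a changed configuration invalidates
#' them.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage artifacts and
#'   resuming.
#' @param verbose print stage progress.
#' @return Object of class `neglect_report`: per-subject mean FC and the
#'   group comparison, group-stats tables with significant-threshold
#'   ranges, AUC feature table and selection, classifier report, run
#'   manifest (subject ids, labels, config hash) and the config.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)

  say("stage 1/6: cohort")
  subjects <- if (!is.null(config$input_dir)) {
    load_subjects(config$input_dir)
  } else {
    generate_cohort(config$cohort)$subjects
  }
  ids <- vapply(subjects, `[[`, "", "subject_id")
  labels <- vapply(subjects, `[[`, "", "group_label")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(config$input_dir))
      write_cohort(structure(list(subjects = subjects, spec = config$cohort),
                             class = "neglect_cohort"),
                   file.path(out_dir, "cohort"))
  }

  say("stage 2/6: preprocessing")
  hemo <- lapply(subjects, function(s)
    preprocess_subject(s$optical, config$cohort$optics, band = config$band,
                       trim = config$trim, window = config$window,
                       strategy = config$window_strategy, car = config$car))

  say("stage 3/6: connectivity")
  conns <- lapply(hemo, correlation_matrix)
  fc <- vapply(conns, mean_fc, numeric(1))
  stacks <- lapply(conns, build_threshold_stack,
                   lo = config$threshold_range[1L],
                   hi = config$threshold_range[2L],
                   step = config$threshold_step,
                   convention = config$density_convention)

  say("stage 4/6: graph metrics (n_rand = %d)", config$n_rand)
  curves_file <- if (!is.null(out_dir)) file.path(out_dir, "metric_curves.csv")
  hash_file <- if (!is.null(out_dir)) file.path(out_dir, "config_hash")
  curves <- NULL
  if (!is.null(out_dir) && file.exists(curves_file) && file.exists(hash_file) &&
      identical(readLines(hash_file, warn = FALSE)[1L], hash)) {
    say("  reusing stored metric curves (config hash matches)")
    long <- utils::read.csv(curves_file, stringsAsFactors = FALSE)
    curves <- split(long[setdiff(names(long), "subject_id")], long$subject_id)
    curves <- curves[ids]
  }
  if (is.null(curves)) {
    curves <- lapply(seq_along(subjects), function(i)
      metric_curves(stacks[[i]], n_rand = config$n_rand,
                    seed = config$seed + 1000L * i,
                    policy = config$path_policy,
                    le_normalization = config$le_normalization))
    names(curves) <- ids
  }
  auc <- t(vapply(curves, auc_over_thresholds, numeric(5)))
  rownames(auc) <- ids
  if (!is.null(out_dir)) {
    write_metric_outputs(curves, auc, labels, out_dir)
    writeLines(hash, hash_file)
  }

  say("stage 5/6: group statistics")
  fc_cmp <- compare_mean_fc(fc, labels)
  stats_res <- threshold_wise_comparison(curves, labels, alpha = config$alpha,
                                         fdr_family = config$fdr_family)
  selection <- select_auc_features(auc, labels, alpha = config$alpha,
                                   select_on = config$select_on)
  feats <- selection$selected
  note <- NULL
  if (!length(feats)) {
    feats <- colnames(auc)
    note <- "no AUC feature significant; classifier fell back to all five"
  }

  say("stage 6/6: classification (features: %s)", paste(feats, collapse = ", "))
  classifier <- loocv_svm(auc[, feats, drop = FALSE], labels,
                          positive = config$positive, cost = config$svm_cost,
                          kernel = config$svm_kernel, grid = config$svm_grid)

  report <- structure(
    list(mean_fc = list(per_subject = stats::setNames(fc, ids),
                        comparison = fc_cmp),
         stats = stats_res,
         auc = data.frame(subject_id = ids, auc, group_label = labels,
                          row.names = NULL),
         selection = selection, selection_note = note,
         classifier = classifier,
         manifest = data.frame(subject_id = ids, group_label = labels,
                               config_hash = hash, row.names = NULL),
         config = config),
    class = "neglect_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(mean_fc = fc_cmp, selection = selection$table,
           counts = as.list(classifier$counts),
           metrics = as.list(classifier$metrics),
           roc_auc = classifier$roc_auc, config_hash = hash),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.neglect_report <- function(x, ...) {
  cmp <- x$mean_fc$comparison
  cat("<neglect_report>\n")
  cat(sprintf("  mean FC: %s %.3f +/- %.3f vs %s %.3f +/- %.3f (t = %.3f, p = %.3g)\n",
              cmp$summary$group[1L], cmp$summary$mean[1L], cmp$summary$sd[1L],
              cmp$summary$group[2L], cmp$summary$mean[2L], cmp$summary$sd[2L],
              cmp$t, cmp$p))
  sel <- x$selection$table
  cat("  AUC features:\n")
  for (k in seq_len(nrow(sel)))
    cat(sprintf("    %-7s t = %6.3f  p = %.3f%s\n", sel$feature[k], sel$t[k],
                sel$p[k], if (sel$selected[k]) "  [selected]" else ""))
  if (!is.null(x$selection_note)) cat("  note:", x$selection_note, "\n")
  print(x$classifier)
  invisible(x)
}
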