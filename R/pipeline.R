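#' Pipeline configuration
#'
#' Reads/writes the YAML configuration driving [run_pipeline()]. Every
#' stochastic stage has an explicit seed; the effective configuration is
#' echoed into the output directory of each run.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_malformed(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  utils::modifyList(defaults, cfg)
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  list(
    contours = "contours.csv",
    clinical = "clinical.csv",
    expected_points = 49L,
    expected_frames = 25L,
    heart_rate_bpm = 68,
    n_segments = 5L,
    cluster = list(k_max = 8L, seed = 7L, outlier_size = 1L),
    predict_length = list(alpha = "cv", folds = 10L, seed = 7L),
    predict_ec = list(axis = "x", train_frac = 0.7, seed = 7L, lambda = 0.1)
  )
}

#' Run the full CTI kinetics pipeline
#'
#' Executes the analysis stages in dependency order on a contour table
#' and a clinical table: geometry metrics, segmental kinetics, cohort
#' assembly, association statistics, EC distribution comparison, NE
#' clustering, and the two prediction models. All outputs (CSV tables,
#' JSON fit reports, the effective config and a run log) are written to
#' `out_dir`. A failing stage aborts with an error naming the stage.
#'
#' @param config Named list (see [default_pipeline_config()]) or a path
#'   to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The cohort tibble, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "ctikin_stage_error", parent = e)
    })
    log_line("stage %-12s ok (%.2f s)", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  cat(sprintf("ctikin pipeline run %s\n", format(Sys.time())), file = log_path)

  dt <- (60 / config$heart_rate_bpm) / config$expected_frames
  cines <- stage("read", {
    if (!file.exists(config$contours)) {
      abort_malformed(sprintf("missing input: %s", config$contours))
    }
    read_contour_table(config$contours,
                       expected_points = config$expected_points,
                       expected_frames = config$expected_frames,
                       frame_interval = dt)
  })
  clinical <- stage("clinical", {
    if (!file.exists(config$clinical)) {
      abort_malformed(sprintf("missing input: %s", config$clinical))
    }
    read_clinical_table(config$clinical)
  })
  geometry <- stage("geometry", compute_geometry_table(cines))
  kin <- stage("kinetics", segment_kinetics_table(cines, dt = dt,
                                                  n_segments = config$n_segments))
  cohort <- stage("cohort", build_cohort_table(geometry, kin$segments, clinical))
  stats_tab <- stage("stats", dplyr::bind_rows(
    cohort_association_screen(cohort),
    compare_ec_distributions(kin$per_point, clinical)))
  clusters <- stage("cluster", cluster_ne(cohort,
                                          k_max = config$cluster$k_max,
                                          seed = config$cluster$seed,
                                          outlier_size = config$cluster$outlier_size))
  fits <- stage("predict", {
    pl <- config$predict_length
    pe <- config$predict_ec
    design <- build_ec_design(kin$per_point, clinical, axis = pe$axis)
    list(
      length_systolic = fit_lasso_length(cohort, "systolic", alpha = pl$alpha,
                                         folds = pl$folds, seed = pl$seed),
      length_diastolic = fit_lasso_length(cohort, "diastolic", alpha = pl$alpha,
                                          folds = pl$folds, seed = pl$seed),
      ec = fit_ec_classifier(design$features, design$labels,
                             groups = design$obs$patient_id,
                             train_frac = pe$train_frac, seed = pe$seed,
                             lambda = pe$lambda)
    )
  })

  stage("write", {
    readr::write_csv(geometry, file.path(out_dir, "geometry.csv"))
    readr::write_csv(kin$segments, file.path(out_dir, "kinetics.csv"))
    readr::write_csv(stats_tab, file.path(out_dir, "stats.csv"))
    readr::write_csv(clusters$assignments, file.path(out_dir, "clusters.csv"))
    fit_report <- list(
      length_systolic = unclass_fit(fits$length_systolic),
      length_diastolic = unclass_fit(fits$length_diastolic),
      ec_classifier = list(accuracy = unname(fits$ec$accuracy),
                           confusion = as.list(fits$ec$confusion),
                           n_train = fits$ec$n_train, n_test = fits$ec$n_test)
    )
    writeLines(yaml::as.yaml(fit_report), file.path(out_dir, "fits.yaml"))
    writeLines(yaml::as.yaml(config), file.path(out_dir, "config.yaml"))
  })
  log_line("pipeline complete: %d patients", nrow(cohort))
  invisible(cohort)
}

unclass_fit <- function(f) {
  list(target = f$target, alpha = f$alpha,
       coefficients = as.list(f$coefficients),
       intercept = f$intercept, mae_mm = f$mae_mm, r2 = f$r2, n = f$n)
}
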