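#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].  Every
#' key has a default except `out_dir`; unknown keys and wrong types are
#' rejected with the offending key named.
#'
#' @param out_dir output directory (required).
#' @param seed master integer seed; every stage derives its RNG state from
#'   it deterministically.
#' @param n_subjects,n_modules,within_module_corr,between_module_corr
#'   cohort generator settings, see [cohort_config()].
#' @param workflow_noise_sd,repeat_sd cohort generator settings, see
#'   [cohort_config()].
#' @param n_repeats repeated measurements for the repeatability stage.
#' @param sparsity_min,sparsity_max,sparsity_step sparsity grid.
#' @param shrinkage,edge_rule network construction settings.
#' @param n_null,rewires_per_edge,lambda_tol small-world assessment
#'   settings.
#' @param alpha,adjustment per-region ANOVA settings.
#' @param n_perm permutations for the network-metric comparison.
#' @param compare_metrics metrics compared between workflows.
#' @param fixture_voxels_per_region approximate label-map voxels per 50 mm^3
#'   of mean region volume for the demonstration registration fixture.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, n_subjects = 22L,
                            n_modules = 4L, within_module_corr = 0.6,
                            between_module_corr = 0.1,
                            workflow_noise_sd = list(BET = 0.05,
                                                     iBEAT = 0.03,
                                                     iBEAT_corrected = 0),
                            repeat_sd = 50, n_repeats = 2L,
                            sparsity_min = 0.10, sparsity_max = 0.46,
                            sparsity_step = 0.02, shrinkage = "auto",
                            edge_rule = "positive", n_null = 100L,
                            rewires_per_edge = 10L, lambda_tol = 1.5,
                            alpha = 0.05, adjustment = "none",
                            n_perm = 199L,
                            compare_metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                            fixture_voxels_per_region = 1) {
  config <- list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
                 n_modules = n_modules,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 workflow_noise_sd = workflow_noise_sd,
                 repeat_sd = repeat_sd, n_repeats = n_repeats,
                 sparsity_min = sparsity_min, sparsity_max = sparsity_max,
                 sparsity_step = sparsity_step, shrinkage = shrinkage,
                 edge_rule = edge_rule, n_null = n_null,
                 rewires_per_edge = rewires_per_edge,
                 lambda_tol = lambda_tol, alpha = alpha,
                 adjustment = adjustment, n_perm = n_perm,
                 compare_metrics = compare_metrics,
                 fixture_voxels_per_region = fixture_voxels_per_region)
  validate_pipeline_config(config)
}

.config_types <- list(
  out_dir = list(check = function(x) is.character(x) && length(x) == 1L,
                 type = "character path"),
  seed = list(check = function(x) is.numeric(x) && length(x) == 1L,
              type = "integer"),
  n_subjects = list(check = function(x) is.numeric(x) && x >= 5,
                    type = "integer >= 5"),
  n_modules = list(check = function(x) is.numeric(x) && x >= 1,
                   type = "integer >= 1"),
  within_module_corr = list(check = function(x) is.numeric(x) && x > 0 &&
                              x < 1, type = "real in (0, 1)"),
  between_module_corr = list(check = function(x) is.numeric(x) && x >= 0 &&
                               x < 1, type = "real in [0, 1)"),
  workflow_noise_sd = list(check = function(x) is.list(x) &&
                             all(unlist(x) >= 0),
                           type = "named list of non-negative reals"),
  repeat_sd = list(check = function(x) is.numeric(x) && x >= 0,
                   type = "non-negative real"),
  n_repeats = list(check = function(x) is.numeric(x) && x >= 2,
                   type = "integer >= 2"),
  sparsity_min = list(check = function(x) is.numeric(x) && x > 0 && x <= 1,
                      type = "real in (0, 1]"),
  sparsity_max = list(check = function(x) is.numeric(x) && x > 0 && x <= 1,
                      type = "real in (0, 1]"),
  sparsity_step = list(check = function(x) is.numeric(x) && x > 0,
                       type = "positive real"),
  shrinkage = list(check = function(x) identical(x, "auto") ||
                     identical(x, "none") || (is.numeric(x) && x >= 0 &&
                                                x <= 1),
                   type = "\"auto\", \"none\" or real in [0, 1]"),
  edge_rule = list(check = function(x) x %in% c("positive", "abs"),
                   type = "\"positive\" or \"abs\""),
  n_null = list(check = function(x) is.numeric(x) && x >= 1,
                type = "integer >= 1"),
  rewires_per_edge = list(check = function(x) is.numeric(x) && x >= 1,
                          type = "integer >= 1"),
  lambda_tol = list(check = function(x) is.numeric(x) && x > 0,
                    type = "positive real"),
  alpha = list(check = function(x) is.numeric(x) && x > 0 && x < 1,
               type = "real in (0, 1)"),
  adjustment = list(check = function(x) x %in% c("none", "BH"),
                    type = "\"none\" or \"BH\""),
  n_perm = list(check = function(x) is.numeric(x) && x >= 100,
                type = "integer >= 100"),
  compare_metrics = list(check = function(x) all(x %in% c("Cp", "Lp",
                                                          "Eglob", "Eloc")),
                         type = "subset of Cp, Lp, Eglob, Eloc"),
  fixture_voxels_per_region = list(check = function(x) is.numeric(x) &&
                                     x > 0, type = "positive real")
)

#' @rdname pipeline_config
#' @param config a configuration list (e.g. parsed from YAML/JSON).
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), names(.config_types))
  if (length(unknown) > 0L) {
    stop("unknown configuration key '", unknown[1L], "'", call. = FALSE)
  }
  for (key in names(.config_types)) {
    spec <- .config_types[[key]]
    if (!key %in% names(config) || is.null(config[[key]])) {
      stop("missing configuration key '", key, "' (expected ", spec$type,
           ")", call. = FALSE)
    }
    if (!isTRUE(spec$check(config[[key]]))) {
      stop("configuration key '", key, "' must be ", spec$type,
           call. = FALSE)
    }
  }
  if (config$sparsity_min > config$sparsity_max) {
    stop("configuration key 'sparsity_min' must not exceed 'sparsity_max'",
         call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param out_dir optional override for the file's `out_dir` key.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(user)) stop("'", path, "' is not a key-value mapping",
                           call. = FALSE)
  unknown <- setdiff(names(user), names(.config_types))
  if (length(unknown) > 0L) {
    stop("unknown configuration key '", unknown[1L], "' in '", path, "'",
         call. = FALSE)
  }
  if (!is.null(out_dir)) user$out_dir <- out_dir
  do.call(pipeline_config, user)
}

#' Run the full synthetic analysis pipeline
#'
#' One-command end-to-end run on synthetic data: cohort simulation, a
#' demonstration of atlas-based volume estimation on a generated
#' registration fixture, network construction, graph metrics with
#' small-world assessment, and the repeatability and workflow-comparison
#' statistics.  All randomness flows from the single master seed; running
#' the same configuration twice produces identical numeric outputs.  Each
#' stage reads only on-disk outputs of earlier stages (plus the config), so
#' any stage can be reproduced from the retained intermediates.
#'
#' @param config a `pipeline_config`, a plain configuration list, or a path
#'   to a YAML/JSON configuration file.
#' @param out_dir overrides `config$out_dir` when given.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config, out_dir = out_dir)
  } else {
    if (!is.null(out_dir)) config$out_dir <- out_dir
    config <- validate_pipeline_config(unclass(config))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cat(NULL, file = log_path)
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    result <- tryCatch(fn(), error = function(e) {
      log_line("stage=", name, " status=failed error=", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("stage=", name, " status=ok elapsed=",
             sprintf("%.2fs", proc.time()[["elapsed"]] - t0))
    result
  }
  sparsity <- seq(config$sparsity_min, config$sparsity_max,
                  by = config$sparsity_step)
  atlas <- load_region_atlas()

  ## stage 1: simulate -------------------------------------------------
  run_stage("simulate", function() {
    cc <- cohort_config(n_subjects = config$n_subjects,
                        seed = config$seed,
                        n_modules = config$n_modules,
                        within_module_corr = config$within_module_corr,
                        between_module_corr = config$between_module_corr,
                        workflow_noise_sd = unlist(config$workflow_noise_sd),
                        repeat_sd = config$repeat_sd, atlas = atlas)
    cohort <- generate_cohort(cc)
    dir.create(file.path(out, "volumes"), showWarnings = FALSE)
    for (w in names(cohort)) {
      write_volume_table(cohort[[w]],
                         file.path(out, "volumes", paste0(w, ".csv")))
    }
    repeats <- generate_repeats(cc, config$n_repeats)
    dir.create(file.path(out, "repeats"), showWarnings = FALSE)
    for (r in seq_along(repeats)) {
      write_volume_table(repeats[[r]],
                         file.path(out, "repeats",
                                   sprintf("measurement_%d.csv", r)))
    }
    NULL
  })

  ## stage 2: volumes (atlas-based estimation demo on a fixture) -------
  run_stage("volumes", function() {
    counts <- pmax(1L, round(default_region_means(atlas) / 50 *
                               config$fixture_voxels_per_region))
    names(counts) <- atlas$label_code
    fixture <- generate_registration_fixture(
      seed = config$seed + 3000L, region_voxel_counts = counts,
      jacobian = "smooth", atlas = atlas)
    write_registration_fixture(fixture, file.path(out, "fixture"))
    fx <- read_registration_fixture(file.path(out, "fixture"), atlas)
    rows <- all_region_volumes(fx, atlas, subject_id = "template_subject")
    utils::write.csv(rows, file.path(out, "fixture", "fixture_volumes.csv"),
                     row.names = FALSE)
    NULL
  })

  ## stage 3: networks -------------------------------------------------
  workflows <- run_stage("network", function() {
    files <- list.files(file.path(out, "volumes"), pattern = "\\.csv$")
    wfs <- sub("\\.csv$", "", files)
    for (w in wfs) {
      tab <- read_volume_table(file.path(out, "volumes",
                                         paste0(w, ".csv")),
                               atlas = atlas, workflow = w)
      net <- build_network(tab, sparsity_range = sparsity,
                           shrinkage = config$shrinkage,
                           edge_rule = config$edge_rule)
      write_network(net, file.path(out, "networks", w))
    }
    wfs
  })

  ## stage 4: metrics --------------------------------------------------
  run_stage("metrics", function() {
    dir.create(file.path(out, "metrics"), showWarnings = FALSE)
    for (w in workflows) {
      net <- read_network(file.path(out, "networks", w), atlas = atlas)
      nmc <- null_model_config(config$n_null, config$rewires_per_edge,
                               config$seed + 1000L)
      report <- metrics_over_range(net, nmc, lambda_tol = config$lambda_tol)
      write_metrics(report, file.path(out, "metrics", paste0(w, ".json")))
      utils::write.csv(report$per_sparsity,
                       file.path(out, "metrics", paste0(w, ".csv")),
                       row.names = FALSE)
    }
    NULL
  })

  ## stage 5: statistics -----------------------------------------------
  run_stage("statistics", function() {
    dir.create(file.path(out, "stats"), showWarnings = FALSE)
    repeats <- lapply(seq_len(config$n_repeats), function(r) {
      read_volume_table(file.path(out, "repeats",
                                  sprintf("measurement_%d.csv", r)),
                        atlas = atlas, workflow = "iBEAT_corrected",
                        measurement_id = r)
    })
    icc_res <- icc(repeats)
    jsonlite::write_json(
      list(per_region = as.list(icc_res$per_region),
           average = icc_res$average, model = icc_res$model),
      file.path(out, "stats", "icc.json"), auto_unbox = TRUE, digits = NA)
    # whole-brain volume = sum of the 64 regional volumes
    wb1 <- rowSums(repeats[[1L]]$values)
    wb2 <- rowSums(repeats[[2L]]$values)
    ba <- bland_altman(wb1, wb2)
    jsonlite::write_json(
      ba[c("mean_diff", "sd_diff", "loa_low", "loa_high", "pct_within",
           "n")],
      file.path(out, "stats", "bland_altman.json"), auto_unbox = TRUE,
      digits = NA)
    tabs <- lapply(workflows, function(w) {
      read_volume_table(file.path(out, "volumes", paste0(w, ".csv")),
                        atlas = atlas, workflow = w)
    })
    names(tabs) <- workflows
    av <- anova_per_region(tabs, alpha = config$alpha,
                           adjustment = config$adjustment)
    utils::write.csv(av$per_region, file.path(out, "stats", "anova.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_significant = av$n_significant, alpha = av$alpha,
           adjustment = av$adjustment),
      file.path(out, "stats", "anova.json"), auto_unbox = TRUE, digits = NA)
    cmp <- compare_network_metrics(
      tabs, sparsity_range = sparsity, shrinkage = config$shrinkage,
      edge_rule = config$edge_rule, metrics = config$compare_metrics,
      n_perm = config$n_perm, seed = config$seed + 2000L)
    utils::write.csv(cmp$comparisons,
                     file.path(out, "stats", "network_comparison.csv"),
                     row.names = FALSE)
    NULL
  })

  ## manifest -----------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, c("log.txt", "manifest.json")))
  checksums <- tools::md5sum(files)
  names(checksums) <- substring(names(checksums), nchar(out) + 2L)
  manifest <- list(
    package_version = as.character(utils::packageVersion("volnet")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("stage=manifest status=ok files=", length(checksums))
  invisible(out)
}
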