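#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]: arena and
#' cohort settings, model settings (`aic_threshold`, `alpha`,
#' `predictor_transform`), the thermal-survey settings, the output
#' directory and the global seed. Any element can be overridden via `...`
#' (flat keys, e.g. `seed = 7`, or whole sub-lists, e.g.
#' `cohort = list(bees_per_group = 6)` which is merged over the defaults).
#'
#' @param ... Overrides merged over the defaults.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 7, cohort = list(bees_per_group = 6))
#' cfg$cohort$bees_per_group
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    input_visits = NULL,   # path to a visits CSV; when set, simulation is skipped
    arena = list(flower_size = "small"),
    cohort = list(groups = c("control", "circle_rewarded", "bar_rewarded"),
                  bees_per_group = 12L),
    model = list(aic_threshold = 2, alpha = 0.05, predictor_transform = "ln",
                 window = 10L),
    thermal = list(enabled = TRUE, n_species = 118L, threshold = 2,
                   flower_pairs = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()]; missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

## Polynomial rolling hash of the canonicalised configuration, for output
## provenance headers. Not cryptographic; collisions only matter for
## telling two configs apart in a log.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # where results land does not change what they are
  txt <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Group-level learning-curve summary
#'
#' Per group and 10-visit block: the mean raw success over bees, its
#' standard error (SD over bees divided by the square root of the number of
#' bees -- the bee is the unit of replication), and the number of bees.
#'
#' @param series A success series from [windowed_success()].
#' @return A data frame with columns `group`, `x`, `mean_success`, `sem`,
#'   `n`. For a group with a single bee the SEM is `NA` and a warning is
#'   issued.
#' @examples
#' s <- data.frame(bee_id = rep(1:3, each = 1), group = "g", x = 10,
#'                 success = c(0.4, 0.5, 0.6),
#'                 theta = arcsine_transform(c(0.4, 0.5, 0.6)))
#' learning_curve_summary(s)  # mean 0.5, sem 0.1/sqrt(3)
#' @export
learning_curve_summary <- function(series) {
  stopifnot(nrow(series) > 0,
            all(c("group", "x", "success", "bee_id") %in% names(series)))
  pieces <- lapply(split(series, list(series$group, series$x), drop = TRUE),
                   function(r) {
    data.frame(group = r$group[1], x = r$x[1],
               mean_success = mean(r$success),
               sem = if (nrow(r) > 1) stats::sd(r$success) / sqrt(nrow(r))
                     else NA_real_,
               n = nrow(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (any(out$n == 1L)) {
    warning("group(s) with a single bee: SEM reported as missing")
  }
  out <- out[order(out$group, out$x), ]
  rownames(out) <- NULL
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or loads) a conditioning dataset, scores it, fits the
#' learning-curve model ladder, runs the per-group learning tests and the
#' test-phase ANOVA with Tukey letters, optionally generates the thermal
#' survey and matched artificial-flower thermographs, and writes every
#' stage's CSV report plus a plain-text run log. All outputs carry the seed
#' and a configuration hash in a leading comment line; rerunning with the
#' same configuration and seed reproduces the files byte for byte.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]). `config$outdir` must be set.
#' @return Invisibly, a list with the in-memory results: `visits`,
#'   `series`, `ladder`, `testphase` (summary table), `anova`,
#'   `curve_summary`, `survey` (or `NULL`), and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$outdir)) stop("config$outdir must be set")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("seed=%d config=%s floraltherm=%s", config$seed,
                 config_hash(config),
                 as.character(utils::packageVersion("floraltherm")))
  log_lines <- c(sprintf("floraltherm run log"),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("floraltherm"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("config hash: %s", config_hash(config)))
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  files <- character(0)
  out_path <- function(name) file.path(config$outdir, name)

  arena <- do.call(arena_config, config$arena)

  ## -- simulate or load ------------------------------------------------
  if (is.null(config$input_visits)) {
    cohort <- do.call(cohort_config,
                      c(config$cohort, list(seed = config$seed)))
    visits <- tryCatch(simulate_cohort(cohort, arena),
                       error = function(e) fail("simulate", e))
    log_lines <- c(log_lines, sprintf(
      "simulated cohort: %d bees x {%s}", cohort$bees_per_group,
      paste(cohort$groups, collapse = ", ")))
  } else {
    visits <- tryCatch(read_visits(config$input_visits),
                       error = function(e) fail("load", e))
    log_lines <- c(log_lines, sprintf("loaded visits: %s", config$input_visits))
  }
  write_visits(visits, out_path("visits.csv"), hdr)
  files <- c(files, out_path("visits.csv"))

  ## -- score -----------------------------------------------------------
  scored <- tryCatch(score_landings(visits[visits$counted, , drop = FALSE]),
                     error = function(e) fail("score", e))
  series <- tryCatch(windowed_success(scored, window = config$model$window),
                     error = function(e) fail("score", e))
  write_series(series, out_path("series.csv"), hdr)
  files <- c(files, out_path("series.csv"))

  ## -- model ladder + per-group tests ----------------------------------
  ladder <- tryCatch(
    run_ladder(series, aic_threshold = config$model$aic_threshold,
               predictor_transform = config$model$predictor_transform),
    error = function(e) fail("ladder", e))
  write_ladder_csv(ladder, out_path("ladder.csv"), hdr)
  files <- c(files, out_path("ladder.csv"))
  cmp_lines <- utils::capture.output(print(ladder$comparisons, digits = 6))
  log_lines <- c(log_lines, "model simplification ladder:", cmp_lines)
  if (!is.null(ladder$per_group)) {
    log_lines <- c(log_lines, "per-group learning tests:",
                   utils::capture.output(print(ladder$per_group, digits = 6)))
  }

  ## -- test phase ------------------------------------------------------
  tp <- anova_res <- tp_summary <- NULL
  if (any(scored$phase == "test")) {
    tp <- tryCatch(testphase_table(scored),
                   error = function(e) fail("testphase", e))
    anova_res <- testphase_anova(tp)
    tp_summary <- tukey_groups(tp, alpha = config$model$alpha)
    write_testphase_csv(tp, out_path("testphase.csv"),
                        alpha = config$model$alpha, header_comment = hdr)
    files <- c(files, out_path("testphase.csv"))
    log_lines <- c(log_lines, sprintf(
      "test-phase ANOVA: F(%d,%d) = %.4f, p = %.4g",
      anova_res$df_between, anova_res$df_within, anova_res$F, anova_res$p))
  }

  ## -- figure-data summary ---------------------------------------------
  curve <- learning_curve_summary(series)
  con <- file(out_path("curve_summary.csv"), "w")
  writeLines(paste("#", hdr), con)
  utils::write.csv(curve, con, row.names = FALSE, quote = FALSE)
  close(con)
  files <- c(files, out_path("curve_summary.csv"))

  ## -- thermal survey --------------------------------------------------
  survey <- NULL
  if (isTRUE(config$thermal$enabled)) {
    survey <- tryCatch(
      simulate_survey(n_species = config$thermal$n_species,
                      seed = config$seed),
      error = function(e) fail("thermal", e))
    summ <- survey_summary(survey$range, threshold = config$thermal$threshold)
    con <- file(out_path("survey.csv"), "w")
    writeLines(paste("#", hdr), con)
    utils::write.csv(survey, con, row.names = FALSE, quote = FALSE)
    close(con)
    files <- c(files, out_path("survey.csv"))
    log_lines <- c(log_lines, utils::capture.output(print(summ)))
  }

  log_lines <- c(log_lines, "files:", paste(" ", basename(files)))
  writeLines(log_lines, out_path("run_log.txt"))
  files <- c(files, out_path("run_log.txt"))

  invisible(list(visits = visits, series = series, ladder = ladder,
                 testphase = tp_summary, anova = anova_res,
                 curve_summary = curve, survey = survey, files = files))
}
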