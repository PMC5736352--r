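## Is `reduced` nested in `full`? Every active term of the reduced spec must
## be active in the full spec, under the same predictor transform.
spec_nested <- function(full, reduced) {
  flags <- c("learning", "group_intercepts", "group_slopes",
             "bee_intercepts", "bee_slopes")
  identical(full$predictor_transform, reduced$predictor_transform) &&
    all(vapply(flags, function(f) !reduced[[f]] || full[[f]], logical(1)))
}

#' Assemble a model-comparison record
#'
#' Low-level constructor for the comparison between a fuller and a reduced
#' nested model: the AIC difference, the deviance change, its chi-square
#' upper-tail p-value at `df` (the number of parameters removed), and the
#' AIC-based decision. The simpler model is kept unless its AIC exceeds the
#' fuller model's by more than `aic_threshold`.
#'
#' @param name Step label.
#' @param AIC_full,AIC_reduced AIC of the fuller and the reduced model.
#' @param deviance_change Deviance of the reduced model minus deviance of
#'   the fuller model.
#' @param df Number of parameters removed (`>= 1`).
#' @param aic_threshold AIC-increase tolerance for accepting the simpler
#'   model (default 2; 6 is the stricter published alternative).
#' @return A one-row data frame of class `model_comparison` with columns
#'   `name`, `AIC_full`, `AIC_reduced`, `delta_AIC`, `deviance_change`,
#'   `df`, `p`, `decision`.
#' @examples
#' model_comparison("interactions", AIC_full = -226.3, AIC_reduced = -216.9,
#'                  deviance_change = 13.4, df = 2)
#' @export
model_comparison <- function(name, AIC_full, AIC_reduced, deviance_change,
                             df, aic_threshold = 2) {
  stopifnot(df >= 1)
  delta_AIC <- AIC_reduced - AIC_full
  p <- stats::pchisq(max(deviance_change, 0), df, lower.tail = FALSE)
  out <- data.frame(name = name, AIC_full = AIC_full,
                    AIC_reduced = AIC_reduced, delta_AIC = delta_AIC,
                    deviance_change = deviance_change, df = as.integer(df),
                    p = p,
                    decision = if (delta_AIC <= aic_threshold) "keep_reduced"
                               else "keep_full",
                    stringsAsFactors = FALSE)
  class(out) <- c("model_comparison", class(out))
  out
}

#' Compare two nested learning-curve fits
#'
#' Computes the AIC difference and the deviance (likelihood-ratio) change
#' between a fuller model and a nested reduction fitted to the same data,
#' with the chi-square p-value at `df = ` the number of parameters removed.
#' The decision follows AIC: the reduced model is kept unless its AIC
#' exceeds the fuller model's by more than `aic_threshold`.
#'
#' @param fit_full,fit_reduced `lcm_fit` objects for the fuller and the
#'   nested reduced model, fitted to the same observations.
#' @param aic_threshold See [model_comparison()].
#' @param name Step label stored in the result.
#' @return A `model_comparison` row.
#' @export
compare_models <- function(fit_full, fit_reduced, aic_threshold = 2,
                           name = "comparison") {
  stopifnot(inherits(fit_full, "lcm_fit"), inherits(fit_reduced, "lcm_fit"))
  if (!spec_nested(fit_full$spec, fit_reduced$spec)) {
    stop("the reduced model is not nested in the full model")
  }
  if (fit_full$n != fit_reduced$n) {
    stop("fits use different numbers of observations")
  }
  df <- fit_full$k - fit_reduced$k
  if (df < 1) stop("the models do not differ in parameter count")
  model_comparison(name,
                   AIC_full = fit_full$AIC, AIC_reduced = fit_reduced$AIC,
                   deviance_change = fit_reduced$deviance - fit_full$deviance,
                   df = df, aic_threshold = aic_threshold)
}

## One rung: fit the reduced spec, compare against the standing best fit.
ladder_rung <- function(name, best_fit, reduced_spec, series, aic_threshold) {
  red_fit <- tryCatch(fit_ml(series, reduced_spec),
                      error = function(e) stop("ladder rung '", name,
                                               "' failed: ", conditionMessage(e)))
  cmp <- compare_models(best_fit, red_fit, aic_threshold, name = name)
  list(cmp = cmp, fit = red_fit)
}

#' Stepwise AIC/deviance model-simplification ladder
#'
#' Runs the fixed simplification order on a success series, starting from
#' the full hierarchical model: (1) drop the per-bee random slopes `r_n`;
#' (2) drop the group-by-experience interactions `c_t`, `c_c`; (3) only if
#' step 2 accepted the no-interaction model, drop the group terms `s_t`,
#' `s_c`; (4) drop the learning slope `l`. Each rung compares the standing
#' best model with its reduction; the reduced model becomes the standing
#' best when its AIC is within `aic_threshold` of the fuller one. When step
#' 2 retains the interactions, steps 3-4 are skipped and (optionally)
#' per-group learning tests are run instead.
#'
#' @param series A success series from [windowed_success()].
#' @param aic_threshold See [model_comparison()].
#' @param predictor_transform Passed to [model_spec()].
#' @param per_group When interactions are retained, also run
#'   [per_group_learning_test()] for every group (default `TRUE`).
#' @return A list of class `lcm_ladder`: `comparisons` (one data-frame row
#'   per rung, in execution order), `final_spec`, `final_fit`, `fits` (all
#'   fitted models, named), and `per_group` (comparison rows or `NULL`).
#' @examples
#' v <- simulate_cohort(cohort_config(bees_per_group = 4, seed = 1),
#'                      arena_config("small"))
#' lad <- run_ladder(windowed_success(score_landings(v[v$counted, ])))
#' lad$comparisons
#' @export
run_ladder <- function(series, aic_threshold = 2,
                       predictor_transform = "ln", per_group = TRUE) {
  if (length(unique(series$group)) < 2L) {
    stop("the simplification ladder needs at least two test groups")
  }
  sp <- function(...) model_spec(..., predictor_transform = predictor_transform)
  full <- sp()
  fits <- list(full = fit_ml(series, full))
  best_spec <- full
  comparisons <- list()

  ## 1: random slopes
  r1 <- ladder_rung("random_slopes", fits$full, sp(bee_slopes = FALSE),
                    series, aic_threshold)
  fits$no_random_slopes <- r1$fit
  comparisons$random_slopes <- r1$cmp
  if (r1$cmp$decision == "keep_reduced") best_spec <- r1$fit$spec
  best_fit <- if (r1$cmp$decision == "keep_reduced") r1$fit else fits$full

  ## 2: group x experience interactions
  r2 <- ladder_rung("interactions", best_fit,
                    sp(group_slopes = FALSE,
                       bee_slopes = best_spec$bee_slopes),
                    series, aic_threshold)
  fits$no_interactions <- r2$fit
  comparisons$interactions <- r2$cmp
  interactions_kept <- r2$cmp$decision == "keep_full"
  per_group_res <- NULL
  if (!interactions_kept) {
    best_fit <- r2$fit
    best_spec <- r2$fit$spec
    ## 3: group terms
    r3 <- ladder_rung("groups", best_fit,
                      sp(group_slopes = FALSE, group_intercepts = FALSE,
                         bee_slopes = best_spec$bee_slopes),
                      series, aic_threshold)
    fits$no_groups <- r3$fit
    comparisons$groups <- r3$cmp
    if (r3$cmp$decision == "keep_reduced") {
      best_fit <- r3$fit
      best_spec <- r3$fit$spec
    }
    ## 4: learning slope
    r4 <- ladder_rung("learning", best_fit,
                      sp(learning = FALSE, group_slopes = FALSE,
                         group_intercepts = best_spec$group_intercepts,
                         bee_slopes = best_spec$bee_slopes),
                      series, aic_threshold)
    fits$no_learning <- r4$fit
    comparisons$learning <- r4$cmp
    if (r4$cmp$decision == "keep_reduced") {
      best_fit <- r4$fit
      best_spec <- r4$fit$spec
    }
  } else if (per_group) {
    per_group_res <- do.call(rbind, lapply(unique(series$group), function(g) {
      cmp <- per_group_learning_test(series, g, aic_threshold,
                                     predictor_transform)
      cmp$name <- paste0("learning:", g)
      cmp
    }))
  }

  structure(list(comparisons = do.call(rbind, unname(comparisons)),
                 final_spec = best_spec,
                 final_fit = best_fit,
                 fits = fits,
                 per_group = per_group_res),
            class = "lcm_ladder")
}

#' @export
print.lcm_ladder <- function(x, ...) {
  cat("<lcm_ladder>\n")
  print(x$comparisons, digits = 4)
  if (!is.null(x$per_group)) {
    cat("per-group learning tests:\n")
    print(x$per_group, digits = 4)
  }
  invisible(x)
}

#' Per-group learning test
#'
#' Fits, on one test group's data only, the per-group model
#' `y = i + l log(x) + b_n` and its slope-free reduction, and compares
#' them. This is the test of whether that group's foraging success changed
#' with experience.
#'
#' @param series A success series.
#' @param group Group label present in `series`.
#' @param aic_threshold See [model_comparison()].
#' @param predictor_transform Passed to [model_spec()].
#' @return A `model_comparison` row.
#' @export
per_group_learning_test <- function(series, group, aic_threshold = 2,
                                    predictor_transform = "ln") {
  sub <- series[series$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("group '", group, "' is absent from the series")
  with_l <- model_spec(learning = TRUE, group_intercepts = FALSE,
                       group_slopes = FALSE, bee_intercepts = TRUE,
                       bee_slopes = FALSE,
                       predictor_transform = predictor_transform)
  without_l <- model_spec(learning = FALSE, group_intercepts = FALSE,
                          group_slopes = FALSE, bee_intercepts = TRUE,
                          bee_slopes = FALSE,
                          predictor_transform = predictor_transform)
  compare_models(fit_ml(sub, with_l), fit_ml(sub, without_l),
                 aic_threshold, name = "learning")
}

#' Write a ladder report as CSV
#'
#' Columns: `step,AIC_full,AIC_reduced,delta_AIC,deviance_change,df,p,decision`.
#' @param ladder An `lcm_ladder` from [run_ladder()].
#' @param path File path.
#' @param header_comment Optional `#` comment line content.
#' @return `path`, invisibly.
#' @export
write_ladder_csv <- function(ladder, path, header_comment = NULL) {
  stopifnot(inherits(ladder, "lcm_ladder"))
  tab <- rbind(ladder$comparisons, ladder$per_group)
  tab <- data.frame(step = tab$name, tab[setdiff(names(tab), "name")],
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
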