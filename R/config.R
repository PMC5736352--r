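#' Flight-arena configuration
#'
#' Describes the artificial-flower arena used in a conditioning experiment.
#' Two canonical designs are supported. The small-flower arena presents
#' sixteen flowers (eight of each temperature pattern); flowers are emptied
#' by probing and only refilled at the end of each foraging bout
#' (`refill_policy = "end_of_bout"`). The large-flower arena presents six
#' flowers (three of each pattern); flowers are topped up and moved to a new
#' position shortly after the bee departs them
#' (`refill_policy = "after_departure"`).
#'
#' @param flower_size `"small"` or `"large"`; fixes the flower counts and
#'   refill policy of the corresponding design.
#' @param mean_landings_per_bout Mean number of landings per foraging bout;
#'   bout lengths are drawn from a Poisson distribution truncated at 1.
#'   Defaults to the observed means: 10.53 (small) or 6.97 (large).
#' @param landings_learning Number of counted landings per bee in the
#'   learning phase (default 60).
#' @param landings_test Number of counted landings per bee in the
#'   nonrewarding test phase (default 20).
#'
#' @return An object of class `arena_config`.
#' @examples
#' arena_config("small")
#' arena_config("large")
#' @export
arena_config <- function(flower_size = c("small", "large"),
                         mean_landings_per_bout = NULL,
                         landings_learning = 60L,
                         landings_test = 20L) {
  flower_size <- match.arg(flower_size)
  if (is.null(mean_landings_per_bout)) {
    mean_landings_per_bout <- if (flower_size == "small") 10.53 else 6.97
  }
  stopifnot(mean_landings_per_bout > 0,
            landings_learning >= 1, landings_test >= 0)
  arena <- list(
    flower_size = flower_size,
    n_rewarding = if (flower_size == "small") 8L else 3L,
    n_nonrewarding = if (flower_size == "small") 8L else 3L,
    refill_policy = if (flower_size == "small") "end_of_bout" else "after_departure",
    mean_landings_per_bout = mean_landings_per_bout,
    landings_learning = as.integer(landings_learning),
    landings_test = as.integer(landings_test),
    patterns = if (flower_size == "small") c("bar", "circle") else c("bar", "cross")
  )
  class(arena) <- "arena_config"
  arena
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %s flowers: %d rewarding + %d nonrewarding, refill %s\n",
              x$flower_size, x$n_rewarding, x$n_nonrewarding, x$refill_policy))
  cat(sprintf("  mean landings/bout %.2f; counted landings %d learning / %d test\n",
              x$mean_landings_per_bout, x$landings_learning, x$landings_test))
  invisible(x)
}

#' Per-bee generative parameters
#'
#' Holds the parameters of one bee's true learning curve on the arcsine
#' (variance-stabilised) scale. The bee's success probability after `x`
#' counted visits is `sin(theta)^2` with
#' `theta = intercept_theta + bee_intercept_dev +
#' (learning_rate + bee_slope_dev) * log(x)`, clamped to `[0, pi/2]`.
#'
#' @param intercept_theta Initial arcsine success rate (radians). `pi/4`
#'   corresponds to chance performance (probability 0.5).
#' @param learning_rate Change in arcsine success per unit `log(visit)`.
#' @param bee_intercept_dev,bee_slope_dev This bee's deviations from the
#'   population intercept and slope (draws from zero-mean distributions when
#'   generated by [simulate_cohort()]).
#' @param spatial_bias In `[0, 1]`; strength of location-based learning that
#'   accrues as the experiment progresses, independent of the temperature
#'   pattern cue (see [simulate_trial()]). Default 0.
#'
#' @return An object of class `bee_params`.
#' @examples
#' bee_params(intercept_theta = pi / 4, learning_rate = 0.08)
#' @export
bee_params <- function(intercept_theta = pi / 4, learning_rate = 0,
                       bee_intercept_dev = 0, bee_slope_dev = 0,
                       spatial_bias = 0) {
  stopifnot(is.finite(intercept_theta), is.finite(learning_rate),
            spatial_bias >= 0, spatial_bias <= 1)
  structure(list(intercept_theta = intercept_theta,
                 learning_rate = learning_rate,
                 bee_intercept_dev = bee_intercept_dev,
                 bee_slope_dev = bee_slope_dev,
                 spatial_bias = spatial_bias),
            class = "bee_params")
}

#' Cohort (test-group) configuration
#'
#' Describes the set of test groups and the population-level generative
#' parameters for a simulated conditioning cohort. The baseline group is the
#' bar-rewards group; the reciprocal-pattern group (circle rewards in the
#' small-flower design, cross rewards in the large) may differ from it by
#' `group_intercept_shift` and `group_slope_shift`. The control group, whose
#' flowers present no temperature pattern, always has a generative learning
#' slope of zero: without a discriminative cue there is nothing to learn.
#'
#' @param groups Character vector drawn from `"control"`, `"bar_rewarded"`,
#'   `"circle_rewarded"`, `"cross_rewarded"`.
#' @param bees_per_group Number of bees simulated per group.
#' @param intercept_theta Population initial arcsine success (radians);
#'   default `pi/4`, i.e. probability 0.5.
#' @param learning_rate Population learning slope (radians per `log(visit)`)
#'   for the pattern-rewarded groups; default 0.08, which carries success
#'   from 0.5 at the start to roughly 0.8 by visit 60.
#' @param group_intercept_shift,group_slope_shift Difference of the
#'   circle/cross-rewards group from the bar-rewards baseline; defaults 0
#'   (learning is symmetric in which pattern is rewarded).
#' @param sd_bee_intercept,sd_bee_slope Standard deviations of the zero-mean
#'   Gaussian per-bee deviations in intercept and slope.
#' @param spatial_bias Location-learning strength passed to every bee
#'   (default 0); see [simulate_trial()].
#' @param n_nests Number of source nests; bees are assigned round-robin.
#' @param seed Global integer seed. Per-bee random streams are derived
#'   deterministically from it.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(bees_per_group = 12, seed = 1)
#' @export
cohort_config <- function(groups = c("control", "circle_rewarded", "bar_rewarded"),
                          bees_per_group = 12L,
                          intercept_theta = pi / 4,
                          learning_rate = 0.08,
                          group_intercept_shift = 0,
                          group_slope_shift = 0,
                          sd_bee_intercept = 0.1,
                          sd_bee_slope = 0.02,
                          spatial_bias = 0,
                          n_nests = 4L,
                          seed = 1L) {
  groups <- unique(as.character(groups))
  if (length(groups) == 0L) stop("`groups` must name at least one test group")
  valid <- c("control", "bar_rewarded", "circle_rewarded", "cross_rewarded")
  bad <- setdiff(groups, valid)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(bees_per_group >= 1, sd_bee_intercept >= 0, sd_bee_slope >= 0,
            n_nests >= 1, spatial_bias >= 0, spatial_bias <= 1)
  structure(list(groups = groups,
                 bees_per_group = as.integer(bees_per_group),
                 intercept_theta = intercept_theta,
                 learning_rate = learning_rate,
                 group_intercept_shift = group_intercept_shift,
                 group_slope_shift = group_slope_shift,
                 sd_bee_intercept = sd_bee_intercept,
                 sd_bee_slope = sd_bee_slope,
                 spatial_bias = spatial_bias,
                 n_nests = as.integer(n_nests),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d bees x {%s}; i=%.3f l=%.3f; bee sd (%.3f, %.3f); seed %d\n",
              x$bees_per_group, paste(x$groups, collapse = ", "),
              x$intercept_theta, x$learning_rate,
              x$sd_bee_intercept, x$sd_bee_slope, x$seed))
  invisible(x)
}

## Population-level curve parameters implied by a cohort config for a group.
## The control group's generative slope is pinned at zero.
group_truth <- function(cohort, group) {
  switch(group,
         control = list(intercept = cohort$intercept_theta, slope = 0),
         bar_rewarded = list(intercept = cohort$intercept_theta,
                             slope = cohort$learning_rate),
         circle_rewarded = ,
         cross_rewarded = list(
           intercept = cohort$intercept_theta + cohort$group_intercept_shift,
           slope = cohort$learning_rate + cohort$group_slope_shift),
         stop("unknown group label: ", group))
}
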