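# Shared fixtures: all built in code, deterministic under fixed seeds.

# A success series generated directly from the linear predictor
# theta = intercept + slope * log(x) (+ per-bee deviations + Gaussian noise),
# bypassing the visit-level simulator. Useful as an exactly specified input
# for the model-fitting layer.
make_series <- function(n_bees = 6, groups = "bar_rewarded",
                        intercept = pi / 4, slope = 0,
                        sd_bee_intercept = 0, sd_bee_slope = 0,
                        sd_resid = 0, xs = seq(10, 60, by = 10),
                        seed = 1) {
  set.seed(seed)
  groups <- rep(groups, length.out = length(groups))
  pieces <- list()
  bee <- 0
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    int_g <- if (length(intercept) > 1) intercept[gi] else intercept
    slo_g <- if (length(slope) > 1) slope[gi] else slope
    for (b in seq_len(n_bees)) {
      bee <- bee + 1
      bdev <- stats::rnorm(1, 0, sd_bee_intercept)
      rdev <- stats::rnorm(1, 0, sd_bee_slope)
      theta <- int_g + bdev + (slo_g + rdev) * log(xs) +
        stats::rnorm(length(xs), 0, sd_resid)
      theta <- pmin(pmax(theta, 0), pi / 2)
      pieces[[bee]] <- data.frame(bee_id = bee, group = g, x = xs,
                                  success = sin(theta)^2, theta = theta,
                                  stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pieces)
}

# Visit-level cohort reduced to a scored success series in one call.
sim_series <- function(seed, bees_per_group = 12,
                       groups = c("control", "circle_rewarded", "bar_rewarded"),
                       arena = arena_config("small"), ...) {
  cc <- cohort_config(groups = groups, bees_per_group = bees_per_group,
                      seed = seed, ...)
  v <- simulate_cohort(cc, arena, phases = "learning")
  windowed_success(score_landings(v[v$counted, , drop = FALSE]))
}

# Hand-rolled one-way ANOVA F from sums of squares, as an independent oracle.
anova_oracle <- function(theta, group) {
  group <- as.character(group)
  grand <- mean(theta)
  means <- tapply(theta, group, mean)
  ns <- tapply(theta, group, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((theta - means[group])^2)
  dfb <- length(means) - 1
  dfw <- length(theta) - length(means)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}
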