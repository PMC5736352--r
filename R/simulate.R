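#' True success probability after a given number of visits
#'
#' Evaluates a bee's generative learning curve. The curve lives on the
#' arcsine square-root scale: `theta(x) = intercept + slope * log(x)`,
#' clamped to `[0, pi/2]`, and the success probability is `sin(theta)^2`.
#' The logarithmic predictor makes early visits count for more, the usual
#' shape of conditioning curves.
#'
#' @param x Visit count(s), `>= 1`.
#' @param intercept Arcsine intercept (radians); include any group and
#'   per-bee intercept terms here.
#' @param slope Total slope in radians per `log(visit)` (population +
#'   group + per-bee terms).
#'
#' @return Success probabilities in `[0, 1]`, one per element of `x`.
#' @examples
#' true_success_curve(10, intercept = pi / 4)            # chance: 0.5
#' true_success_curve(20, intercept = 0.6, slope = 0.1)  # sin(0.6 + 0.1 log 20)^2
#' @export
true_success_curve <- function(x, intercept, slope = 0) {
  if (any(!is.finite(x)) || any(x < 1)) {
    stop("visit count `x` must be finite and >= 1")
  }
  theta <- clamp_theta(intercept + slope * log(x))
  sin(theta)^2
}

clamp_theta <- function(theta) pmin(pmax(theta, 0), pi / 2)

## Per-visit probability p* such that the arcsine-transformed success over a
## block of `n` Bernoulli(p*) visits is unbiased for the target theta:
##   E[ asin(sqrt(X/n)) ] = theta,  X ~ Binomial(n, p*).
## The plain inverse p = sin(theta)^2 leaves a theta-dependent transform bias
## of up to ~0.03 rad at n = 10; solving for p* removes it, so that the
## block-level linear model fitted downstream is correctly specified.
unbiased_block_prob <- function(theta, n) {
  theta <- clamp_theta(theta)
  vapply(theta, function(th) {
    if (th <= 0) return(0)
    if (th >= pi / 2) return(1)
    f <- function(p) {
      x <- 0:n
      sum(stats::dbinom(x, n, p) * asin(sqrt(x / n))) - th
    }
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }, numeric(1))
}

## Flower table for one bee: ids, designated reward role, displayed pattern.
## Rewarding flowers come first. Control flowers display no pattern (heating
## disconnected) but keep their designated roles, which is how the test
## phase of the control group is scored.
arena_flowers <- function(arena, group) {
  n <- arena$n_rewarding + arena$n_nonrewarding
  designated <- c(rep(TRUE, arena$n_rewarding), rep(FALSE, arena$n_nonrewarding))
  if (group == "control") {
    pattern <- rep("none", n)
  } else {
    rewarded_pattern <- switch(group,
                               bar_rewarded = "bar",
                               circle_rewarded = "circle",
                               cross_rewarded = "cross")
    if (!rewarded_pattern %in% arena$patterns) {
      stop("group ", group, " is incompatible with the ",
           arena$flower_size, "-flower arena (patterns: ",
           paste(arena$patterns, collapse = "/"), ")")
    }
    distractor <- setdiff(arena$patterns, rewarded_pattern)
    pattern <- ifelse(designated, rewarded_pattern, distractor)
  }
  data.frame(flower_id = seq_len(n), designated = designated,
             pattern = pattern, stringsAsFactors = FALSE)
}

rtrunc_pois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out < 1)) {
    idx <- which(out < 1)
    out[idx] <- stats::rpois(length(idx), lambda)
  }
  out
}

#' Simulate one bee's landings in one experimental phase
#'
#' Generates the bout-structured sequence of flower landings for a single
#' bee until the configured number of counted landings is reached. Each
#' counted landing is correct with the probability implied by the bee's
#' learning curve; the probe decision is then derived from the landed
#' flower's (designated) reward role, so that scoring the records recovers
#' the generated outcomes exactly.
#'
#' Depletion and revisit rules follow the arena design. In the small-flower
#' arena a probed flower is empty for the rest of the bout and further
#' landings on it are not counted; all flowers are refilled at the bout
#' boundary. In the large-flower arena flowers are refilled and relocated
#' shortly after the bee departs, so only an immediate return (before the
#' bee has landed elsewhere) is not counted.
#'
#' In the test phase all flowers are nonrewarding; landings are generated at
#' the success level the bee had reached at the end of the learning phase,
#' and the records keep the flowers' designated roles via their patterns and
#' ids so the test phase can be scored by the preceding reward scheme.
#'
#' @param bee A [bee_params()] object.
#' @param arena An [arena_config()] object.
#' @param group Test-group label (see [cohort_config()]).
#' @param phase `"learning"` or `"test"`.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param bee_id,nest_id Identifiers stored in the records.
#' @param prob_anchor How the per-visit success probability is derived from
#'   the curve. `"unbiased_block"` (default) holds the probability constant
#'   within each 10-visit block at the value that makes the block's
#'   arcsine-transformed success unbiased for `theta` at the block's
#'   endpoint; `"block"` uses the plain `sin(theta)^2` at the block
#'   endpoint; `"visit"` evaluates `sin(theta)^2` at every visit.
#'
#' @return A data frame of visit records with columns `bee_id`, `nest_id`,
#'   `group`, `phase`, `bout_index`, `visit_index` (1-based over counted
#'   landings, `NA` for uncounted ones), `flower_id`, `pattern`,
#'   `rewarding`, `probed`, `counted`.
#' @examples
#' rec <- simulate_trial(bee_params(learning_rate = 0.08), arena_config("small"),
#'                       group = "bar_rewarded", seed = 1)
#' sum(rec$counted)  # 60
#' @export
simulate_trial <- function(bee, arena, group = "bar_rewarded",
                           phase = c("learning", "test"), seed = 1L,
                           bee_id = 1L, nest_id = 1L,
                           prob_anchor = c("unbiased_block", "block", "visit")) {
  stopifnot(inherits(bee, "bee_params"), inherits(arena, "arena_config"))
  phase <- match.arg(phase)
  prob_anchor <- match.arg(prob_anchor)
  flowers <- arena_flowers(arena, group)
  n_target <- if (phase == "learning") arena$landings_learning else arena$landings_test
  if (n_target == 0L) return(empty_visits())

  intercept <- bee$intercept_theta + bee$bee_intercept_dev
  slope <- bee$learning_rate + bee$bee_slope_dev
  window <- 10L

  ## Per-visit success probability for counted visit x.
  p_of_x <- local({
    cache <- new.env(parent = emptyenv())
    function(x) {
      x_eval <- if (phase == "test") arena$landings_learning
                else if (prob_anchor == "visit") x
                else window * ceiling(x / window)
      key <- as.character(x_eval)
      if (!is.null(cache[[key]])) return(cache[[key]])
      th <- clamp_theta(intercept + slope * log(max(x_eval, 1)))
      p <- if (prob_anchor == "visit") sin(th)^2
           else if (phase == "test") unbiased_block_prob(th, n_target)
           else unbiased_block_prob(th, window)
      cache[[key]] <- p
      p
    }
  })

  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_fl <- nrow(flowers)
  rec <- list()
  counted_so_far <- 0L
  bout <- 0L
  last_flower <- NA_integer_
  while (counted_so_far < n_target) {
    bout <- bout + 1L
    bout_len <- rtrunc_pois(1, arena$mean_landings_per_bout)
    emptied <- logical(n_fl)
    for (i in seq_len(bout_len)) {
      if (counted_so_far >= n_target) break
      progress <- counted_so_far / n_target
      w <- rep(1, n_fl)
      if (bee$spatial_bias > 0) {
        w[flowers$designated] <- 1 + 2 * bee$spatial_bias * progress
      }
      fl <- sample.int(n_fl, 1L, prob = w)
      if (arena$refill_policy == "end_of_bout") {
        countable <- !emptied[fl]
      } else {
        ## after_departure: the flower is refilled and moved once the bee
        ## has landed elsewhere; only an immediate return is uncounted
        countable <- is.na(last_flower) || fl != last_flower
      }
      if (countable) {
        x <- counted_so_far + 1L
        p <- p_of_x(x)
        if (bee$spatial_bias > 0) {
          q <- bee$spatial_bias * progress
          p <- q + (1 - q) * p
        }
        correct <- stats::runif(1) < p
        designated <- flowers$designated[fl]
        probed <- if (correct) designated else !designated
        rec[[length(rec) + 1L]] <- list(bout, x, fl, probed, TRUE)
        counted_so_far <- x
        if (probed) emptied[fl] <- TRUE
      } else {
        rec[[length(rec) + 1L]] <- list(bout, NA_integer_, fl, FALSE, FALSE)
      }
      last_flower <- fl
    }
    last_flower <- NA_integer_  # bout boundary: bee returns to the nest
  }
  m <- length(rec)
  out <- data.frame(
    bee_id = rep(bee_id, m),
    nest_id = rep(nest_id, m),
    group = rep(group, m),
    phase = rep(phase, m),
    bout_index = vapply(rec, `[[`, integer(1), 1L),
    visit_index = vapply(rec, `[[`, integer(1), 2L),
    flower_id = vapply(rec, `[[`, integer(1), 3L),
    stringsAsFactors = FALSE
  )
  out$pattern <- flowers$pattern[out$flower_id]
  out$rewarding <- if (phase == "learning") flowers$designated[out$flower_id]
                   else rep(FALSE, m)
  out$probed <- vapply(rec, `[[`, logical(1), 4L)
  out$counted <- vapply(rec, `[[`, logical(1), 5L)
  out
}

empty_visits <- function() {
  data.frame(bee_id = integer(), nest_id = integer(), group = character(),
             phase = character(), bout_index = integer(),
             visit_index = integer(), flower_id = integer(),
             pattern = character(), rewarding = logical(),
             probed = logical(), counted = logical(),
             stringsAsFactors = FALSE)
}

#' Simulate a full conditioning cohort
#'
#' Generates every bee of every test group, each with independent zero-mean
#' Gaussian deviations in intercept and learning slope, through both the
#' learning phase and the nonrewarding test phase. Per-bee random streams
#' are derived deterministically from the cohort seed, so individual bees
#' are reproducible regardless of cohort composition.
#'
#' @param cohort A [cohort_config()] object.
#' @param arena An [arena_config()] object.
#' @param phases Which phases to generate (default both).
#' @param prob_anchor Passed to [simulate_trial()].
#'
#' @return A data frame of visit records (see [simulate_trial()]) for the
#'   whole cohort, with an attribute `"bee_truth"`: one row per bee giving
#'   the generative intercept and slope actually used.
#' @examples
#' visits <- simulate_cohort(cohort_config(bees_per_group = 2, seed = 1),
#'                           arena_config("small"))
#' table(visits$group[visits$counted & visits$phase == "learning"])
#' @export
simulate_cohort <- function(cohort, arena,
                            phases = c("learning", "test"),
                            prob_anchor = "unbiased_block") {
  stopifnot(inherits(cohort, "cohort_config"), inherits(arena, "arena_config"))
  phases <- match.arg(phases, c("learning", "test"), several.ok = TRUE)
  pieces <- list()
  truth <- list()
  counter <- 0L
  for (g in cohort$groups) {
    tr <- group_truth(cohort, g)
    for (b in seq_len(cohort$bees_per_group)) {
      counter <- counter + 1L
      base_seed <- (cohort$seed * 1009L + counter * 7919L) %% .Machine$integer.max
      set.seed(base_seed)
      b_dev <- if (cohort$sd_bee_intercept > 0)
        stats::rnorm(1, 0, cohort$sd_bee_intercept) else 0
      r_dev <- if (cohort$sd_bee_slope > 0)
        stats::rnorm(1, 0, cohort$sd_bee_slope) else 0
      bee <- bee_params(intercept_theta = tr$intercept,
                        learning_rate = tr$slope,
                        bee_intercept_dev = b_dev,
                        bee_slope_dev = r_dev,
                        spatial_bias = cohort$spatial_bias)
      nest <- ((counter - 1L) %% cohort$n_nests) + 1L
      for (ph in phases) {
        ph_seed <- (base_seed + if (ph == "learning") 1L else 2L) %% .Machine$integer.max
        pieces[[length(pieces) + 1L]] <-
          simulate_trial(bee, arena, group = g, phase = ph, seed = ph_seed,
                         bee_id = counter, nest_id = nest,
                         prob_anchor = prob_anchor)
      }
      truth[[counter]] <- data.frame(
        bee_id = counter, nest_id = nest, group = g,
        intercept = tr$intercept + b_dev, slope = tr$slope + r_dev,
        bee_intercept_dev = b_dev, bee_slope_dev = r_dev,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "bee_truth") <- do.call(rbind, truth)
  out
}

#' Write / read visit records as CSV
#'
#' The on-disk format is a comma-delimited table with the exact header
#' `bee_id,nest_id,group,phase,bout_index,visit_index,flower_id,pattern,rewarding,probed,counted`
#' and logical flags encoded as 0/1. An optional leading `#` comment line
#' records the seed and configuration hash of the run that produced the
#' file.
#'
#' @param visits A visit-record data frame.
#' @param path File path.
#' @param header_comment Optional single comment line (without the leading
#'   `"# "`) written above the header.
#' @return `write_visits()` returns `path` invisibly; `read_visits()`
#'   returns the visit-record data frame.
#' @export
write_visits <- function(visits, path, header_comment = NULL) {
  cols <- c("bee_id", "nest_id", "group", "phase", "bout_index",
            "visit_index", "flower_id", "pattern", "rewarding", "probed",
            "counted")
  stopifnot(all(cols %in% names(visits)))
  out <- visits[cols]
  for (cc in c("rewarding", "probed", "counted")) out[[cc]] <- as.integer(out[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cc in c("rewarding", "probed", "counted")) out[[cc]] <- as.logical(out[[cc]])
  out$visit_index <- as.integer(out$visit_index)
  out
}
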