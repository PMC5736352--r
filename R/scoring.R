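#' Arcsine square-root transform for proportions
#'
#' The variance-stabilising transform `asin(sqrt(p))` maps proportions in
#' `[0, 1]` to radians in `[0, pi/2]`; its inverse is `sin(theta)^2`. A
#' plain `asin(p)` variant is available for sensitivity checks.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param theta Radians in `[0, pi/2]`.
#' @param method `"asin_sqrt"` (default) or `"asin"`.
#' @return Transformed values.
#' @examples
#' arcsine_transform(c(0, 0.5, 1))  # 0, pi/4, pi/2
#' inverse_arcsine(pi / 4)          # 0.5
#' @export
arcsine_transform <- function(p, method = c("asin_sqrt", "asin")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  if (method == "asin_sqrt") asin(sqrt(p)) else asin(p)
}

#' @rdname arcsine_transform
#' @export
inverse_arcsine <- function(theta, method = c("asin_sqrt", "asin")) {
  method <- match.arg(method)
  if (method == "asin_sqrt") sin(theta)^2 else sin(theta)
}

#' Reward scheme learned during the learning phase
#'
#' Builds, per bee, the mapping from flower identity to its reward role in
#' the learning phase. For pattern-rewarded groups the role follows the
#' temperature pattern; for the control group (no pattern displayed) it
#' follows the flower's designated position. The scheme is what scores the
#' nonrewarding test phase.
#'
#' @param records Visit records covering the learning phase.
#' @return A data frame with columns `bee_id`, `group`, `pattern`,
#'   `flower_id`, `rewarding` (one row per bee x flower landed on).
#' @export
reward_scheme <- function(records) {
  learn <- records[records$phase == "learning", , drop = FALSE]
  if (nrow(learn) == 0L) stop("no learning-phase records to derive a reward scheme from")
  key <- !duplicated(learn[c("bee_id", "flower_id")])
  out <- learn[key, c("bee_id", "group", "pattern", "flower_id", "rewarding")]
  rownames(out) <- NULL
  out
}

#' Score counted landings as correct or incorrect actions
#'
#' In the learning phase a landing is correct when the bee probes the
#' feeding well of a rewarding flower or withholds probing on a
#' nonrewarding one; anything else is incorrect. In the test phase every
#' flower is nonrewarding, and a flower's "rewarding" status is the status
#' that its temperature pattern (or, for the control group, its designated
#' position) had in the preceding learning phase.
#'
#' @param records Visit records; every row must be counted (apply
#'   [filter_revisits()] or subset on `counted` first).
#' @param scheme A reward scheme from [reward_scheme()]; defaults to the
#'   scheme derivable from the learning-phase rows of `records` when any
#'   test-phase rows are present.
#' @return `records` with an added logical column `correct`.
#' @examples
#' v <- simulate_cohort(cohort_config(bees_per_group = 2, seed = 1),
#'                      arena_config("small"))
#' scored <- score_landings(v[v$counted, ])
#' mean(scored$correct)
#' @export
score_landings <- function(records, scheme = NULL) {
  if (any(!records$counted)) {
    stop("score_landings() expects counted records only; filter revisits first")
  }
  records$correct <- NA
  learn <- records$phase == "learning"
  records$correct[learn] <-
    records$rewarding[learn] == records$probed[learn]
  if (any(!learn)) {
    if (is.null(scheme)) scheme <- reward_scheme(records)
    test <- records[!learn, , drop = FALSE]
    ## pattern-based lookup where a pattern is displayed, position-based
    ## (flower_id) for the control group's unpatterned flowers; where a bee
    ## never landed on a flower/pattern in the learning phase, fall back to
    ## its group's (shared) scheme
    learned <- rep(NA, nrow(test))
    by_pattern <- test$pattern != "none"
    if (any(by_pattern)) {
      pat_map <- unique(scheme[scheme$pattern != "none",
                               c("bee_id", "group", "pattern", "rewarding")])
      idx <- match(paste(test$bee_id[by_pattern], test$pattern[by_pattern]),
                   paste(pat_map$bee_id, pat_map$pattern))
      learned[by_pattern] <- pat_map$rewarding[idx]
      miss <- by_pattern & is.na(learned)
      if (any(miss)) {
        grp_map <- unique(pat_map[c("group", "pattern", "rewarding")])
        idx <- match(paste(test$group[miss], test$pattern[miss]),
                     paste(grp_map$group, grp_map$pattern))
        learned[miss] <- grp_map$rewarding[idx]
      }
    }
    if (any(!by_pattern)) {
      idx <- match(paste(test$bee_id[!by_pattern], test$flower_id[!by_pattern]),
                   paste(scheme$bee_id, scheme$flower_id))
      learned[!by_pattern] <- scheme$rewarding[idx]
      miss <- !by_pattern & is.na(learned)
      if (any(miss)) {
        grp_map <- unique(scheme[c("group", "flower_id", "rewarding")])
        idx <- match(paste(test$group[miss], test$flower_id[miss]),
                     paste(grp_map$group, grp_map$flower_id))
        learned[miss] <- grp_map$rewarding[idx]
      }
    }
    if (any(is.na(learned))) {
      stop("test-phase records whose learned reward status cannot be resolved")
    }
    records$correct[!learn] <- learned == test$probed
  }
  records
}

#' Enforce revisit-exclusion rules on a landing sequence
#'
#' Recomputes the `counted` flags of a visit-record sequence from the raw
#' landing order, applying the arena's revisit rules, and renumbers
#' `visit_index` over the counted landings. Small-flower arena: a landing
#' on a flower the bee has already emptied (probed) earlier in the same
#' bout is not counted; all flowers are refilled at the bout boundary.
#' Large-flower arena: flowers are refilled and relocated once the bee has
#' landed elsewhere, so only an immediate return to the flower just
#' departed is not counted. First landings are always counted. The
#' operation is idempotent.
#'
#' @param records Visit records ordered by bee, phase and landing time
#'   (bout indices must be non-decreasing within each bee and phase).
#' @param arena The [arena_config()] the records were collected under.
#' @return `records` with `counted` and `visit_index` recomputed.
#' @export
filter_revisits <- function(records, arena) {
  stopifnot(inherits(arena, "arena_config"))
  out <- records
  for (key in unique(paste(records$bee_id, records$phase))) {
    sel <- which(paste(records$bee_id, records$phase) == key)
    r <- records[sel, , drop = FALSE]
    if (is.unsorted(r$bout_index)) {
      stop("records are not in landing order (bout_index decreases) for bee ",
           r$bee_id[1], ", ", r$phase[1], " phase")
    }
    counted <- logical(nrow(r))
    if (arena$refill_policy == "end_of_bout") {
      emptied <- integer(0)
      cur_bout <- NA_integer_
      for (i in seq_len(nrow(r))) {
        if (!identical(cur_bout, r$bout_index[i])) {
          cur_bout <- r$bout_index[i]
          emptied <- integer(0)
        }
        counted[i] <- !(r$flower_id[i] %in% emptied)
        if (counted[i] && r$probed[i]) emptied <- c(emptied, r$flower_id[i])
      }
    } else {
      last <- NA_integer_
      cur_bout <- NA_integer_
      for (i in seq_len(nrow(r))) {
        if (!identical(cur_bout, r$bout_index[i])) {
          cur_bout <- r$bout_index[i]
          last <- NA_integer_
        }
        counted[i] <- is.na(last) || r$flower_id[i] != last
        last <- r$flower_id[i]
      }
    }
    out$counted[sel] <- counted
    vi <- rep(NA_integer_, nrow(r))
    vi[counted] <- seq_len(sum(counted))
    out$visit_index[sel] <- vi
  }
  out
}

#' Windowed success rates over the learning phase
#'
#' Splits each bee's counted, scored landings into consecutive blocks of
#' `window` visits and reports the proportion of correct actions per block,
#' indexed by the visit count at the block's end (10, 20, ..., 60 for the
#' canonical design), together with its arcsine square-root transform.
#' Landings beyond the last full window are dropped.
#'
#' @param scored Scored counted records from [score_landings()].
#' @param window Block width in visits (default 10).
#' @param phase Phase to summarise (default `"learning"`).
#' @return A data frame with columns `bee_id`, `group`, `x`, `success`,
#'   `theta` -- one row per bee per block.
#' @examples
#' v <- simulate_cohort(cohort_config(bees_per_group = 2, seed = 1),
#'                      arena_config("small"))
#' series <- windowed_success(score_landings(v[v$counted, ]))
#' head(series)
#' @export
windowed_success <- function(scored, window = 10L, phase = "learning") {
  stopifnot("correct" %in% names(scored), window >= 1)
  sub <- scored[scored$phase == phase & scored$counted, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no counted records in the requested phase")
  pieces <- lapply(split(sub, sub$bee_id), function(r) {
    r <- r[order(r$visit_index), , drop = FALSE]
    n_blocks <- nrow(r) %/% window
    if (n_blocks < 1L) {
      stop("bee ", r$bee_id[1], " has fewer counted landings (", nrow(r),
           ") than one window (", window, ")")
    }
    succ <- vapply(seq_len(n_blocks), function(b) {
      mean(r$correct[(window * (b - 1) + 1):(window * b)])
    }, numeric(1))
    data.frame(bee_id = r$bee_id[1], group = r$group[1],
               x = window * seq_len(n_blocks),
               success = succ, theta = arcsine_transform(succ),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$bee_id, out$x), ]
}

#' Per-bee success over the nonrewarding test phase
#'
#' @param scored Scored counted records from [score_landings()] including
#'   test-phase rows.
#' @return A data frame with one row per bee: `bee_id`, `group`, `success`
#'   (proportion correct over the test landings) and `theta` (arcsine
#'   square-root scale).
#' @export
testphase_table <- function(scored) {
  stopifnot("correct" %in% names(scored))
  sub <- scored[scored$phase == "test" & scored$counted, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no counted test-phase records")
  pieces <- lapply(split(sub, sub$bee_id), function(r) {
    data.frame(bee_id = r$bee_id[1], group = r$group[1],
               success = mean(r$correct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$theta <- arcsine_transform(out$success)
  rownames(out) <- NULL
  out[order(out$bee_id), ]
}

#' Write a success series as CSV
#'
#' Columns: `bee_id,group,x,success,theta`.
#' @param series A success series from [windowed_success()].
#' @param path File path.
#' @param header_comment Optional `#` comment line content.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, header_comment = NULL) {
  cols <- c("bee_id", "group", "x", "success", "theta")
  stopifnot(all(cols %in% names(series)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  utils::write.csv(series[cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
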