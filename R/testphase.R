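#' One-way ANOVA on test-phase arcsine success
#'
#' Compares the arcsine-transformed test-phase success between test groups
#' by one-way analysis of variance. With one observation per bee, including
#' bee identity as a random factor is equivalent to the plain one-way
#' ANOVA, which is what is computed.
#'
#' @param table A test-phase table from [testphase_table()] (columns
#'   `bee_id`, `group`, `theta`).
#' @return A list with `F`, `df_between`, `df_within` and `p`.
#' @examples
#' tab <- data.frame(bee_id = 1:6, group = rep(c("a", "b"), each = 3),
#'                   theta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
#' testphase_anova(tab)
#' @export
testphase_anova <- function(table) {
  check_testphase_table(table)
  table$group <- factor(table$group)
  fit <- stats::aov(theta ~ group, data = table)
  sm <- summary(fit)[[1]]
  ssb <- sm["group", "Sum Sq"]
  df_between <- sm["group", "Df"]
  df_within <- sm["Residuals", "Df"]
  if (ssb <= .Machine$double.eps * sum(table$theta^2, 1)) {
    ## no between-group variation at all
    return(list(F = 0, df_between = df_between, df_within = df_within, p = 1))
  }
  list(F = sm["group", "F value"],
       df_between = df_between, df_within = df_within,
       p = sm["group", "Pr(>F)"])
}

check_testphase_table <- function(table) {
  stopifnot(all(c("group", "theta") %in% names(table)))
  counts <- table(table$group)
  if (length(counts) < 2L) stop("at least two test groups are required")
  if (any(counts < 2L)) {
    stop("every group needs at least two bees; too few in: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  invisible(TRUE)
}

#' Tukey HSD letter groupings for test-phase success
#'
#' Runs all pairwise Tukey honest-significant-difference comparisons on the
#' one-way ANOVA of arcsine test-phase success and assigns compact letter
#' groupings: groups that are not significantly different share a letter.
#' Letters are assigned in descending order of group mean, starting at
#' `"a"`, and the assignment does not depend on the input row order.
#'
#' @param table A test-phase table (columns `group`, `theta`, and
#'   optionally `success` for reporting).
#' @param alpha Significance level for the pairwise tests (default 0.05).
#' @return A data frame with one row per group, ordered by descending mean:
#'   `group`, `n`, `mean_theta`, `letter` (and `mean_success`, `sem` when
#'   `success` is available).
#' @export
tukey_groups <- function(table, alpha = 0.05) {
  check_testphase_table(table)
  table$group <- factor(table$group)
  fit <- stats::aov(theta ~ group, data = table)
  tk <- stats::TukeyHSD(fit, "group")$group
  groups <- levels(table$group)
  means <- tapply(table$theta, table$group, mean)
  ord <- names(sort(means, decreasing = TRUE))

  ## significant pairs from the Tukey table ("g2-g1" row names)
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  if (nrow(tk) > 0) {
    for (i in seq_len(nrow(tk))) {
      if (!is.na(tk[i, "p adj"]) && tk[i, "p adj"] < alpha) {
        sig[pairs[i, 1], pairs[i, 2]] <- TRUE
        sig[pairs[i, 2], pairs[i, 1]] <- TRUE
      }
    }
  }

  ## insert-and-absorb compact letter display
  sets <- list(ord)
  for (g1 in ord) {
    for (g2 in ord) {
      if (g1 < g2 && sig[g1, g2]) {
        new_sets <- list()
        for (s in sets) {
          if (all(c(g1, g2) %in% s)) {
            new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        ## drop duplicates, empty sets and sets absorbed by a superset
        uniq <- unique(lapply(new_sets, sort))
        uniq <- uniq[vapply(uniq, length, integer(1)) > 0]
        keep <- vapply(seq_along(uniq), function(i) {
          !any(vapply(seq_along(uniq), function(j) {
            j != i && length(uniq[[j]]) > length(uniq[[i]]) &&
              all(uniq[[i]] %in% uniq[[j]])
          }, logical(1)))
        }, logical(1))
        sets <- uniq[keep]
      }
    }
  }
  ## order letter sets by the best (highest-mean) group they contain
  rank_of <- stats::setNames(seq_along(ord), ord)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), numeric(1)))]
  letters_per_group <- vapply(ord, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))

  out <- data.frame(group = ord,
                    n = as.integer(table(table$group)[ord]),
                    mean_theta = as.numeric(means[ord]),
                    letter = letters_per_group,
                    stringsAsFactors = FALSE)
  if ("success" %in% names(table)) {
    out$mean_success <- as.numeric(tapply(table$success, table$group, mean)[ord])
    sds <- as.numeric(tapply(table$success, table$group, stats::sd)[ord])
    out$sem <- sds / sqrt(out$n)
  }
  rownames(out) <- NULL
  out
}

#' Write the test-phase summary as CSV
#'
#' Columns: `group,n,mean_success,sem,letter`, preceded by a one-line ANOVA
#' summary comment.
#' @param table A test-phase table (with `success`).
#' @param path File path.
#' @param alpha Significance level for the Tukey letters.
#' @param header_comment Optional extra `#` comment line content.
#' @return `path`, invisibly.
#' @export
write_testphase_csv <- function(table, path, alpha = 0.05,
                                header_comment = NULL) {
  an <- testphase_anova(table)
  tg <- tukey_groups(table, alpha)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  writeLines(sprintf("# one-way ANOVA on arcsine success: F(%d,%d) = %.3f, p = %.4g",
                     an$df_between, an$df_within, an$F, an$p), con)
  cols <- c("group", "n", "mean_success", "sem", "letter")
  utils::write.csv(tg[intersect(cols, names(tg))], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
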