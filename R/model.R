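#' Learning-curve model specification
#'
#' Selects which terms of the full hierarchical learning-curve model are
#' active. On the arcsine scale the full model for bee `n` of a given test
#' group at visit count `x` is
#'
#' \deqn{y_{nx} = i + l\,\ln x + T (s_t + c_t \ln x) + C (s_c + c_c \ln x)
#'   + b_n + r_n \ln x}
#'
#' where `T` indicates the circle/cross-rewards group, `C` the control
#' group (the bar-rewards group is the baseline), `b_n` and `r_n` are
#' zero-mean Gaussian per-bee deviations in intercept and slope, and the
#' residual is Gaussian. Group slope terms require both the learning slope
#' and the group intercept terms (hierarchy of effects).
#'
#' @param learning Include the population slope `l`?
#' @param group_intercepts Include the group intercept offsets `s_t`, `s_c`?
#' @param group_slopes Include the group-by-experience interactions `c_t`,
#'   `c_c`?
#' @param bee_intercepts Include per-bee random intercepts `b_n`?
#' @param bee_slopes Include per-bee random slopes `r_n`?
#' @param predictor_transform `"ln"` (natural log of the visit count, the
#'   default) or `"identity"`.
#' @return An object of class `lcm_spec`.
#' @examples
#' model_spec()                                   # the full model
#' model_spec(group_slopes = FALSE)               # no interactions
#' model_spec(learning = FALSE, group_intercepts = FALSE,
#'            group_slopes = FALSE, bee_slopes = FALSE)
#' @export
model_spec <- function(learning = TRUE, group_intercepts = TRUE,
                       group_slopes = TRUE, bee_intercepts = TRUE,
                       bee_slopes = TRUE,
                       predictor_transform = c("ln", "identity")) {
  predictor_transform <- match.arg(predictor_transform)
  if (group_slopes && !(learning && group_intercepts)) {
    stop("group slope terms require both `learning` and `group_intercepts`")
  }
  structure(list(learning = learning,
                 group_intercepts = group_intercepts,
                 group_slopes = group_slopes,
                 bee_intercepts = bee_intercepts,
                 bee_slopes = bee_slopes,
                 predictor_transform = predictor_transform),
            class = "lcm_spec")
}

#' @export
print.lcm_spec <- function(x, ...) {
  on <- names(Filter(isTRUE, x[c("learning", "group_intercepts",
                                 "group_slopes", "bee_intercepts",
                                 "bee_slopes")]))
  cat("<lcm_spec>", if (length(on)) paste(on, collapse = " + ") else "intercept only",
      sprintf("[predictor: %s]\n", x$predictor_transform))
  invisible(x)
}

#' Group indicator coding
#'
#' Maps a test-group label to the Boolean indicator pair `(T, C)`:
#' the bar-rewards group is the baseline `(0, 0)`, the control group is
#' `(0, 1)`, and the circle- or cross-rewards group is `(1, 0)`.
#'
#' @param group Character vector of group labels.
#' @return A two-column matrix with columns `T` and `C`.
#' @examples
#' group_indicator(c("bar_rewarded", "control", "circle_rewarded"))
#' @export
group_indicator <- function(group) {
  Tc <- ifelse(group %in% c("circle_rewarded", "cross_rewarded"), 1,
               ifelse(group %in% c("bar_rewarded", "control"), 0, NA))
  Cc <- ifelse(group == "control", 1,
               ifelse(group %in% c("bar_rewarded", "circle_rewarded",
                                   "cross_rewarded"), 0, NA))
  if (any(is.na(Tc)) || any(is.na(Cc))) {
    stop("unknown group label(s): ",
         paste(unique(group[is.na(Tc) | is.na(Cc)]), collapse = ", "))
  }
  cbind(T = Tc, C = Cc)
}

#' Build the design for a learning-curve model
#'
#' Assembles the response (arcsine-transformed block success), the
#' fixed-effect design matrix and the random-effect structure from a
#' success series and a [model_spec()].
#'
#' @param series A success series from [windowed_success()] (columns
#'   `bee_id`, `group`, `x`, `theta`).
#' @param spec A [model_spec()].
#' @return An object of class `lcm_design`: list with elements `y`, `X`
#'   (named columns), `bee` (factor), `lnx` (transformed predictor) and
#'   `spec`.
#' @export
build_design <- function(series, spec = model_spec()) {
  stopifnot(inherits(spec, "lcm_spec"),
            all(c("bee_id", "group", "x", "theta") %in% names(series)))
  lnx <- if (spec$predictor_transform == "ln") log(series$x) else series$x
  X <- matrix(1, nrow(series), 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$learning) X <- cbind(X, lnx = lnx)
  if (spec$group_intercepts || spec$group_slopes) {
    TC <- group_indicator(series$group)
    ## indicator columns for groups absent from the data would be all-zero;
    ## drop them so two-group designs stay full rank
    present <- colSums(TC != 0) > 0
    if (spec$group_intercepts) X <- cbind(X, TC[, present, drop = FALSE])
    if (spec$group_slopes) {
      S <- TC[, present, drop = FALSE] * lnx
      colnames(S) <- paste0(colnames(S), ":lnx")
      X <- cbind(X, S)
    }
  }
  structure(list(y = series$theta, X = X,
                 bee = factor(series$bee_id), lnx = lnx, spec = spec),
            class = "lcm_design")
}

## -2 * profile log-likelihood machinery -------------------------------------

## Split a design into per-bee blocks once, for the marginal likelihood.
design_blocks <- function(design) {
  idx <- split(seq_along(design$y), design$bee)
  lapply(idx, function(ii) {
    list(y = design$y[ii], X = design$X[ii, , drop = FALSE],
         z = design$lnx[ii])
  })
}

## Gaussian marginal negative log-likelihood with both the fixed effects
## (by generalised least squares) and the residual variance (analytically)
## profiled out. `lambda` holds the variance ratios relative to the
## residual variance: named subset of (lb = bee-intercept, lr = bee-slope).
## Per-bee covariance is sigma2 * W_n with W_n = I + lb J + lr z z'.
## Returns -loglik, the GLS beta and the profiled variance components.
profile_nll <- function(lambda, blocks, p) {
  lb <- if ("lb" %in% names(lambda)) lambda[["lb"]] else 0
  lr <- if ("lr" %in% names(lambda)) lambda[["lr"]] else 0
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  logdet <- 0
  yWy <- 0
  n <- 0
  ## identical z vectors across bees (balanced designs) share one factor
  cache <- list()
  for (bl in blocks) {
    m <- length(bl$y)
    key <- paste(signif(bl$z, 12), collapse = ",")
    ch <- cache[[key]]
    if (is.null(ch)) {
      W <- diag(1, m) + lb + lr * tcrossprod(bl$z)
      ch <- tryCatch(chol(W), error = function(e) NULL)
      if (is.null(ch)) return(list(nll = Inf))
      cache[[key]] <- ch
    }
    Wi_X <- backsolve(ch, forwardsolve(t(ch), bl$X))
    Wi_y <- backsolve(ch, forwardsolve(t(ch), bl$y))
    A <- A + crossprod(bl$X, Wi_X)
    bvec <- bvec + crossprod(bl$X, Wi_y)
    yWy <- yWy + sum(bl$y * Wi_y)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    n <- n + m
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = Inf))
  ## (y - Xb)' W^{-1} (y - Xb) = y'W^{-1}y - 2 b'X'W^{-1}y + b'Ab
  quad <- yWy - 2 * sum(beta * bvec) + sum(beta * (A %*% beta))
  s2 <- max(quad / n, 1e-12)
  nll <- 0.5 * (n * log(2 * pi) + logdet + n * log(s2) + n)
  list(nll = nll, beta = drop(beta), sigma2 = s2,
       vb = lb * s2, vr = lr * s2)
}

#' Fit a learning-curve model by maximum likelihood
#'
#' Maximises the Gaussian marginal likelihood of an [build_design()] design
#' over the fixed effects and the active variance components (per-bee
#' intercept variance, per-bee slope variance, residual variance). Fixed
#' effects are profiled out by generalised least squares; the variance
#' components are optimised on the log scale (with a floor of `1e-10` to
#' avoid boundary pathologies) by Nelder-Mead from a fixed set of starting
#' points, so the fit is deterministic. ML (not REML) estimation is used
#' throughout, so information criteria are comparable across fixed-effect
#' structures.
#'
#' @param design An `lcm_design` from [build_design()], or a success series
#'   (in which case `spec` is used to build the design).
#' @param spec A [model_spec()], used when `design` is a success series.
#' @return An object of class `lcm_fit`: fixed-effect `coefficients`,
#'   variance components `sigma2`, `var_bee_intercept`, `var_bee_slope`,
#'   `loglik`, `deviance` (`-2 loglik`), parameter count `k` (fixed effects
#'   + active variance components + residual variance) and `AIC`
#'   (`deviance + 2 k`).
#' @examples
#' v <- simulate_cohort(cohort_config(bees_per_group = 4, seed = 1),
#'                      arena_config("small"))
#' series <- windowed_success(score_landings(v[v$counted, ]))
#' fit <- fit_ml(series, model_spec(bee_slopes = FALSE))
#' fit$AIC
#' @export
fit_ml <- function(design, spec = model_spec()) {
  if (!inherits(design, "lcm_design")) design <- build_design(design, spec)
  spec <- design$spec
  X <- design$X
  y <- design$y
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1L) stop("fewer rows than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }

  ols_beta <- qr.coef(qrX, y)
  ols_res <- y - X %*% ols_beta
  s2_ols <- max(sum(ols_res^2) / n, 1e-12)

  vc_names <- c("sigma2",
                if (spec$bee_intercepts) "vb",
                if (spec$bee_slopes) "vr")
  n_vc <- length(vc_names)

  if (n_vc == 1L) {
    ## pure fixed-effects model: ML solution is closed-form OLS
    beta <- drop(ols_beta)
    s2 <- s2_ols
    loglik <- -0.5 * n * (log(2 * pi * s2) + 1)
    vb <- vr <- 0
    conv <- TRUE
  } else {
    blocks <- design_blocks(design)
    floor_l <- 1e-10  # variance-ratio floor against boundary pathologies
    lam_names <- c(if (spec$bee_intercepts) "lb", if (spec$bee_slopes) "lr")
    nll_par <- function(par) {
      lam <- pmax(exp(par), floor_l)
      names(lam) <- lam_names
      profile_nll(lam, blocks, p)$nll
    }
    if (length(lam_names) == 1L) {
      opt <- stats::optimize(nll_par, c(log(1e-8), log(1e4)), tol = 1e-10)
      best <- list(par = opt$minimum, value = opt$objective, convergence = 0)
    } else {
      ## fixed multi-start grid (ratios of bee to residual variance);
      ## the slope ratio acts through z^2 ~ (ln x)^2, hence smaller starts
      starts <- list(log(c(0.3, 0.03)), log(c(1, 0.1)),
                     log(c(0.02, 0.002)), log(c(3, 0.0005)))
      best <- NULL
      for (st in starts) {
        opt <- stats::optim(st, nll_par, method = "Nelder-Mead",
                            control = list(maxit = 1000, reltol = 1e-12))
        if (is.null(best) || opt$value < best$value) best <- opt
      }
    }
    lam <- pmax(exp(best$par), floor_l)
    names(lam) <- lam_names
    ml <- profile_nll(lam, blocks, p)
    beta <- ml$beta
    names(beta) <- colnames(X)
    loglik <- -ml$nll
    s2 <- ml$sigma2
    vb <- if (spec$bee_intercepts) ml$vb else 0
    vr <- if (spec$bee_slopes) ml$vr else 0
    conv <- best$convergence == 0
  }

  k <- p + n_vc  # fixed effects + bee variance components + residual variance
  deviance <- -2 * loglik
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 sigma2 = s2,
                 var_bee_intercept = vb,
                 var_bee_slope = vr,
                 loglik = loglik,
                 deviance = deviance,
                 k = k,
                 AIC = deviance + 2 * k,
                 n = n,
                 spec = spec,
                 converged = conv),
            class = "lcm_fit")
}

#' @export
print.lcm_fit <- function(x, ...) {
  cat("<lcm_fit> ML Gaussian learning-curve model\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  var components: residual %.5f, bee intercept %.5f, bee slope %.5f\n",
              x$sigma2, x$var_bee_intercept, x$var_bee_slope))
  cat(sprintf("  logLik %.3f | deviance %.3f | k %d | AIC %.3f | n %d\n",
              x$loglik, x$deviance, x$k, x$AIC, x$n))
  invisible(x)
}

#' Deviance, parameter count and AIC of a fit
#'
#' @param fit An `lcm_fit`.
#' @return A list with `deviance` (`-2 loglik`), `k` and `AIC`
#'   (`deviance + 2 k`, exactly).
#' @examples
#' \dontrun{information_criteria(fit)}
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "lcm_fit"))
  list(deviance = fit$deviance, k = fit$k, AIC = fit$AIC)
}

#' Population-level predicted learning curve
#'
#' Predicts the arcsine success and probability for a given test group at
#' the requested visit counts, with per-bee deviations set to zero.
#'
#' @param fit An `lcm_fit`.
#' @param group Test-group label.
#' @param xs Visit counts (`>= 1`).
#' @return A data frame with columns `x`, `theta`, `prob`.
#' @export
predict_curve <- function(fit, group, xs) {
  stopifnot(inherits(fit, "lcm_fit"))
  if (any(xs < 1)) stop("visit counts must be >= 1")
  spec <- fit$spec
  lnx <- if (spec$predictor_transform == "ln") log(xs) else xs
  X <- matrix(1, length(xs), 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$learning) X <- cbind(X, lnx = lnx)
  if (spec$group_intercepts || spec$group_slopes) {
    TC <- group_indicator(rep(group, length(xs)))
    if (spec$group_intercepts) X <- cbind(X, TC)
    if (spec$group_slopes) {
      X <- cbind(X, "T:lnx" = TC[, "T"] * lnx, "C:lnx" = TC[, "C"] * lnx)
    }
    ## columns pruned at fit time (group absent from the data) predict as
    ## zero only if the requested group does not load on them
    missing_cols <- setdiff(colnames(X), names(fit$coefficients))
    if (length(missing_cols)) {
      if (any(X[, missing_cols, drop = FALSE] != 0)) {
        stop("group '", group, "' was not represented in the fitted model")
      }
      X <- X[, setdiff(colnames(X), missing_cols), drop = FALSE]
    }
  }
  theta <- clamp_theta(drop(X %*% fit$coefficients[colnames(X)]))
  data.frame(x = xs, theta = theta, prob = sin(theta)^2)
}

#' Serialise a fit as a flat key-value report
#'
#' @param fit An `lcm_fit`.
#' @param path File path; when `NULL`, the lines are returned instead.
#' @return The report lines, invisibly when written to `path`.
#' @export
write_fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "lcm_fit"))
  lines <- c(
    sprintf("%s\t%.10g", names(fit$coefficients), fit$coefficients),
    sprintf("sigma2\t%.10g", fit$sigma2),
    sprintf("var_bee_intercept\t%.10g", fit$var_bee_intercept),
    sprintf("var_bee_slope\t%.10g", fit$var_bee_slope),
    sprintf("loglik\t%.10g", fit$loglik),
    sprintf("deviance\t%.10g", fit$deviance),
    sprintf("k\t%d", fit$k),
    sprintf("AIC\t%.10g", fit$AIC)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
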