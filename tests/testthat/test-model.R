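test_that("design matrices follow the group indicator coding", {
  series <- make_series(n_bees = 12,
                        groups = c("control", "circle_rewarded", "bar_rewarded"))
  d <- build_design(series, model_spec())
  expect_equal(dim(d$X), c(216L, 6L))
  expect_equal(colnames(d$X),
               c("(Intercept)", "lnx", "T", "C", "T:lnx", "C:lnx"))
  # a control bee's row at x = 10: T = 0, C = 1, predictor ln 10
  row <- which(series$group == "control" & series$x == 10)[1]
  expect_equal(unname(d$X[row, ]), c(1, log(10), 0, 1, 0, log(10)))
  # a circle-rewards bee: T = 1, C = 0
  row2 <- which(series$group == "circle_rewarded" & series$x == 20)[1]
  expect_equal(unname(d$X[row2, ]), c(1, log(20), 1, 0, log(20), 0))

  minimal <- model_spec(learning = FALSE, group_intercepts = FALSE,
                        group_slopes = FALSE, bee_intercepts = FALSE,
                        bee_slopes = FALSE)
  expect_equal(colnames(build_design(series, minimal)$X), "(Intercept)")

  bad <- series
  bad$group[1] <- "mystery"
  expect_error(build_design(bad, model_spec()), "unknown group label")
  # hierarchy: interactions require learning and group intercepts
  expect_error(model_spec(learning = FALSE, group_slopes = TRUE),
               "require both")
})

test_that("ML fitting recovers exact solutions on noiseless data", {
  series <- make_series(n_bees = 5, intercept = 0.5, slope = 0.1)
  spec <- model_spec(group_intercepts = FALSE, group_slopes = FALSE,
                     bee_intercepts = FALSE, bee_slopes = FALSE)
  fit <- fit_ml(series, spec)
  expect_equal(unname(fit$coefficients), c(0.5, 0.1), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-10)

  # two balanced groups with a pure intercept offset delta
  delta <- 0.15
  series2 <- make_series(n_bees = 6, groups = c("bar_rewarded", "control"),
                         intercept = c(0.6, 0.6 + delta), slope = c(0.05, 0.05))
  fit2 <- fit_ml(series2, model_spec(group_slopes = FALSE,
                                     bee_intercepts = FALSE,
                                     bee_slopes = FALSE))
  expect_equal(unname(fit2$coefficients["C"]), delta, tolerance = 1e-8)
})

test_that("with no bee variance the ML fit equals the OLS oracle", {
  series <- make_series(n_bees = 4, groups = c("bar_rewarded", "control"),
                        intercept = c(0.7, 0.8), slope = c(0.06, 0.01),
                        sd_resid = 0.12, seed = 7)
  spec <- model_spec(group_slopes = FALSE, bee_intercepts = FALSE,
                     bee_slopes = FALSE)
  fit <- fit_ml(series, spec)
  gi <- group_indicator(series$group)
  ols <- lm(series$theta ~ log(series$x) + gi[, "C"])
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
  n <- nrow(series)
  expect_equal(fit$sigma2, sum(resid(ols)^2) / n, tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("the fitter agrees with an independent mixed-model implementation", {
  series <- sim_series(seed = 5)
  fit <- fit_ml(series, model_spec())
  d <- series
  d$lnx <- log(d$x)
  gi <- group_indicator(d$group)
  d$Tg <- gi[, "T"]
  d$Cg <- gi[, "C"]
  m <- lme4::lmer(theta ~ lnx + Tg + Cg + Tg:lnx + Cg:lnx +
                    (1 | bee_id) + (0 + lnx | bee_id),
                  data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients),
               unname(lme4::fixef(m)[c("(Intercept)", "lnx", "Tg", "Cg",
                                       "lnx:Tg", "lnx:Cg")]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(c(fit$var_bee_intercept, fit$var_bee_slope, fit$sigma2), vc,
               tolerance = 1e-3)

  # random-intercept-only model too
  fit1 <- fit_ml(series, model_spec(bee_slopes = FALSE))
  m1 <- lme4::lmer(theta ~ lnx + Tg + Cg + Tg:lnx + Cg:lnx + (1 | bee_id),
                   data = d, REML = FALSE)
  expect_equal(fit1$loglik, as.numeric(logLik(m1)), tolerance = 1e-5)
})

test_that("adding parameters never increases the deviance", {
  # nested-model monotonicity on random small datasets
  for (s in 1:50) {
    series <- make_series(n_bees = 6, intercept = 0.7, slope = 0.05,
                          sd_bee_intercept = 0.1, sd_bee_slope = 0.02,
                          sd_resid = 0.15, seed = 100 + s)
    full <- fit_ml(series, model_spec(group_intercepts = FALSE,
                                      group_slopes = FALSE))
    red <- fit_ml(series, model_spec(group_intercepts = FALSE,
                                     group_slopes = FALSE,
                                     bee_slopes = FALSE))
    expect_lte(full$deviance, red$deviance + 1e-6)
  }
})

test_that("information criteria satisfy AIC = deviance + 2k", {
  series <- sim_series(seed = 6, bees_per_group = 6)
  for (spec in list(model_spec(),
                    model_spec(bee_slopes = FALSE),
                    model_spec(group_slopes = FALSE, bee_slopes = FALSE),
                    model_spec(learning = FALSE, group_intercepts = FALSE,
                               group_slopes = FALSE, bee_slopes = FALSE))) {
    fit <- fit_ml(series, spec)
    ic <- information_criteria(fit)
    expect_equal(ic$AIC, ic$deviance + 2 * ic$k)
    expect_true(is.finite(ic$deviance))
  }
})

test_that("singular designs fail loudly with the collinear columns named", {
  # a single observed visit count makes the predictor collinear with the
  # intercept
  series <- make_series(n_bees = 6, groups = "bar_rewarded", slope = 0.05,
                        sd_resid = 0.1, seed = 3, xs = rep(20, 6))
  expect_error(fit_ml(series, model_spec(group_intercepts = FALSE,
                                         group_slopes = FALSE,
                                         bee_slopes = FALSE)),
               "singular design.*lnx")
})

test_that("population-level predictions follow the fitted curve", {
  series <- make_series(n_bees = 5, groups = c("bar_rewarded", "control"),
                        intercept = c(0.6, 0.75), slope = c(0.08, 0.08),
                        sd_resid = 0.05, seed = 9)
  fit <- fit_ml(series, model_spec(group_slopes = FALSE,
                                   bee_intercepts = TRUE, bee_slopes = FALSE))
  pr <- predict_curve(fit, "bar_rewarded", c(1, 10, 20, 40, 60))
  # at x = 1 the prediction is the intercept (plus group terms): ln 1 = 0
  expect_equal(pr$theta[1], unname(fit$coefficients["(Intercept)"]))
  expect_true(all(diff(pr$theta) >= 0))  # positive slope: monotone
  expect_equal(pr$prob, sin(pr$theta)^2)

  # slope-free fit predicts a flat curve
  flat <- make_series(n_bees = 5, groups = c("bar_rewarded", "control"),
                      intercept = c(0.7, 0.7), slope = c(0, 0),
                      sd_resid = 0.05, seed = 10)
  fit0 <- fit_ml(flat, model_spec(learning = FALSE, group_intercepts = FALSE,
                                  group_slopes = FALSE, bee_slopes = FALSE))
  pr0 <- predict_curve(fit0, "control", c(10, 60))
  expect_equal(pr0$theta[1], pr0$theta[2])
  expect_error(predict_curve(fit0, "control", 0), ">= 1")
})

test_that("fit reports serialise as flat key-value text", {
  series <- make_series(n_bees = 4, slope = 0.05, sd_resid = 0.1, seed = 2)
  fit <- fit_ml(series, model_spec(group_intercepts = FALSE,
                                   group_slopes = FALSE, bee_slopes = FALSE))
  lines <- write_fit_report(fit)
  expect_true(any(grepl("^AIC\t", lines)))
  got <- as.numeric(sub(".*\t", "", lines[grepl("^deviance\t", lines)]))
  expect_equal(got, fit$deviance, tolerance = 1e-8)
})
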