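test_that("thermograph generation is deterministic and bounded", {
  sp <- pattern_spec("circle_edge_hot", noise_sd = 0.3, seed = 5)
  t1 <- generate_thermograph(sp)
  t2 <- generate_thermograph(sp)
  expect_identical(t1$grid, t2$grid)
  expect_identical(dim(t1$grid), dim(t1$mask))
  expect_gt(sum(t1$mask), 400)  # at least 20x20 flower pixels

  # noiseless grids live between the plateaus, for every shape
  for (shape in c("circle_edge_hot", "bar_hot", "cross_hot", "center_hot")) {
    tg <- generate_thermograph(pattern_spec(shape, noise_sd = 0))
    vals <- tg$grid[tg$mask]
    expect_true(all(vals >= 25 & vals <= 33))
  }
  expect_error(generate_thermograph(pattern_spec("bar_hot"), pixel_size = 5),
               "at least 20 pixels")
  expect_error(pattern_spec("bar_hot", hot_temp = 20, cold_temp = 25),
               "hot_temp")
  expect_error(pattern_spec("cross_hot", heated_area_fraction = 1.2),
               "strictly between")
})

test_that("differently shaped patterns match in heated area", {
  # the no-cue constraint: circle and bar heat the same area
  f <- 0.25
  circ <- generate_thermograph(pattern_spec("circle_edge_hot",
                                            heated_area_fraction = f))
  bar <- generate_thermograph(pattern_spec("bar_hot", heated_area_fraction = f))
  hc <- heated_area_stats(circ)$heated_fraction
  hb <- heated_area_stats(bar)$heated_fraction
  expect_lt(abs(hc - hb) / hb, 0.02)
  expect_equal(hc, f, tolerance = 0.02)

  # large flowers: cross vs bar
  crossL <- generate_thermograph(pattern_spec("cross_hot", diameter = 85,
                                              hot_temp = 30, cold_temp = 24))
  barL <- generate_thermograph(pattern_spec("bar_hot", diameter = 85,
                                            hot_temp = 30, cold_temp = 24))
  expect_lt(abs(heated_area_stats(crossL)$heated_fraction -
                heated_area_stats(barL)$heated_fraction) /
              heated_area_stats(barL)$heated_fraction, 0.02)
})

test_that("within-flower range matches the hottest minus coldest point", {
  expect_equal(within_flower_range(generate_thermograph(pattern_spec("uniform"))), 0)
  # 33 degC hot / 25 degC cold plateaus give an 8 degC contrast
  circ <- generate_thermograph(pattern_spec("circle_edge_hot",
                                            hot_temp = 33, cold_temp = 25))
  expect_equal(within_flower_range(circ), 8, tolerance = 0.01)

  # exhaustive pixel-scan oracle on a noisy field
  tg <- generate_thermograph(pattern_spec("bar_hot", noise_sd = 0.5, seed = 9))
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(nrow(tg$grid))) {
    for (j in seq_len(ncol(tg$grid))) {
      if (tg$mask[i, j]) {
        mx <- max(mx, tg$grid[i, j])
        mn <- min(mn, tg$grid[i, j])
      }
    }
  }
  expect_equal(within_flower_range(tg), mx - mn)

  # invariant under a constant offset of the whole grid
  tg2 <- tg
  tg2$grid <- tg2$grid + 3.7
  expect_equal(within_flower_range(tg2), within_flower_range(tg))
})

test_that("heated-area statistics cover degenerate fields", {
  tg <- generate_thermograph(pattern_spec("bar_hot"))
  # every pixel above a cut below the cold plateau
  expect_equal(heated_area_stats(tg, cut = 20)$heated_fraction, 1)
  # checkerboard half-hot field: fraction one half
  chk <- tg
  chk$grid[] <- 25
  chk$grid[(row(chk$grid) + col(chk$grid)) %% 2 == 0] <- 33
  expect_equal(heated_area_stats(chk, cut = 29)$heated_fraction, 0.5,
               tolerance = 0.02)
})

test_that("matched pattern pairs present no overall-temperature cue", {
  f <- 0.25
  circ <- generate_thermograph(pattern_spec("circle_edge_hot",
                                            heated_area_fraction = f))
  bar <- generate_thermograph(pattern_spec("bar_hot", heated_area_fraction = f))
  m1 <- heated_area_stats(circ)$mean_overall_temp
  m2 <- heated_area_stats(bar)$mean_overall_temp
  expect_lt(abs(m1 - m2), 0.25)  # far below the 2 degC detectability limit
  expect_lt(abs(within_flower_range(circ) - within_flower_range(bar)), 0.05)
})

test_that("survey summaries count detectable species and their ranges", {
  # 65 of 118 species at the 2 degC threshold displays as 55%
  ranges <- c(seq(2, 8, length.out = 65), seq(0, 1.9, length.out = 53))
  s <- survey_summary(ranges, threshold = 2)
  expect_equal(s$n_species, 118L)
  expect_equal(s$n_detectable, 65L)
  expect_equal(s$percent_display, 55)

  # hand-computed mean and sample SD over the detectable subset
  s2 <- survey_summary(c(2, 4, 6), threshold = 2)
  expect_equal(s2$mean_range, 4)
  expect_equal(s2$sd_range, 2)

  # nothing detectable: flagged, not an error
  s3 <- survey_summary(c(0.1, 0.5, 1.9), threshold = 2)
  expect_equal(s3$n_detectable, 0L)
  expect_true(is.na(s3$mean_range))

  # the proportion is scale-free under duplication
  s4 <- survey_summary(rep(ranges, 2), threshold = 2)
  expect_equal(s4$proportion_detectable, s$proportion_detectable)

  expect_error(survey_summary(numeric(0)), "non-empty")
  expect_error(survey_summary(c(1, -2)), "non-negative")
})

test_that("the synthetic survey produces plausible per-species ranges", {
  sv <- simulate_survey(n_species = 60, seed = 3)
  expect_equal(nrow(sv), 60L)
  expect_true(all(sv$range >= 0))
  # uniform species have near-zero range; patterned species track contrast
  expect_lt(max(sv$range[sv$shape == "uniform"]), 1.5)
  pat <- sv$shape != "uniform"
  expect_gt(cor(sv$contrast[pat], sv$range[pat]), 0.95)
  # deterministic under the seed
  expect_identical(simulate_survey(n_species = 60, seed = 3), sv)
})

test_that("thermographs survive the delimited-text round trip", {
  tg <- generate_thermograph(pattern_spec("cross_hot", noise_sd = 0.2, seed = 8),
                             pixel_size = 1)
  base <- file.path(withr::local_tempdir(), "tg")
  write_thermograph(tg, base)
  back <- read_thermograph(base)
  expect_equal(back$grid, tg$grid, tolerance = 1e-6)
  expect_identical(back$mask, tg$mask)
  expect_equal(back$pixel_size, tg$pixel_size)
  expect_equal(within_flower_range(back), within_flower_range(tg),
               tolerance = 1e-6)
})
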