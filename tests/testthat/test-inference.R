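test_that("fit_linear: exact cases and agreement with lm", {
  f <- fit_linear(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)

  f0 <- fit_linear(c(0, 1, 2), c(1, 1, 1))
  expect_equal(f0$slope, 0); expect_equal(f0$F_stat, 0)
  expect_equal(f0$p_value, 1)

  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(50); y <- 2 * x + rnorm(50)
    f <- fit_linear(x, y)
    m <- summary(lm(y ~ x))
    expect_equal(f$slope, unname(coef(m)[2, 1]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1, 1]), tolerance = 1e-10)
    expect_equal(f$F_stat, unname(m$fstatistic[1]), tolerance = 1e-10)
    expect_equal(f$p_value, unname(coef(m)[2, 4]), tolerance = 1e-10)
  }

  expect_error(fit_linear(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
  # NaN pairs are dropped before fitting
  f2 <- fit_linear(c(0, 1, 2, NaN), c(0, 1, 2, 5))
  expect_identical(f2$n_points, 3L)
})

test_that("classification counts by sign and significance", {
  fits <- list(list(slope = 1, p_value = 0.001),
               list(slope = -1, p_value = 0.001),
               list(slope = 1, p_value = 0.5))
  cc <- classify_roi_fits(fits)
  expect_equal(unname(cc$counts), c(1L, 1L, 1L))
  cc0 <- classify_roi_fits(list())
  expect_equal(sum(cc0$counts), 0L)
})

test_that("resampling comparison is deterministic and calibrated", {
  gen_pop <- function(n_roi, slope, seed) {
    set.seed(seed)
    lapply(seq_len(n_roi), function(i) {
      x <- seq(0, 1, length.out = 20)
      list(x = x, y = slope * x + rnorm(20, 0, 0.3))
    })
  }
  pop <- gen_pop(30, 1, 1)
  ref_pop <- gen_pop(5, 1, 2)
  ref <- fit_linear(unlist(lapply(ref_pop, `[[`, "x")),
                    unlist(lapply(ref_pop, `[[`, "y")))
  rc <- resample_comparison(pop, 5, ref, n_reps = 200, seed = 7)
  rc2 <- resample_comparison(pop, 5, ref, n_reps = 200, seed = 7)
  expect_identical(rc$slopes, rc2$slopes)
  expect_true(rc$contained)

  # reference displaced far outside the cloud is rejected
  ref_far <- ref; ref_far$slope <- ref$slope + 5
  expect_false(resample_comparison(pop, 5, ref_far, n_reps = 200, seed = 7)$contained)

  expect_error(resample_comparison(pop, 30, ref), "smaller")
})

test_that("ANCOVA omnibus matches the nested-model lm/anova oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- sample(2:4, 1)
    groups <- lapply(seq_len(g), function(i) {
      x <- rnorm(30)
      list(x = x, y = i * 0.3 * x + rnorm(30))
    })
    names(groups) <- paste0("grp", seq_len(g))
    res <- ancova_slopes(groups)
    df <- do.call(rbind, lapply(seq_len(g), function(i)
      data.frame(x = groups[[i]]$x, y = groups[[i]]$y, g = names(groups)[i])))
    df$g <- factor(df$g)
    a <- anova(lm(y ~ g + x, df), lm(y ~ g * x, df))
    expect_equal(res$F_stat, a$F[2], tolerance = 1e-8)
    expect_equal(res$p_value, a$`Pr(>F)`[2], tolerance = 1e-8)
  }
  expect_error(ancova_slopes(list(a = list(x = 1:5, y = 1:5))), ">= 2 groups")
  expect_error(ancova_slopes(list(a = list(x = 1:5, y = rnorm(5)),
                                  b = list(x = rep(1, 5), y = rnorm(5)))),
               "b")
})

test_that("ANCOVA pairwise Tukey separates unequal slopes", {
  set.seed(42)
  mk <- function(sl) { x <- rnorm(200); list(x = x, y = sl * x + rnorm(200)) }
  res <- ancova_slopes(list(flat = mk(0), steep = mk(1), steep2 = mk(1)))
  pw <- res$pairwise
  p_fs <- pw$adjusted_p[pw$group_a == "flat" & pw$group_b == "steep"]
  p_ss <- pw$adjusted_p[pw$group_a == "steep" & pw$group_b == "steep2"]
  expect_lt(p_fs, 0.001)
  expect_gt(p_ss, 0.05)
  expect_identical(nrow(pw), 3L)           # all pairs covered
  expect_true(all(pw$adjusted_p >= 0 & pw$adjusted_p <= 1))
})

test_that("one-way ANOVA matches the textbook decomposition and aov/TukeyHSD", {
  # hand-computed 3-group toy table
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8, 9, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- anova_tukey(vals, grp)
  a <- summary(aov(vals ~ factor(grp)))[[1]]
  expect_equal(res$F_stat, a$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, a$`Pr(>F)`[1], tolerance = 1e-10)
  tk <- TukeyHSD(aov(vals ~ factor(grp)))$`factor(grp)`
  for (k in seq_len(nrow(res$pairwise))) {
    pair <- paste0(res$pairwise$group_b[k], "-", res$pairwise$group_a[k])
    expect_equal(res$pairwise$adjusted_p[k], tk[pair, "p adj"],
                 tolerance = 1e-8, label = pair)
  }

  # identical groups: F ~ 0, p ~ 1
  res0 <- anova_tukey(rep(5, 12), grp)
  expect_equal(res0$F_stat, 0)

  # one group shifted by 10 sd: its pairwise p is tiny
  set.seed(8)
  v2 <- c(rnorm(20), rnorm(20), rnorm(20) + 10)
  g2 <- rep(c("l1", "l2", "l9"), each = 20)
  res2 <- anova_tukey(v2, g2, reference = "l9")
  pw <- res2$pairwise
  expect_lt(max(pw$adjusted_p[pw$vs_reference]), 0.01)

  # undersized groups are dropped
  suppressMessages(res3 <- anova_tukey(c(vals, 99), c(grp, "solo")))
  expect_false("solo" %in% c(res3$pairwise$group_a, res3$pairwise$group_b))
})

test_that("shuffle baseline: unit-mean identity, determinism, band sanity", {
  set.seed(9)
  n_roi <- 12; n_t <- 3000
  tr <- t(vapply(seq_len(n_roi), function(i) {
    x <- 1 + rnorm(n_t, 0, 0.2); x / mean(x)
  }, numeric(n_t)))
  b <- shuffle_baseline(tr, subsample_n = 6, n_shuffles = 50,
                        n_subsample_reps = 50, frame_rate_hz = 30,
                        min_shift_s = 10, seed = 3)
  expect_equal(mean(b$mean), 1, tolerance = 0.01)
  expect_true(all(b$ci_lo <= b$mean & b$mean <= b$ci_hi))
  b2 <- shuffle_baseline(tr, subsample_n = 6, n_shuffles = 50,
                         n_subsample_reps = 50, frame_rate_hz = 30,
                         min_shift_s = 10, seed = 3)
  expect_identical(b$ci_hi, b2$ci_hi)

  expect_error(shuffle_baseline(tr, subsample_n = 20), "exceeds")

  # binned variant: bin_fun is applied to every replicate mean
  bb <- shuffle_baseline(tr, subsample_n = 6, n_shuffles = 20,
                         n_subsample_reps = 20, frame_rate_hz = 30,
                         min_shift_s = 10, seed = 3,
                         bin_fun = function(m) tapply(m, rep(1:60, each = 50), mean))
  expect_length(bb$mean, 60)
})

test_that("significant-run detection applies the consecutive-point rule", {
  base <- structure(list(mean = rep(1, 300), ci_lo = rep(0.9, 300),
                         ci_hi = rep(1.1, 300)),
                    class = "axonav_shuffle_baseline")
  s <- rep(1, 300); s[101:102] <- 1.2
  r <- detect_significant_runs(s, base, min_run = 2, frame_rate_hz = 30)
  expect_identical(nrow(r$segments), 1L)
  expect_identical(r$segments$start, 100L)
  expect_identical(r$segments$end, 102L)        # half-open [100, 102)
  expect_equal(r$segments$duration_s, 2 / 30)

  s2 <- rep(1, 300); s2[150] <- 1.2             # isolated point: no segment
  expect_identical(nrow(detect_significant_runs(s2, base, 2)$segments), 0L)

  expect_identical(nrow(detect_significant_runs(base$mean, base, 2)$segments), 0L)
  expect_error(detect_significant_runs(rep(1, 10), base), "length")
})
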