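test_that("discrimination and the forward model evaluate the algebra", {
  expect_equal(discrimination(3.74, 2.13), 1.61)
  expect_equal(discrimination(5, 5), 0)
  expect_equal(discrimination(-25.5, -28.3), 2.8)

  expect_equal(mixing_forward(1, 2.13, 4.12, 1.61), 3.74)
  expect_equal(mixing_forward(0, 7, -3, 0), -3)
  expect_equal(mixing_forward(0.5, 2, 4, 0), 3)
  expect_warning(mixing_forward(1.4, 2, 4, 0), "fraction")
})

test_that("inverting the reference nitrogen means gives the published line", {
  gm <- reference_group_means()
  nline <- mixing_line(gm$d15N[1], gm$d15N[2], gm$d15N[3], "N")
  expect_equal(nline$intercept, 0.19, tolerance = 0.01)
  expect_equal(nline$slope, 0.50, tolerance = 0.01)
  expect_equal(discrimination_at(nline, 1), 1.61, tolerance = 1e-12)
  # the line read at the implied discrimination returns to a pure-leaf diet
  expect_equal(as.numeric(fraction_at(nline, 1.61)), 1, tolerance = 0.01)

  cline <- mixing_line(gm$d13C[1], gm$d13C[2], gm$d13C[3], "C")
  expect_equal(cline$intercept, -0.5556, tolerance = 1e-4)
  expect_equal(cline$slope, 0.5556, tolerance = 1e-4)
  expect_equal(discrimination_at(cline, 1), 2.8, tolerance = 1e-12)

  # literature full-trophic-step discrimination implies an impossible
  # leaf fraction and is flagged, not clamped
  f <- fraction_at(nline, 3.4)
  expect_equal(as.numeric(f), nline$intercept + nline$slope * 3.4)
  expect_gt(as.numeric(f), 1.85)
  expect_true(attr(f, "out_of_range"))

  expect_error(mixing_line(3, 2, 2, "N"), "degenerate")
})

test_that("line round trips hold to machine precision", {
  set.seed(5)
  for (i in 1:20) {
    means <- rnorm(3, sd = 5)
    if (abs(means[2] - means[3]) < 0.1) next
    line <- mixing_line(means[1], means[2], means[3],
                        sample(c("N", "C"), 1))
    delta <- rnorm(1, sd = 3)
    expect_equal(discrimination_at(line, fraction_at(line, delta)), delta,
                 tolerance = 1e-12)
    # fraction hits 1 exactly at consumer - source1
    expect_equal(as.numeric(fraction_at(line, means[1] - means[2])), 1,
                 tolerance = 1e-12)
    # forward then invert recovers the fraction
    p_star <- runif(1)
    d_star <- rnorm(1)
    cons <- mixing_forward(p_star, means[2], means[3], d_star)
    line2 <- mixing_line(cons, means[2], means[3])
    expect_equal(as.numeric(fraction_at(line2, d_star)), p_star,
                 tolerance = 1e-12)
  }
})

test_that("group means summarize roles and refuse missing ones", {
  d <- data.frame(role = c("leaves", "leaves", "larvae"),
                  d15N = c(2, 4, 5), d13C = c(-28, -26, -27))
  gm <- group_means(d)
  expect_equal(gm$mean_d15N[gm$role == "leaves"], 3)
  expect_equal(gm$sd_d15N[gm$role == "larvae"], 0)
  expect_identical(gm$n[gm$role == "larvae"], 1L)
  expect_error(group_means(d, c("leaves", "consumer")), "consumer")
})

test_that("Welch t has fractional df, antisymmetry, and a hand-checked value", {
  a <- c(0, 0, 1, 1)
  b <- c(10, 10, 11, 11)
  r <- welch_t(a, b)
  # hand Welch: means 0.5 / 10.5, each var 1/3 with n = 4
  # t = -10 / sqrt(2 * (1/3) / 4) = -24.4949, Welch-Satterthwaite df = 6
  expect_equal(r$statistic, -10 / sqrt(1 / 6), tolerance = 1e-9)
  expect_equal(r$df, 6, tolerance = 1e-9)

  r2 <- welch_t(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)

  # unequal variances produce fractional df
  set.seed(8)
  x <- rnorm(20, sd = 0.3)
  y <- rnorm(12, sd = 2)
  rw <- welch_t(x, y)
  expect_false(abs(rw$df - round(rw$df)) < 1e-9)
  rp <- welch_t(x, y, pooled = TRUE)
  expect_equal(rp$df, 30)

  # identical groups: no evidence
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("paired mode differences drive the test and ids must match", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 2)

  a <- c(3.1, 2.8, 3.6, 3.3)
  b <- c(2.0, 2.2, 2.1, 1.9)
  ids <- c("t1", "t2", "t3", "t4")
  r <- welch_t(a, b, paired = TRUE, ids_a = ids, ids_b = rev(ids))
  ref <- stats::t.test(a, b[match(ids, rev(ids))], paired = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$df, 3)

  expect_error(welch_t(a, b, paired = TRUE, ids_a = ids,
                       ids_b = c("t1", "t2", "t3", "t9")), "t9")
  expect_error(welch_t(a, b[1:3], paired = TRUE), "equal-length")
})

test_that("one-way ANOVA matches stats::anova and guards zero within-variance", {
  r <- oneway_anova(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(12)
  g <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))
  r <- oneway_anova(g)
  ref <- stats::anova(stats::lm(unlist(g) ~ rep(names(g), lengths(g))))
  expect_equal(r$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(r$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_identical(r$df, "2,21")

  # within-group SS exactly zero while means differ: divergent F
  r <- oneway_anova(list(a = c(0, 0), b = c(1, 1), c = c(2, 2)))
  expect_identical(r$statistic, Inf)
  expect_equal(r$p_value, 0)

  expect_error(oneway_anova(list(a = 1:3)), "2 group")
  expect_error(oneway_anova(list(a = 1:3, b = 2)), "2 observations")
})

test_that("fitted lines converge to truth as noise shrinks", {
  sds <- c(0.5, 0.05, 0.005)
  err <- vapply(sds, function(s) {
    cfg <- isotope_sim_config(true_p = 0.8, delta15N_frac = 1.61,
                              source_sds = c(leaves = s, larvae = s),
                              consumer_sd = s,
                              n_per_role = c(consumer = 17, leaves = 47,
                                             larvae = 20),
                              seed = 101)
    d <- generate_isotope_dataset(cfg)
    nline <- fit_mixing_line(d, "N")
    true_line <- mixing_line(0.8 * 2.13 + 0.2 * 4.12 + 1.61, 2.13, 4.12, "N")
    abs(nline$intercept - true_line$intercept) +
      abs(nline$slope - true_line$slope)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})
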