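test_that("generated feature tables respect class fractions, ranges and determinism", {
  cfg <- small_amp_cfg(seed = 7)
  t1 <- generate_feature_table(cfg)
  t2 <- generate_feature_table(small_amp_cfg(seed = 7))

  # determinism for a fixed seed
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$metadata, t2$metadata)

  # aphytophagous point mass at 0: zero chloroplast reads, every sample
  prev <- chloroplast_proportions(t1)
  expect_true(all(prev$proportion[prev$diet_class == "aphytophagous"] == 0))

  # library sizes inside the configured range
  lib <- library_sizes(t1)
  expect_true(all(lib >= 2000 & lib <= 5000))

  # degenerate range pins every library size
  t3 <- generate_feature_table(
    amplicon_sim_config(n_samples_per_class = 3,
                        library_size_range = c(500, 500),
                        n_otus = 10, seed = 3))
  expect_true(all(library_sizes(t3) == 500))
})

test_that("read conservation holds: chloroplast + bacterial + non-bacterial = library", {
  t <- generate_feature_table(small_amp_cfg(seed = 11))
  chl <- vapply(t$taxonomy, function(l) is_chloroplast(parse_lineage(l)),
                logical(1))
  bact <- vapply(t$taxonomy, function(l) is_bacterial(parse_lineage(l)),
                 logical(1))
  pools <- colSums(t$counts[chl, , drop = FALSE]) +
    colSums(t$counts[bact & !chl, , drop = FALSE]) +
    colSums(t$counts[!bact, , drop = FALSE])
  expect_identical(unname(pools), unname(library_sizes(t)))
})

test_that("per-sample substreams are stable when a class is enlarged", {
  small <- generate_feature_table(small_amp_cfg(seed = 5))
  big <- generate_feature_table(
    amplicon_sim_config(n_samples_per_class = 6,
                        library_size_range = c(2000, 5000),
                        n_otus = 30, seed = 5))
  shared <- colnames(small$counts)
  expect_identical(big$counts[, shared], small$counts)
})

test_that("invalid simulation configs name the offending field", {
  expect_error(amplicon_sim_config(library_size_range = c(10, 5)),
               "library_size_range")
  expect_error(amplicon_sim_config(n_otus = 1), "n_otus")
  expect_error(
    amplicon_sim_config(chl_fraction_dist = list(
      phytophagous = list(kind = "beta", shape1 = -1, shape2 = 1))),
    "chl_fraction_dist")
  expect_error(dist_point(1.5), "distribution")
  expect_error(isotope_sim_config(true_p = 1.2), "true_p")
  expect_error(isotope_sim_config(consumer_sd = -1), "sds")
})

test_that("noise-free isotope data hit the mixing-model mean exactly", {
  cfg <- isotope_sim_config(true_p = 1, true_q = 1,
                            delta15N_frac = 1.61, delta13C_frac = 2.8,
                            source_sds = c(leaves = 0, larvae = 0),
                            consumer_sd = 0,
                            n_per_role = c(consumer = 5, leaves = 5,
                                           larvae = 5), seed = 1)
  d <- generate_isotope_dataset(cfg)
  expect_equal(d$d15N[d$role == "consumer"], rep(2.13 + 1.61, 5))
  expect_equal(d$d13C[d$role == "consumer"], rep(-28.3 + 2.8, 5))

  # identity case: p = 0 and zero discrimination collapse onto the second
  # source mean
  cfg0 <- isotope_sim_config(true_p = 0, true_q = 0,
                             delta15N_frac = 0, delta13C_frac = 0,
                             source_sds = c(leaves = 0, larvae = 0),
                             consumer_sd = 0,
                             n_per_role = c(consumer = 3, leaves = 1,
                                            larvae = 1), seed = 1)
  d0 <- generate_isotope_dataset(cfg0)
  expect_equal(d0$d15N[d0$role == "consumer"], rep(4.12, 3))
})

test_that("a role with n = 0 yields no rows and no error", {
  cfg <- isotope_sim_config(n_per_role = c(consumer = 4, leaves = 0,
                                           larvae = 2), seed = 2)
  d <- generate_isotope_dataset(cfg)
  expect_identical(sum(d$role == "leaves"), 0L)
  expect_identical(sum(d$role == "consumer"), 4L)
})

test_that("analytic round trip recovers true_p through the fitted line", {
  cfg <- isotope_sim_config(true_p = 0.37, true_q = 0.81,
                            delta15N_frac = 2.2, delta13C_frac = 1.1,
                            source_sds = c(leaves = 0, larvae = 0),
                            consumer_sd = 0,
                            n_per_role = c(consumer = 6, leaves = 6,
                                           larvae = 6), seed = 4)
  d <- generate_isotope_dataset(cfg)
  nline <- fit_mixing_line(d, "N")
  cline <- fit_mixing_line(d, "C")
  expect_equal(as.numeric(fraction_at(nline, 2.2)), 0.37, tolerance = 1e-12)
  expect_equal(as.numeric(fraction_at(cline, 1.1)), 0.81, tolerance = 1e-12)
})

test_that("with many samples the estimated fraction lands near truth", {
  cfg <- isotope_sim_config(true_p = 0.6,
                            delta15N_frac = 1.5,
                            n_per_role = c(consumer = 10000, leaves = 10000,
                                           larvae = 10000), seed = 21)
  d <- generate_isotope_dataset(cfg)
  nline <- fit_mixing_line(d, "N")
  p_hat <- as.numeric(fraction_at(nline, 1.5))
  # delta-method se of the fraction estimate at the true discrimination
  se <- sqrt(nline$intercept_se^2 + (1.5 * nline$slope_se)^2)
  expect_lt(abs(p_hat - 0.6), 3 * se)

  gm <- group_means(d, "leaves")
  expect_lt(abs(gm$mean_d15N - 2.13), 0.02)
})

test_that("feature-table and isotope writers round-trip through disk", {
  t <- generate_feature_table(small_amp_cfg(seed = 9))
  prefix <- file.path(tempdir(), "roundtrip")
  write_feature_table(t, prefix)
  t2 <- read_feature_table(prefix)
  expect_identical(t$counts, t2$counts)
  expect_identical(unname(t$taxonomy), unname(t2$taxonomy))
  expect_identical(t$metadata, t2$metadata)

  iso <- generate_isotope_dataset(isotope_sim_config(seed = 9))
  path <- file.path(tempdir(), "iso.csv")
  write_isotope_csv(iso, path)
  iso2 <- read_isotope_csv(path)
  expect_equal(iso$d15N, iso2$d15N)
  expect_identical(iso$role, iso2$role)
})
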