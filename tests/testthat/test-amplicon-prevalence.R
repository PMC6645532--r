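test_that("lineage parsing strips rank prefixes and keeps rank order", {
  expect_identical(
    parse_lineage("k__Bacteria; p__Cyanobacteria; c__Chloroplast"),
    c("Bacteria", "Cyanobacteria", "Chloroplast"))
  expect_identical(parse_lineage("k__Bacteria"), "Bacteria")
  expect_identical(parse_lineage("Unassigned"), "Unassigned")
  # empty ranks survive as empty tokens
  expect_identical(parse_lineage("k__Bacteria; p__; c__Bacilli"),
                   c("Bacteria", "", "Bacilli"))
})

test_that("chloroplast and domain predicates follow the token rules", {
  expect_true(is_chloroplast(c("Bacteria", "Cyanobacteria", "Chloroplast")))
  expect_false(is_chloroplast(c("Bacteria", "Firmicutes", "Bacilli")))
  expect_true(is_chloroplast(c("bacteria", "cyanobacteria", "chloroplast",
                               "streptophyta")))
  expect_false(is_bacterial(c("Archaea", "Euryarchaeota")))
  expect_true(is_bacterial(c("Bacteria", "Cyanobacteria", "Chloroplast")))
  expect_false(is_bacterial("Unassigned"))
  expect_true(is_mitochondrial(c("Bacteria", "Proteobacteria",
                                 "Alphaproteobacteria", "Rickettsiales",
                                 "mitochondria")))
})

test_that("the five filter steps reproduce hand-derived outputs", {
  # documented toy table: all OTUs clear every threshold, including
  # otu2's single read in s1 (1 / 601 > 0.01% of the library)
  out <- filter_feature_table(toy_table(), filter_spec())
  expect_identical(out$counts, toy_table()$counts)

  # an OTU with 9 reads overall is below the 10-read floor
  t <- toy_table()
  t$counts["otu3", ] <- c(4L, 5L)
  out <- filter_feature_table(t, filter_spec())
  expect_false("otu3" %in% rownames(out$counts))

  # a sample left under 500 reads after OTU filters is excluded
  t <- toy_table()
  t$counts[, "s1"] <- c(450L, 49L, 0L)
  out <- filter_feature_table(t, filter_spec())
  expect_false("s1" %in% colnames(out$counts))
  expect_false("s1" %in% out$metadata$sample_id)

  # non-bacterial OTUs leave before any count-based rule
  t <- toy_table()
  t$taxonomy["otu1"] <- "k__Archaea; p__Euryarchaeota"
  out <- filter_feature_table(t, filter_spec())
  expect_false("otu1" %in% rownames(out$counts))

  # the per-sample floor zeroes small counts against post-step-2 totals:
  # 2 reads of otu2 in a 30,000-read sample sit under 0.01%
  counts <- matrix(c(20000L, 600L,
                     2L, 800L,
                     9998L, 0L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  t <- feature_table(counts, toy_table()$taxonomy, toy_table()$metadata)
  out <- filter_feature_table(t, filter_spec())
  expect_identical(out$counts["otu2", "s1"], 0L)
  expect_identical(out$counts["otu2", "s2"], 800L)
})

test_that("the global reading of the abundance floor drops whole OTUs", {
  counts <- matrix(c(20000L, 30000L,
                     2L, 2L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
  t <- feature_table(counts, toy_table()$taxonomy[1:2],
                     toy_table()$metadata)
  out <- filter_feature_table(
    t, filter_spec(fraction_rule = "global", min_otu_total = 1))
  expect_false("otu2" %in% rownames(out$counts))
})

test_that("filtering is idempotent and monotone on random synthetic tables", {
  for (seed in 1:8) {
    t <- generate_feature_table(small_amp_cfg(seed = seed))
    s <- filter_spec(min_library_size = 100)
    once <- filter_feature_table(t, s)
    twice <- filter_feature_table(once, s)
    expect_identical(once$counts, twice$counts)

    # stricter thresholds never retain more
    stricter <- filter_feature_table(
      t, filter_spec(min_otu_total = 50, min_library_size = 1000))
    expect_lte(nrow(stricter$counts), nrow(once$counts))
    expect_lte(ncol(stricter$counts), ncol(once$counts))
  }
})

test_that("an all-filtered table warns and returns empty", {
  t <- toy_table()
  expect_warning(out <- filter_feature_table(
    t, filter_spec(min_library_size = 10^6)), "empty")
  expect_identical(ncol(out$counts), 0L)
})

test_that("chloroplast proportions are exact ratios with metadata attached", {
  counts <- matrix(c(0L, 700L, 584L,
                     1200L, 0L, 416L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("chl", "bact"), c("a", "b", "c")))
  t <- feature_table(
    counts,
    taxonomy = c(chl = "k__Bacteria; p__Cyanobacteria; c__Chloroplast",
                 bact = "k__Bacteria; p__Firmicutes; c__Bacilli"),
    metadata = data.frame(sample_id = c("a", "b", "c"), species = "sp",
                          tissue_type = "gut",
                          diet_class = c("aphytophagous", "phytophagous",
                                         "unknown"),
                          stringsAsFactors = FALSE))
  prev <- chloroplast_proportions(t)
  expect_equal(prev$proportion, c(0, 1, 0.584))
  expect_identical(prev$chloroplast_reads + (prev$total_reads -
                     prev$chloroplast_reads), prev$total_reads)
  expect_identical(prev$diet_class,
                   c("aphytophagous", "phytophagous", "unknown"))
  expect_true(all(prev$proportion >= 0 & prev$proportion <= 1))
})

test_that("proportions on filtered synthetic tables stay in [0,1] and zero for aphytophagous", {
  t <- generate_feature_table(small_amp_cfg(seed = 31))
  f <- filter_feature_table(t, filter_spec(min_library_size = 100))
  prev <- chloroplast_proportions(f)
  expect_true(all(prev$proportion >= 0 & prev$proportion <= 1))
  expect_true(all(prev$proportion[prev$diet_class == "aphytophagous"] == 0))
})

test_that("BIOM-JSON tables read back equal to the TSV representation", {
  t <- generate_feature_table(small_amp_cfg(seed = 13))
  b <- biomformat::make_biom(
    t$counts,
    observation_metadata = data.frame(taxonomy = unname(t$taxonomy),
                                      row.names = rownames(t$counts)))
  path <- file.path(tempdir(), "table.biom")
  biomformat::write_biom(b, path)
  t2 <- read_biom_feature_table(path, metadata = t$metadata)
  expect_equal(unname(t2$counts[rownames(t$counts), colnames(t$counts)]),
               unname(t$counts))
  expect_true(is_chloroplast(parse_lineage(t2$taxonomy[["chl_001"]])))
})
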