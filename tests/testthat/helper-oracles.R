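# Independent oracles, kept free of the package's implementation paths.

# Exact two-sided rank-sum p by brute-force enumeration of all
# C(n1 + n2, n1) assignments of ranks to group 1 (tie-free data only).
brute_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(!any(duplicated(c(x, y))))
  r <- rank(c(x, y))
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(seq_len(n1 + n2)[combs], nrow = n1)) -
    n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= obs_u), mean(us >= obs_u)))
}

# Kruskal-Wallis H from the rank-sum definition, with midranks and the
# standard tie correction.
hand_kruskal_H <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Toy feature table used in the filtering contract: 3 OTUs x 2 samples,
# counts [[600, 0], [1, 10000], [0, 400]], all bacterial-domain.
toy_table <- function() {
  counts <- matrix(c(600L, 0L,
                     1L, 10000L,
                     0L, 400L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  feature_table(
    counts,
    taxonomy = c(
      otu1 = "k__Bacteria; p__Firmicutes; c__Bacilli",
      otu2 = "k__Bacteria; p__Cyanobacteria; c__Chloroplast",
      otu3 = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria"
    ),
    metadata = data.frame(
      sample_id = c("s1", "s2"),
      species = "sp", tissue_type = "gut", diet_class = "unknown",
      stringsAsFactors = FALSE
    )
  )
}

# Small simulated amplicon config for fast property checks.
small_amp_cfg <- function(seed = 1L, ...) {
  amplicon_sim_config(n_samples_per_class = 4,
                      library_size_range = c(2000, 5000),
                      n_otus = 30, seed = seed, ...)
}
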