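#' Configuration for simulated amplicon feature tables
#'
#' Describes the statistical structure of a simulated gut-content 16S
#' dataset: diet classes, per-class distributions of the true chloroplast
#' read fraction, library sizes, and the OTU pool. Defaults emulate a
#' small multi-species gut metabarcoding study: libraries of 15,000-47,000
#' reads; chloroplast fractions broadly spread over (0, 1) for
#' plant-feeding (and unknown-diet) classes, modelled as Beta(1.2, 0.9);
#' and exactly zero for non-plant-feeding classes (point mass at 0).
#'
#' @param n_samples_per_class Integer, samples drawn for each diet class.
#' @param diet_classes Character vector drawn from
#'   `"phytophagous"`, `"aphytophagous"`, `"unknown"`.
#' @param chl_fraction_dist Named list (one entry per diet class) of
#'   distribution specs for the true chloroplast fraction, each created by
#'   [dist_point()], [dist_uniform()] or [dist_beta()]. Classes without an
#'   entry get the defaults above.
#' @param library_size_range Integer pair `(low, high)`; per-sample library
#'   sizes are drawn uniformly on this range. Default `c(15000, 47000)`.
#' @param n_otus Total OTUs in the chloroplast + bacterial pools (split
#'   roughly 1:4); must be at least 2.
#' @param n_non_bacterial_otus Extra OTUs outside the bacterial domain
#'   (Archaea, Unassigned) included to exercise domain filtering.
#' @param rare_otu_rate Fraction of bacterial OTUs given abundances so low
#'   their expected table-wide total falls below the default
#'   10-read OTU filter.
#' @param non_bacterial_rate Expected fraction of each library assigned to
#'   the non-bacterial pool.
#' @param prop_whole Expected fraction of samples recorded as whole-body
#'   (`tissue_type "whole"`) rather than dissected gut.
#' @param seed Integer seed; one global seed governs all draws, with
#'   per-sample substreams derived deterministically so enlarging a class
#'   does not reshuffle previously generated samples.
#' @return An object of class `amplicon_sim_config`.
#' @export
amplicon_sim_config <- function(n_samples_per_class = 8,
                                diet_classes = c("phytophagous",
                                                 "aphytophagous",
                                                 "unknown"),
                                chl_fraction_dist = list(),
                                library_size_range = c(15000, 47000),
                                n_otus = 60,
                                n_non_bacterial_otus = 3,
                                rare_otu_rate = 0.1,
                                non_bacterial_rate = 0.005,
                                prop_whole = 0.15,
                                seed = 1L) {
  known <- c("phytophagous", "aphytophagous", "unknown")
  bad <- setdiff(diet_classes, known)
  if (length(bad) > 0) {
    stop("unknown diet_classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(library_size_range) != 2 || library_size_range[1] < 1 ||
      library_size_range[1] > library_size_range[2]) {
    stop("`library_size_range` must be an increasing pair with low >= 1",
         call. = FALSE)
  }
  if (n_otus < 2) stop("`n_otus` must be >= 2", call. = FALSE)
  if (rare_otu_rate < 0 || rare_otu_rate > 1 ||
      non_bacterial_rate < 0 || non_bacterial_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  defaults <- list(
    phytophagous = dist_beta(1.2, 0.9),
    aphytophagous = dist_point(0),
    unknown = dist_beta(1.2, 0.9)
  )
  for (cl in diet_classes) {
    if (is.null(chl_fraction_dist[[cl]])) {
      chl_fraction_dist[[cl]] <- defaults[[cl]]
    } else {
      validate_dist(chl_fraction_dist[[cl]], paste0("chl_fraction_dist$", cl))
    }
  }
  structure(
    list(n_samples_per_class = as.integer(n_samples_per_class),
         diet_classes = diet_classes,
         chl_fraction_dist = chl_fraction_dist,
         library_size_range = as.integer(library_size_range),
         n_otus = as.integer(n_otus),
         n_non_bacterial_otus = as.integer(n_non_bacterial_otus),
         rare_otu_rate = rare_otu_rate,
         non_bacterial_rate = non_bacterial_rate,
         prop_whole = prop_whole,
         seed = as.integer(seed)),
    class = "amplicon_sim_config"
  )
}

#' Distribution specs for the true chloroplast fraction
#'
#' `dist_point(value)` is a point mass (e.g. exactly 0 chloroplast reads
#' for non-plant-feeders); `dist_uniform(min, max)` and
#' `dist_beta(shape1, shape2)` give spread over \[0, 1\].
#'
#' @param value,min,max,shape1,shape2 Distribution parameters; fractions
#'   must lie in \[0, 1\] and Beta shapes must be positive.
#' @return A list with a `kind` tag, used in
#'   [amplicon_sim_config()]`$chl_fraction_dist`.
#' @name fraction_dist
NULL

#' @rdname fraction_dist
#' @export
dist_point <- function(value) {
  validate_dist(structure(list(kind = "point", value = value)))
}

#' @rdname fraction_dist
#' @export
dist_uniform <- function(min = 0, max = 1) {
  validate_dist(structure(list(kind = "uniform", min = min, max = max)))
}

#' @rdname fraction_dist
#' @export
dist_beta <- function(shape1, shape2) {
  validate_dist(structure(list(kind = "beta", shape1 = shape1,
                               shape2 = shape2)))
}

validate_dist <- function(d, field = "chl_fraction_dist") {
  ok <- is.list(d) && !is.null(d$kind) && switch(
    d$kind,
    point = !is.null(d$value) && d$value >= 0 && d$value <= 1,
    uniform = !is.null(d$min) && !is.null(d$max) &&
      d$min >= 0 && d$max <= 1 && d$min <= d$max,
    beta = !is.null(d$shape1) && !is.null(d$shape2) &&
      d$shape1 > 0 && d$shape2 > 0,
    FALSE
  )
  if (!isTRUE(ok)) {
    stop("invalid distribution spec in `", field, "`", call. = FALSE)
  }
  d
}

draw_fraction <- function(d) {
  switch(d$kind,
         point = d$value,
         uniform = stats::runif(1, d$min, d$max),
         beta = stats::rbeta(1, d$shape1, d$shape2))
}

#' Generate a synthetic amplicon feature table
#'
#' Simulates a gut-content 16S feature table with the structure the
#' chloroplast-prevalence analysis assumes. For each sample: a library size
#' is drawn uniformly on the configured range; a small non-bacterial read
#' count is drawn binomially; the remaining reads are split between the
#' chloroplast and bacterial OTU pools by a binomial draw around the
#' sample's class-specific true chloroplast fraction; reads are then spread
#' across the OTUs of each pool multinomially with table-wide Dirichlet
#' weights. A configured fraction of bacterial OTUs is made rare (expected
#' table-wide total below the default 10-read filter). Chloroplast OTUs
#' are labelled at the class rank under Cyanobacteria; non-bacterial OTUs
#' alternate between Archaea and Unassigned lineages.
#'
#' Per-sample random substreams are seeded deterministically from the
#' global seed, the diet-class index and the within-class index, so the
#' same sample is identical across runs and across enlargements of other
#' classes.
#'
#' @param cfg An [amplicon_sim_config()].
#' @return A [feature_table()].
#' @export
generate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "amplicon_sim_config"))

  n_chl <- max(1L, round(cfg$n_otus / 5))
  n_bact <- cfg$n_otus - n_chl
  otu_ids <- c(sprintf("chl_%03d", seq_len(n_chl)),
               sprintf("bact_%03d", seq_len(n_bact)),
               if (cfg$n_non_bacterial_otus > 0)
                 sprintf("nonbact_%03d", seq_len(cfg$n_non_bacterial_otus)))
  taxonomy <- c(
    stats::setNames(rep(paste0("k__Bacteria; p__Cyanobacteria; ",
                               "c__Chloroplast; o__Streptophyta; f__; g__; s__"),
                        n_chl), otu_ids[seq_len(n_chl)]),
    stats::setNames(bacterial_lineages(n_bact),
                    otu_ids[n_chl + seq_len(n_bact)])
  )
  if (cfg$n_non_bacterial_otus > 0) {
    nb_ids <- otu_ids[cfg$n_otus + seq_len(cfg$n_non_bacterial_otus)]
    nb_lin <- rep(c("k__Archaea; p__Euryarchaeota; c__; o__; f__; g__; s__",
                    "Unassigned"),
                  length.out = cfg$n_non_bacterial_otus)
    taxonomy <- c(taxonomy, stats::setNames(nb_lin, nb_ids))
  }

  # table-wide OTU weights (one stream, seeded from the global seed)
  set.seed(cfg$seed %% .Machine$integer.max)
  w_chl <- stats::rgamma(n_chl, shape = 1)
  w_chl <- w_chl / sum(w_chl)
  w_bact <- stats::rgamma(n_bact, shape = 1)
  n_rare <- round(cfg$rare_otu_rate * n_bact)
  # rare OTUs are pitched at ~0.3 expected reads per sample, keeping their
  # expected table-wide total below the default 10-read OTU filter for
  # tables of up to ~30 samples; calibrated per sample (not per table) so
  # enlarging a class cannot reshuffle the weights of existing samples
  if (n_rare > 0 && n_rare < n_bact) {
    rare_idx <- seq_len(n_rare)
    w_bact <- w_bact / sum(w_bact)
    w_bact[rare_idx] <- 0.3 / (mean(cfg$library_size_range) * 0.5)
  }
  w_bact <- w_bact / sum(w_bact)
  w_nb <- if (cfg$n_non_bacterial_otus > 0) {
    x <- stats::rgamma(cfg$n_non_bacterial_otus, shape = 1)
    x / sum(x)
  } else {
    numeric(0)
  }

  counts <- matrix(0L, nrow = length(otu_ids), ncol = 0,
                   dimnames = list(otu_ids, NULL))
  meta <- list()
  for (ci in seq_along(cfg$diet_classes)) {
    cl <- cfg$diet_classes[ci]
    dist <- cfg$chl_fraction_dist[[cl]]
    for (i in seq_len(cfg$n_samples_per_class)) {
      # per-sample substream: stable under enlargement of other classes
      set.seed((cfg$seed + 1000000L * ci + i) %% .Machine$integer.max)
      lib <- if (cfg$library_size_range[1] == cfg$library_size_range[2]) {
        cfg$library_size_range[1]
      } else {
        sample(cfg$library_size_range[1]:cfg$library_size_range[2], 1L)
      }
      f <- draw_fraction(dist)
      n_nb <- if (cfg$n_non_bacterial_otus > 0) {
        stats::rbinom(1, lib, cfg$non_bacterial_rate)
      } else 0L
      n_chl_reads <- stats::rbinom(1, lib - n_nb, f)
      n_bact_reads <- lib - n_nb - n_chl_reads
      col <- c(
        as.integer(stats::rmultinom(1, n_chl_reads, w_chl)),
        as.integer(stats::rmultinom(1, n_bact_reads, w_bact)),
        if (cfg$n_non_bacterial_otus > 0)
          as.integer(stats::rmultinom(1, n_nb, w_nb))
      )
      sid <- sprintf("%s_%02d", cl, i)
      counts <- cbind(counts, col)
      colnames(counts)[ncol(counts)] <- sid
      meta[[sid]] <- data.frame(
        sample_id = sid,
        species = sprintf("sim_species_%s", toupper(substr(cl, 1, 1))),
        tissue_type = if (stats::runif(1) < cfg$prop_whole) "whole" else "gut",
        diet_class = cl,
        stringsAsFactors = FALSE
      )
    }
  }
  feature_table(counts, taxonomy, do.call(rbind, meta))
}

bacterial_lineages <- function(n) {
  templates <- c(
    "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__; s__",
    "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__; g__; s__",
    "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; f__; g__; s__",
    "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__; g__; s__",
    "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__; g__Wolbachia; s__"
  )
  rep(templates, length.out = n)
}
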