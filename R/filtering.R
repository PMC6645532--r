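#' Feature-table filter specification
#'
#' Quality filters applied to an amplicon feature table before computing
#' per-sample chloroplast proportions. Defaults mirror standard gut-content
#' metabarcoding practice: drop non-bacterial OTUs, drop OTUs with fewer
#' than 10 reads overall, zero per-sample counts below 0.01% of that
#' sample's library, and exclude samples left with fewer than 500 reads.
#'
#' @param min_otu_total Minimum total reads across all samples for an OTU
#'   to be retained (strict: totals *below* this are dropped). Default 10.
#' @param min_sample_fraction Per-sample relative-abundance floor; counts
#'   strictly below `min_sample_fraction * library size` are zeroed.
#'   Default `1e-4` (0.01%).
#' @param min_library_size Minimum post-filter library size for a sample to
#'   be retained (strict). Default 500.
#' @param drop_non_bacterial Drop OTUs whose domain rank is not Bacteria
#'   (Archaea, Unassigned, ...). Chloroplast OTUs are bacterial-domain and
#'   are retained. Default `TRUE`.
#' @param drop_mitochondrial Drop mitochondrial OTUs entirely. They are
#'   bacterial-domain organellar reads but carry no plant-diet signal;
#'   off by default so the default filter matches the bacterial-domain rule
#'   alone. Default `FALSE`.
#' @param fraction_rule How the relative-abundance floor is applied:
#'   `"per_sample"` (default) zeroes individual counts below the floor;
#'   `"global"` instead drops an OTU from the whole table when it exceeds
#'   the floor in no sample. The per-sample reading is the package default;
#'   the global reading is provided because the rule's scope is a known
#'   ambiguity in how such filters are described.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_otu_total = 10,
                        min_sample_fraction = 1e-4,
                        min_library_size = 500,
                        drop_non_bacterial = TRUE,
                        drop_mitochondrial = FALSE,
                        fraction_rule = c("per_sample", "global")) {
  fraction_rule <- match.arg(fraction_rule)
  if (min_otu_total < 0 || min_sample_fraction < 0 || min_library_size < 0) {
    stop("filter thresholds must be >= 0", call. = FALSE)
  }
  if (min_sample_fraction >= 1) {
    stop("`min_sample_fraction` must be < 1", call. = FALSE)
  }
  structure(
    list(min_otu_total = min_otu_total,
         min_sample_fraction = min_sample_fraction,
         min_library_size = min_library_size,
         drop_non_bacterial = drop_non_bacterial,
         drop_mitochondrial = drop_mitochondrial,
         fraction_rule = fraction_rule),
    class = "filter_spec"
  )
}

#' Filter a feature table
#'
#' Applies the quality filters of a [filter_spec()] in a fixed, documented
#' order:
#'
#' 1. drop OTUs whose domain is non-bacterial (if enabled), and
#'    mitochondrial OTUs (if enabled);
#' 2. drop OTUs with total count across all samples below `min_otu_total`;
#' 3. zero, per sample, any count strictly below
#'    `min_sample_fraction` times that sample's library total as it stands
#'    after steps 1-2 (or, under the `"global"` rule, drop OTUs below the
#'    floor in every sample);
#' 4. drop OTUs whose counts are now all zero;
#' 5. drop samples whose remaining total is below `min_library_size`.
#'
#' The input is not modified; a new table is returned. A table left empty
#' by filtering is returned empty with a warning rather than an error.
#'
#' @param table A [feature_table()].
#' @param spec A [filter_spec()]; defaults to `filter_spec()`.
#' @return A filtered [feature_table()].
#' @export
filter_feature_table <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "filter_spec"))
  counts <- table$counts
  taxonomy <- table$taxonomy

  # step 1: domain / organelle filters
  if (spec$drop_non_bacterial || spec$drop_mitochondrial) {
    keep <- vapply(taxonomy, function(l) {
      tok <- parse_lineage(l)
      ok <- TRUE
      if (spec$drop_non_bacterial) ok <- is_bacterial(tok)
      if (ok && spec$drop_mitochondrial) ok <- !is_mitochondrial(tok)
      ok
    }, logical(1))
    counts <- counts[keep, , drop = FALSE]
  }

  # step 2: overall OTU abundance
  counts <- counts[rowSums(counts) >= spec$min_otu_total, , drop = FALSE]

  # step 3: per-sample relative-abundance floor, against the library totals
  # as they stand after steps 1-2
  if (spec$min_sample_fraction > 0 && nrow(counts) > 0 && ncol(counts) > 0) {
    lib <- colSums(counts)
    floor_per_sample <- spec$min_sample_fraction * lib
    below <- sweep(counts, 2L, floor_per_sample, `<`)
    if (spec$fraction_rule == "per_sample") {
      counts[below] <- 0L
    } else {
      counts <- counts[rowSums(!below & counts > 0) > 0, , drop = FALSE]
    }
  }

  # step 4: OTUs emptied by step 3
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]

  # step 5: sample depth
  counts <- counts[, colSums(counts) >= spec$min_library_size, drop = FALSE]

  if (nrow(counts) == 0 || ncol(counts) == 0) {
    warning("filtering left an empty feature table", call. = FALSE)
  }
  metadata <- table$metadata[table$metadata$sample_id %in% colnames(counts), ,
                             drop = FALSE]
  structure(
    list(counts = counts,
         taxonomy = taxonomy[rownames(counts)],
         metadata = metadata),
    class = "feature_table"
  )
}
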