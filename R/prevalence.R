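#' Per-sample chloroplast read proportions
#'
#' For each sample of an (already filtered) feature table, computes the
#' proportion of reads assigned to chloroplast OTUs out of all retained
#' reads — the diet signal at the heart of the chloroplast-prevalence
#' analysis. Mitochondrial OTUs, if retained, count toward the denominator
#' but never the numerator.
#'
#' @param table A [feature_table()], normally the output of
#'   [filter_feature_table()].
#' @return A data frame of class `prevalence_result` with columns
#'   `sample_id`, `chloroplast_reads`, `total_reads`, `proportion`,
#'   `species`, `tissue_type`, `diet_class`. Samples with zero total reads
#'   (impossible after filtering, possible on raw input) are excluded with
#'   a warning.
#' @export
chloroplast_proportions <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  chl <- vapply(table$taxonomy, function(l) is_chloroplast(parse_lineage(l)),
                logical(1))
  total <- colSums(table$counts)
  chl_reads <- if (any(chl)) {
    colSums(table$counts[chl, , drop = FALSE])
  } else {
    stats::setNames(rep(0L, ncol(table$counts)), colnames(table$counts))
  }
  keep <- total > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " sample(s) with zero total reads",
            call. = FALSE)
  }
  md <- table$metadata[match(colnames(table$counts)[keep],
                             table$metadata$sample_id), , drop = FALSE]
  out <- data.frame(
    sample_id = colnames(table$counts)[keep],
    chloroplast_reads = as.integer(chl_reads[keep]),
    total_reads = as.integer(total[keep]),
    proportion = unname(chl_reads[keep] / total[keep]),
    species = md$species,
    tissue_type = md$tissue_type,
    diet_class = md$diet_class,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("prevalence_result", "data.frame")
  out
}
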