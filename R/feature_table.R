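#' Construct a feature table
#'
#' Bundles an OTU-by-sample count matrix with per-OTU taxonomy lineages and
#' per-sample metadata — the object the 16S gut-content analysis filters and
#' summarizes. Counts are non-negative integers; every OTU must have a
#' taxonomy entry and every sample a metadata row.
#'
#' @param counts Non-negative integer matrix, rows = OTUs, columns = samples,
#'   with row and column names.
#' @param taxonomy Named character vector mapping `otu_id` to a ranked
#'   lineage string (Greengenes style, possibly truncated).
#' @param metadata Data frame with columns `sample_id`, `species`,
#'   `tissue_type` (one of `"gut"`, `"whole"`) and `diet_class` (one of
#'   `"phytophagous"`, `"aphytophagous"`, `"unknown"`).
#' @return An object of class `feature_table`: a list with elements
#'   `counts`, `taxonomy`, `metadata`.
#' @export
feature_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have OTU rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  missing_tax <- setdiff(rownames(counts), names(taxonomy))
  if (length(missing_tax) > 0) {
    stop("OTUs without taxonomy: ", paste(missing_tax, collapse = ", "),
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    stop("`metadata` must have a sample_id column", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(counts = counts,
         taxonomy = taxonomy[rownames(counts)],
         metadata = metadata),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  total reads:", sum(x$counts), "\n")
  if ("diet_class" %in% names(x$metadata)) {
    tab <- table(x$metadata$diet_class)
    cat("  diet classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Library sizes of a feature table
#'
#' @param table A [feature_table()].
#' @return Named integer vector of per-sample read totals.
#' @export
library_sizes <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  colSums(table$counts)
}

#' Write a feature table as a TSV trio
#'
#' Writes the count matrix (`<prefix>_counts.tsv`, first column `otu_id`,
#' one column per sample), the taxonomy map (`<prefix>_taxonomy.tsv`:
#' `otu_id <tab> lineage`) and the sample metadata
#' (`<prefix>_metadata.tsv`). Plain text, readable by
#' [read_feature_table()].
#'
#' @param table A [feature_table()].
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_feature_table <- function(table, prefix) {
  stopifnot(inherits(table, "feature_table"))
  paths <- paste0(prefix, c("_counts.tsv", "_taxonomy.tsv", "_metadata.tsv"))
  counts_df <- data.frame(otu_id = rownames(table$counts),
                          table$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tax_df <- data.frame(otu_id = names(table$taxonomy),
                       lineage = unname(table$taxonomy),
                       stringsAsFactors = FALSE)
  utils::write.table(tax_df, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(prefix) {
  paths <- paste0(prefix, c("_counts.tsv", "_taxonomy.tsv", "_metadata.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing feature-table files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts_df <- utils::read.delim(paths[1], check.names = FALSE,
                                 stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  tax_df <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  taxonomy <- stats::setNames(tax_df$lineage, tax_df$otu_id)
  metadata <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  feature_table(counts, taxonomy, metadata)
}

#' Read a BIOM-JSON (format 1.0) feature table
#'
#' Interoperability reader for the BIOM format used by QIIME-era pipelines.
#' Taxonomy is taken from the per-observation `taxonomy` metadata field
#' (joined with `"; "` when stored as a list); sample metadata, if present
#' in the file, is merged with the `metadata` argument.
#'
#' @param path Path to a BIOM-JSON file.
#' @param metadata Optional data frame of per-sample metadata (columns
#'   `sample_id`, `species`, `tissue_type`, `diet_class`); required when the
#'   BIOM file carries none.
#' @return A [feature_table()].
#' @export
read_biom_feature_table <- function(path, metadata = NULL) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the biomformat package is required to read BIOM files",
         call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b))
  obs <- biomformat::observation_metadata(b)
  if (is.null(obs)) {
    stop("BIOM file carries no observation (taxonomy) metadata", call. = FALSE)
  }
  lineage_of <- function(m) {
    v <- if (is.list(m)) unlist(m$taxonomy %||% m) else m
    paste(as.character(v), collapse = "; ")
  }
  if (is.data.frame(obs)) {
    taxonomy <- apply(obs, 1L, function(r) paste(r, collapse = "; "))
  } else {
    taxonomy <- vapply(obs, lineage_of, character(1))
  }
  names(taxonomy) <- rownames(counts)
  if (is.null(metadata)) {
    sm <- biomformat::sample_metadata(b)
    if (is.null(sm)) {
      stop("no sample metadata in BIOM file; supply `metadata`",
           call. = FALSE)
    }
    metadata <- data.frame(sample_id = rownames(sm), sm,
                           stringsAsFactors = FALSE)
  }
  feature_table(round(counts), taxonomy, metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
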