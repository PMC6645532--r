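#' Parse a Greengenes-style ranked lineage string
#'
#' Splits a taxonomy lineage such as
#' `"k__Bacteria; p__Cyanobacteria; c__Chloroplast"` into its rank tokens,
#' stripping the single-letter rank prefixes (`k__`, `p__`, ...) and
#' preserving rank order. Empty ranks (a bare prefix like `"g__"`) are kept
#' as empty strings so positional rank information survives truncation.
#'
#' Input that carries no separator and no rank prefix (e.g. `"Unassigned"`)
#' is returned as a single-token lineage.
#'
#' @param lineage_string Character vector of lineage strings.
#' @return For a single input string, a character vector of rank tokens; for
#'   a vector input, a list of such vectors.
#' @examples
#' parse_lineage("k__Bacteria; p__Cyanobacteria; c__Chloroplast")
#' parse_lineage("Unassigned")
#' @export
parse_lineage <- function(lineage_string) {
  parse_one <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(character(0))
    }
    tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    sub("^[a-zA-Z]__", "", tokens)
  }
  if (length(lineage_string) == 1L) parse_one(lineage_string)
  else lapply(lineage_string, parse_one)
}

#' Is a lineage a chloroplast lineage?
#'
#' A lineage counts as chloroplast if any rank token equals `"chloroplast"`,
#' case-insensitively. Matching by token anywhere in the lineage (rather
#' than at a fixed rank) tolerates truncated lineages and the inconsistent
#' rank placement of organellar 16S in reference taxonomies.
#'
#' @param lineage Character vector of rank tokens as returned by
#'   [parse_lineage()], or a raw lineage string (parsed on the fly).
#' @return Logical flag.
#' @examples
#' is_chloroplast(c("Bacteria", "Cyanobacteria", "Chloroplast"))
#' is_chloroplast("k__Bacteria; p__Firmicutes; c__Bacilli")
#' @export
is_chloroplast <- function(lineage) {
  lineage <- as_tokens(lineage)
  any(tolower(lineage) == "chloroplast")
}

#' Is a lineage a mitochondrial lineage?
#'
#' Mitochondrial 16S co-amplifies just like plastid 16S. These reads sit in
#' the bacterial domain but are not a diet signal; [filter_feature_table()]
#' can drop them via its `drop_mitochondrial` flag. Matching is by rank
#' token (`"mitochondria"`), case-insensitive.
#'
#' @inheritParams is_chloroplast
#' @return Logical flag.
#' @export
is_mitochondrial <- function(lineage) {
  lineage <- as_tokens(lineage)
  any(tolower(lineage) == "mitochondria")
}

#' Is a lineage in the bacterial domain?
#'
#' True iff the domain (first) rank equals `"bacteria"`, case-insensitively.
#' Chloroplast and mitochondrial lineages are bacterial under this rule:
#' organellar 16S is classified inside the bacterial domain, which is what
#' lets chloroplast reads survive the non-bacterial filter and act as a
#' diet signal downstream.
#'
#' @inheritParams is_chloroplast
#' @return Logical flag; `FALSE` for empty or unassigned lineages.
#' @examples
#' is_bacterial(c("Archaea", "Euryarchaeota"))     # FALSE
#' is_bacterial(c("Bacteria", "Cyanobacteria", "Chloroplast")) # TRUE
#' @export
is_bacterial <- function(lineage) {
  lineage <- as_tokens(lineage)
  length(lineage) >= 1L && tolower(lineage[[1]]) == "bacteria"
}

# Accept either a pre-parsed token vector or a raw lineage string.
as_tokens <- function(lineage) {
  if (length(lineage) == 1L && grepl("__|;", lineage)) {
    lineage <- parse_lineage(lineage)
  }
  as.character(lineage)
}
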