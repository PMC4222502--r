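#' Gene maps
#'
#' A gene map is an ordered assignment of genes to chromosome positions for
#' one species, with optional strand, painting-segment label and provenance
#' (whether the gene was placed in the current study or taken from previous
#' mapping). Coordinates are held internally as 0-based half-open intervals;
#' readers and writers translate from/to the 1-based inclusive convention of
#' genome-browser tables.
#'
#' @param species species name.
#' @param gene character vector of unique gene identifiers.
#' @param chrom chromosome of each gene.
#' @param start,end 0-based half-open coordinates (`start < end`). `end`
#'   defaults to `start + 1` (point features, e.g. FISH band midpoints).
#' @param strand `"+"`, `"-"` or `"unknown"` (default). FISH-derived
#'   assignments are unoriented at gene level, so `"unknown"` is legitimate.
#' @param label optional painting-segment label (e.g. `"C7"`), `NA` if none.
#' @param provenance `"current_study"` or `"previous"` per record.
#' @return A `gene_map`: a data.frame with columns `gene`, `chrom`, `start`,
#'   `end`, `strand`, `label`, `provenance`, sorted by `(chrom, start)`, with
#'   attribute `species`.
#' @export
gene_map <- function(species, gene, chrom, start, end = NULL,
                     strand = NULL, label = NULL, provenance = NULL) {
  n <- length(gene)
  if (is.null(end)) end <- start + 1
  if (is.null(strand)) strand <- rep("unknown", n)
  if (is.null(label)) label <- rep(NA_character_, n)
  if (is.null(provenance)) provenance <- rep("current_study", n)
  df <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), label = as.character(label),
                   provenance = as.character(provenance),
                   stringsAsFactors = FALSE)
  validate_gene_map(df, species)
  df <- df[order(df$chrom, df$start, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, species = species, class = c("gene_map", "data.frame"))
}

validate_gene_map <- function(df, species) {
  if (anyDuplicated(df$gene)) {
    d <- unique(df$gene[duplicated(df$gene)])
    rows <- which(df$gene %in% d)
    stop("duplicate gene_id(s) in map for '", species, "': ",
         paste(d, collapse = ", "), " (rows ", paste(rows, collapse = ", "), ")")
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) stop("empty chromosome name in gene map")
  bad <- which(!(df$start < df$end))
  if (length(bad)) stop("start >= end for gene(s): ", paste(df$gene[bad], collapse = ", "))
  ok_strand <- df$strand %in% c("+", "-", "unknown")
  if (any(!ok_strand)) stop("invalid strand value(s): ",
                            paste(unique(df$strand[!ok_strand]), collapse = ", "))
  invisible(df)
}

#' @export
print.gene_map <- function(x, ...) {
  cat("gene_map:", attr(x, "species"), "-", nrow(x), "gene(s) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

map_species <- function(map) attr(map, "species")
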