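#' Read a gene map from a tab-separated file
#'
#' Expects a TSV with a header naming at least gene, chromosome and position
#' columns. Recognised column aliases: `gene`/`gene_id`, `chrom`/`chromosome`/
#' `chr`, `start`/`position`/`pos`, `end`/`stop`, `strand`, `label`/`segment`/
#' `segment_label`, `provenance`. Lines beginning with `#` are comments.
#' Input coordinates are 1-based inclusive (Ensembl convention); they are
#' normalized to the internal 0-based half-open convention, which preserves
#' interval length. A missing `end` column yields point features.
#'
#' @param path file path.
#' @param species species name; defaults to the file name without extension.
#' @param one_based are input coordinates 1-based inclusive? Default `TRUE`.
#' @return a [gene_map()].
#' @export
read_gene_map <- function(path, species = NULL, one_based = TRUE) {
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  pick <- function(aliases) {
    hit <- intersect(aliases, names(df))
    if (length(hit)) df[[hit[1L]]] else NULL
  }
  gene  <- pick(c("gene", "gene_id"))
  chrom <- pick(c("chrom", "chromosome", "chr"))
  start <- pick(c("start", "position", "pos"))
  if (is.null(gene) || is.null(chrom) || is.null(start)) {
    stop("gene map '", path, "' must name gene, chromosome and position columns")
  }
  start <- suppressWarnings(as.numeric(start))
  if (anyNA(start) || anyNA(gene) || any(!nzchar(chrom))) {
    bad <- which(is.na(start) | is.na(gene) | !nzchar(chrom))
    stop("malformed row(s) in '", path, "' at data line(s): ",
         paste(bad, collapse = ", "))
  }
  end <- pick(c("end", "stop"))
  if (!is.null(end)) end <- suppressWarnings(as.numeric(end))
  if (one_based) {
    start0 <- start - 1
    end0 <- if (is.null(end)) start else end      # inclusive end == half-open end
  } else {
    start0 <- start
    end0 <- if (is.null(end)) start + 1 else end
  }
  gene_map(species, gene = gene, chrom = chrom, start = start0, end = end0,
           strand = pick("strand"),
           label = pick(c("label", "segment", "segment_label")),
           provenance = pick("provenance"))
}

#' Write a gene map to TSV (1-based inclusive coordinates)
#'
#' Inverse of [read_gene_map()]: `read_gene_map(write_gene_map(m))` recovers
#' `m` record for record.
#'
#' @param map a [gene_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  stopifnot(inherits(map, "gene_map"))
  out <- data.frame(gene = map$gene, chromosome = map$chrom,
                    start = map$start + 1, end = map$end,
                    strand = map$strand, segment_label = map$label,
                    provenance = map$provenance, stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}

#' Read signed-genome arrangements
#'
#' One line per chromosome: species, chromosome name, then space- (or tab-)
#' separated signed markers, e.g. `dunnart chr3 C10 C12 C11`. `#` starts a
#' comment. Consecutive lines of one species are collected into one genome.
#'
#' @param path file path.
#' @return named list of [signed_genome()] objects (one per species), with
#'   attribute `alphabet` holding the union of marker names seen.
#' @export
read_arrangements <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(), alphabet = character(0)))
  }
  per_species <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "[ \t]+")[[1L]]
    if (length(tok) < 3L) {
      stop("malformed arrangement line ", i, " in '", path,
           "': need species, chromosome, >=1 marker")
    }
    sp <- tok[1L]; ch <- tok[2L]; mk <- tok[-(1:2)]
    if (!is.null(per_species[[sp]]) && ch %in% names(per_species[[sp]])) {
      stop("chromosome '", ch, "' repeated for species '", sp, "'")
    }
    per_species[[sp]] <- c(per_species[[sp]], stats::setNames(list(mk), ch))
  }
  genomes <- lapply(names(per_species), function(sp) signed_genome(sp, per_species[[sp]]))
  names(genomes) <- names(per_species)
  structure(genomes, alphabet = sort(unique(unlist(lapply(genomes, genome_markers)))))
}

#' Write signed-genome arrangements
#' @param genomes list of [signed_genome()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_arrangements <- function(genomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    stopifnot(inherits(g, "signed_genome"))
    for (nm in names(g$chromosomes)) {
      writeLines(paste(g$species, nm, paste(g$chromosomes[[nm]], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a species tree in newick format
#'
#' Thin wrapper over [ape::read.tree()] that validates the tree is rooted and
#' that required species are present as leaves.
#'
#' @param path newick file path.
#' @param species optional character vector of species that must be leaves.
#' @return an `ape` `phylo` object.
#' @export
read_species_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from '", path, "'")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!is.null(species)) {
    missing <- setdiff(species, tree$tip.label)
    if (length(missing)) {
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    }
  }
  tree
}

#' Write a summary table to TSV
#'
#' Generic writer for the pipeline's tabular stage outputs (block summaries,
#' map summaries, segment tables, ...). Tables round-trip losslessly through
#' [read_summary_table()]. An empty table yields a header-only file.
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  write_tsv_file(as.data.frame(x), path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' Chromosome identifier columns (`chromosome`, `chrom`, `chromA`, `chromB`)
#' are always read as character: chromosomes are names, not numbers, even
#' when they look numeric.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_summary_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in intersect(c("chromosome", "chrom", "chromA", "chromB"), names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}

write_tsv_file <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}
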