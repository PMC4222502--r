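#' Merge newly mapped genes with previously published assignments
#'
#' Union of two gene maps for the same species, retaining per-record
#' provenance. A gene present in both maps at the same location collapses to
#' one record with provenance `"previous"` (the earlier study takes priority
#' for attribution); a gene present at two different locations is an error.
#'
#' @param current gene map from the present study (provenance is forced to
#'   `"current_study"` for records unique to it).
#' @param previous gene map of previously published assignments (provenance
#'   forced to `"previous"`).
#' @return a merged [gene_map()].
#' @export
merge_maps <- function(current, previous) {
  stopifnot(inherits(current, "gene_map"), inherits(previous, "gene_map"))
  if (!identical(map_species(current), map_species(previous))) {
    stop("cannot merge maps of different species: '", map_species(current),
         "' vs '", map_species(previous), "'")
  }
  cur <- as.data.frame(current); prev <- as.data.frame(previous)
  cur$provenance <- rep("current_study", nrow(cur))
  prev$provenance <- rep("previous", nrow(prev))
  shared <- intersect(cur$gene, prev$gene)
  if (length(shared)) {
    a <- cur[match(shared, cur$gene), ]; b <- prev[match(shared, prev$gene), ]
    conflict <- a$chrom != b$chrom | a$start != b$start
    if (any(conflict)) {
      gs <- shared[conflict]
      detail <- paste0(gs, " (", a$chrom[conflict], ":", a$start[conflict] + 1,
                       " vs ", b$chrom[conflict], ":", b$start[conflict] + 1, ")")
      stop("gene(s) assigned to two locations: ", paste(detail, collapse = "; "))
    }
    cur <- cur[!(cur$gene %in% shared), , drop = FALSE]
  }
  merged <- rbind(prev, cur)
  gene_map(map_species(current), gene = merged$gene, chrom = merged$chrom,
           start = merged$start, end = merged$end, strand = merged$strand,
           label = merged$label, provenance = merged$provenance)
}

#' Per-chromosome accounting of a gene map
#'
#' Counts mapped genes per chromosome split by provenance, with a totals row
#' (the shape of a genes-mapped-per-chromosome table). Predicted chromosome
#' sizes, when supplied, are pass-through metadata and are never computed.
#'
#' @param map a [gene_map()].
#' @param predicted_sizes optional data.frame with columns `chromosome` and
#'   `predicted_size_mb`.
#' @return data.frame with columns `chromosome`, `predicted_size_mb`,
#'   `n_current`, `n_previous`, `n_total`; final row `chromosome == "Total"`.
#' @export
summarize_map <- function(map, predicted_sizes = NULL) {
  df <- as.data.frame(map)
  chroms <- sort(unique(c(df$chrom,
                          if (!is.null(predicted_sizes)) predicted_sizes$chromosome)))
  n_cur <- vapply(chroms, function(ch)
    sum(df$chrom == ch & df$provenance == "current_study"), integer(1))
  n_prev <- vapply(chroms, function(ch)
    sum(df$chrom == ch & df$provenance == "previous"), integer(1))
  sizes <- rep(NA_real_, length(chroms))
  if (!is.null(predicted_sizes)) {
    m <- match(chroms, predicted_sizes$chromosome)
    sizes <- predicted_sizes$predicted_size_mb[m]
  }
  out <- data.frame(chromosome = chroms, predicted_size_mb = sizes,
                    n_current = n_cur, n_previous = n_prev,
                    n_total = n_cur + n_prev, stringsAsFactors = FALSE)
  total <- data.frame(chromosome = "Total",
                      predicted_size_mb = if (all(is.na(sizes))) NA_real_ else sum(sizes, na.rm = TRUE),
                      n_current = sum(n_cur), n_previous = sum(n_prev),
                      n_total = sum(n_cur) + sum(n_prev), stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Flag genes whose observed chromosome contradicts expectation
#'
#' Compares an observed gene map against an expected map through a chromosome
#' homology table (expected-species chromosome to observed-species
#' chromosome, possibly one-to-many, as painting homologies are). A gene
#' observed on a chromosome not homologous to its expected chromosome is a
#' discrepancy: it is classified `"transposition_candidate"` when at least
#' one of its flanking neighbours in the expected map is also discordant
#' (suggesting a moved region), else `"assembly_error_candidate"`. Both
#' labels are advisory. Genes with no expected location are reported
#' separately: they resolve previous blank spots on the map.
#'
#' @param observed observed [gene_map()].
#' @param expected expected [gene_map()] (e.g. positions lifted from another
#'   species' assembly).
#' @param homology data.frame with columns `expected_chrom`, `observed_chrom`.
#' @return list with elements `discrepancies` (data.frame: `gene`,
#'   `expected_chromosome`, `observed_chromosome`, `classification`) and
#'   `blank_spots` (character vector of observed genes with no expectation).
#' @export
flag_discrepancies <- function(observed, expected, homology) {
  stopifnot(all(c("expected_chrom", "observed_chrom") %in% names(homology)))
  obs <- as.data.frame(observed); exp <- as.data.frame(expected)
  blank <- setdiff(obs$gene, exp$gene)
  shared <- intersect(obs$gene, exp$gene)
  homologs <- split(homology$observed_chrom, homology$expected_chrom)
  exp_chrom <- exp$chrom[match(shared, exp$gene)]
  obs_chrom <- obs$chrom[match(shared, obs$gene)]
  concordant <- mapply(function(e, o) o %in% homologs[[e]], exp_chrom, obs_chrom)
  bad <- which(!concordant)
  if (!length(bad)) {
    return(list(discrepancies = data.frame(gene = character(0),
                                           expected_chromosome = character(0),
                                           observed_chromosome = character(0),
                                           classification = character(0),
                                           stringsAsFactors = FALSE),
                blank_spots = blank))
  }
  # neighbour context in the expected map, for classification
  exp_ord <- exp[order(exp$chrom, exp$start), ]
  discord_gene <- shared[bad]
  classification <- vapply(discord_gene, function(g) {
    ch <- exp_ord$chrom[exp_ord$gene == g]
    on_ch <- exp_ord[exp_ord$chrom == ch, , drop = FALSE]
    i <- which(on_ch$gene == g)
    nbrs <- on_ch$gene[c(i - 1L, i + 1L)]
    nbrs <- nbrs[!is.na(nbrs)]
    if (any(nbrs %in% discord_gene)) "transposition_candidate" else "assembly_error_candidate"
  }, character(1))
  list(discrepancies = data.frame(gene = discord_gene,
                                  expected_chromosome = exp_chrom[bad],
                                  observed_chromosome = obs_chrom[bad],
                                  classification = unname(classification),
                                  stringsAsFactors = FALSE),
       blank_spots = blank)
}

#' Group map records into order-certain runs
#'
#' FISH on condensed metaphase chromosomes cannot resolve the relative order
#' of loci closer than about 1 Mb. Consecutive genes on one chromosome whose
#' spacing falls below `resolution_mb` are grouped as order-uncertain (the
#' grouping is the transitive closure of the below-resolution relation);
#' genes spaced above resolution form singleton groups. Groups never span
#' chromosomes.
#'
#' @param map a [gene_map()].
#' @param resolution_mb resolution limit in megabases (default 1).
#' @return the map's data.frame with an added integer column `order_group`;
#'   genes sharing a group id have uncertain relative order.
#' @export
order_confidence <- function(map, resolution_mb = 1) {
  df <- as.data.frame(map)
  df <- df[order(df$chrom, df$start, df$gene), , drop = FALSE]
  n <- nrow(df)
  grp <- integer(n)
  gid <- 0L
  for (i in seq_len(n)) {
    new_group <- i == 1L ||
      df$chrom[i] != df$chrom[i - 1L] ||
      (df$start[i] - df$start[i - 1L]) >= resolution_mb * 1e6
    if (new_group) gid <- gid + 1L
    grp[i] <- gid
  }
  df$order_group <- grp
  rownames(df) <- NULL
  df
}
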