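#' Read an ortholog position table
#'
#' TSV with header columns `gene`, `chromA`, `startA`, `endA`, `chromB`,
#' `startB`, `endB` (case-insensitive; `endA`/`endB` optional). Coordinates
#' are 1-based inclusive on input. Genes lacking a species-B chromosome may
#' have empty `chromB`/`startB` fields; they are retained here and excluded
#' (with a warning) by [detect_blocks()].
#'
#' @param path file path.
#' @param one_based are input coordinates 1-based inclusive? Default `TRUE`.
#' @return data.frame with columns `gene`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB` (0-based half-open internally).
#' @export
read_ortholog_table <- function(path, one_based = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("gene", "chroma", "starta", "chromb", "startb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ortholog table '", path, "' missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene_id(s) in ortholog table: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  grab <- function(col, fallback = NULL) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else fallback
  }
  startA <- grab("starta"); startB <- grab("startb")
  endA <- grab("enda", startA); endB <- grab("endb", startB)
  off <- if (one_based) 1 else 0
  out <- data.frame(gene = as.character(df$gene),
                    chromA = as.character(df$chroma),
                    startA = startA - off, endA = if (one_based) endA else endA,
                    chromB = as.character(df$chromb),
                    startB = startB - off, endB = if (one_based) endB else endB,
                    stringsAsFactors = FALSE)
  if (!one_based) { out$endA <- endA; out$endB <- endB }
  out
}

#' Detect conserved synteny blocks from an ortholog table
#'
#' Genes are sorted along species A; a block is a maximal run of consecutive
#' species-A genes whose species-B chromosome is constant. Gene order within
#' species B is *not* required to be conserved (inversions inside a block do
#' not split it); monotonicity of the species-B positions is only recorded in
#' the `order_conserved` flag. Blocks whose species-A span falls below
#' `min_span_kb` are discarded after run formation.
#'
#' @param table ortholog table: data.frame with columns `gene`, `chromA`,
#'   `startA`, `endA`, `chromB`, `startB` (and optionally `endB`); 0-based
#'   half-open coordinates as produced by [read_ortholog_table()] or
#'   [make_ortholog_table()].
#' @param min_span_kb minimum species-A span in kilobases (default 100).
#' @return data.frame of class `synteny_blocks` with one row per block:
#'   `id`, `chromA`, `startA`, `endA`, `chromB`, `n_genes`, `span_mb`,
#'   `order_conserved`, and a list-column `genes` holding each block's gene
#'   table (ordered along species A).
#' @export
detect_blocks <- function(table, min_span_kb = 100) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (!("endA" %in% names(table))) table$endA <- table$startA + 1
  unplaced <- is.na(table$chromB) | !nzchar(table$chromB) | is.na(table$startB)
  if (any(unplaced)) {
    warning(sum(unplaced), " gene(s) lack a species-B location and were excluded: ",
            paste(utils::head(table$gene[unplaced], 5), collapse = ", "),
            if (sum(unplaced) > 5) ", ..." else "")
    table <- table[!unplaced, , drop = FALSE]
  }
  if (!nrow(table)) return(empty_blocks())
  tab <- table[order(table$chromA, table$startA, table$gene), , drop = FALSE]
  brk <- c(TRUE, tab$chromA[-1] != tab$chromA[-nrow(tab)] |
                 tab$chromB[-1] != tab$chromB[-nrow(tab)])
  run <- cumsum(brk)
  rows <- lapply(unname(split(seq_len(nrow(tab)), run)), function(idx) {
    g <- tab[idx, , drop = FALSE]
    startA <- min(g$startA); endA <- max(g$endA)
    mono <- length(idx) < 2L || all(diff(g$startB) > 0) || all(diff(g$startB) < 0)
    list(chromA = g$chromA[1L], startA = startA, endA = endA,
         chromB = g$chromB[1L], n_genes = nrow(g),
         span_mb = (endA - startA) / 1e6, order_conserved = mono, genes = g)
  })
  blocks <- data.frame(
    id = paste0("blk", seq_along(rows)),
    chromA = vapply(rows, `[[`, character(1), "chromA"),
    startA = vapply(rows, `[[`, numeric(1), "startA"),
    endA = vapply(rows, `[[`, numeric(1), "endA"),
    chromB = vapply(rows, `[[`, character(1), "chromB"),
    n_genes = vapply(rows, `[[`, integer(1), "n_genes"),
    span_mb = vapply(rows, `[[`, numeric(1), "span_mb"),
    order_conserved = vapply(rows, `[[`, logical(1), "order_conserved"),
    stringsAsFactors = FALSE)
  blocks$genes <- I(lapply(rows, `[[`, "genes"))
  keep <- blocks$span_mb >= min_span_kb / 1000
  blocks <- blocks[keep, , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks)) blocks$id <- paste0("blk", seq_len(nrow(blocks)))
  class(blocks) <- c("synteny_blocks", "data.frame")
  blocks
}

empty_blocks <- function() {
  b <- data.frame(id = character(0), chromA = character(0), startA = numeric(0),
                  endA = numeric(0), chromB = character(0), n_genes = integer(0),
                  span_mb = numeric(0), order_conserved = logical(0),
                  stringsAsFactors = FALSE)
  b$genes <- I(list())
  class(b) <- c("synteny_blocks", "data.frame")
  b
}

#' Summarize conserved blocks per chromosome
#'
#' Per species-A chromosome: block count, smallest/largest/mean span in Mb,
#' plus an overall row aggregating all blocks. Spans are reported to two
#' decimal places.
#'
#' @param blocks a `synteny_blocks` data.frame from [detect_blocks()] (or any
#'   data.frame with columns `chromA` and `span_mb`).
#' @return data.frame with columns `chromosome`, `n_blocks`, `smallest_mb`,
#'   `largest_mb`, `mean_mb`; the final row has `chromosome == "Overall"`.
#' @export
summarize_blocks <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(data.frame(chromosome = character(0), n_blocks = integer(0),
                      smallest_mb = numeric(0), largest_mb = numeric(0),
                      mean_mb = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- function(chrom, spans) {
    data.frame(chromosome = chrom, n_blocks = length(spans),
               smallest_mb = round(min(spans), 2), largest_mb = round(max(spans), 2),
               mean_mb = round(mean(spans), 2), stringsAsFactors = FALSE)
  }
  per <- lapply(split(blocks$span_mb, blocks$chromA), function(s) s)
  out <- do.call(rbind, Map(agg, names(per), per))
  out <- out[order(out$chromosome), , drop = FALSE]
  out <- rbind(out, agg("Overall", blocks$span_mb))
  rownames(out) <- NULL
  out
}

#' Select FISH probe-target genes from conserved blocks
#'
#' Large blocks (species-A span strictly greater than `large_threshold_mb`)
#' contribute the first and last gene along species A (roles `left_end`,
#' `right_end`); smaller blocks contribute the single gene nearest the block
#' midpoint (role `single`). A block spanning exactly the threshold takes the
#' small-block rule. A midpoint tie between two genes is broken toward the
#' earlier gene along species A, so the selection is deterministic.
#'
#' @param blocks a `synteny_blocks` data.frame from [detect_blocks()].
#' @param large_threshold_mb span threshold in megabases (default 3).
#' @return data.frame with columns `block_id`, `gene`, `role`.
#' @export
select_probe_targets <- function(blocks, large_threshold_mb = 3) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(data.frame(block_id = character(0), gene = character(0),
                      role = character(0), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    g <- blocks$genes[[i]]
    stopifnot(nrow(g) >= 1L)
    g <- g[order(g$startA, g$gene), , drop = FALSE]
    if (blocks$span_mb[i] > large_threshold_mb && nrow(g) >= 2L) {
      out[[i]] <- data.frame(block_id = blocks$id[i],
                             gene = c(g$gene[1L], g$gene[nrow(g)]),
                             role = c("left_end", "right_end"),
                             stringsAsFactors = FALSE)
    } else {
      mid <- (blocks$startA[i] + blocks$endA[i]) / 2
      centre <- (g$startA + g$endA) / 2
      d <- abs(centre - mid)
      pick <- which(d == min(d))[1L]          # ties resolve to earlier gene
      out[[i]] <- data.frame(block_id = blocks$id[i], gene = g$gene[pick],
                             role = "single", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
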