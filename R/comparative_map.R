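#' Delineate oriented conserved segments between two gene maps
#'
#' Orthology is implicit through shared gene identifiers. Genes are taken in
#' species-A map order; a homology segment is a maximal run of genes whose
#' images in species B are consecutive (in B's gene-order ranks restricted to
#' the shared gene universe) on one B chromosome with a consistent direction.
#' A chromosome change (in either species), a rank gap, or a direction change
#' starts a new segment. Consecutiveness is ordinal, not metric: FISH maps
#' have reliable order but not reliable base-pair distances.
#'
#' @param mapA,mapB [gene_map()] objects sharing gene identifiers.
#' @return data.frame of class `homology_segments`, one row per segment:
#'   `id`, `chromA`, `chromB`, `startA`, `endA`, `n_genes`, `orientation`
#'   (`"+"`, `"-"`, or `"unoriented"` for singletons), with list-column
#'   `genes` (gene ids in species-A order).
#' @export
build_segments <- function(mapA, mapB) {
  a <- as.data.frame(mapA); b <- as.data.frame(mapB)
  shared <- intersect(a$gene, b$gene)
  only <- c(setdiff(a$gene, b$gene), setdiff(b$gene, a$gene))
  if (length(only)) {
    warning(length(only), " gene(s) present in only one map were excluded: ",
            paste(utils::head(only, 5), collapse = ", "),
            if (length(only) > 5) ", ..." else "")
  }
  if (!length(shared)) return(empty_segments())
  a <- a[a$gene %in% shared, , drop = FALSE]
  b <- b[b$gene %in% shared, , drop = FALSE]
  a <- a[order(a$chrom, a$start, a$gene), , drop = FALSE]
  b <- b[order(b$chrom, b$start, b$gene), , drop = FALSE]
  rankB <- stats::setNames(seq_len(nrow(b)), b$gene)
  chromB <- stats::setNames(b$chrom, b$gene)

  n <- nrow(a)
  seg_id <- integer(n)
  sid <- 1L
  seg_id[1L] <- sid
  if (n > 1L) {
    dir <- 0L
    for (i in 2:n) {
      d <- rankB[[a$gene[i]]] - rankB[[a$gene[i - 1L]]]
      break_here <- a$chrom[i] != a$chrom[i - 1L] ||
        chromB[[a$gene[i]]] != chromB[[a$gene[i - 1L]]] ||
        abs(d) != 1L || (dir != 0L && d != dir)
      if (break_here) { sid <- sid + 1L; dir <- 0L } else dir <- d
      seg_id[i] <- sid
    }
  }
  rows <- lapply(unname(split(seq_len(n), seg_id)), function(idx) {
    g <- a[idx, , drop = FALSE]
    orientation <- if (length(idx) < 2L) "unoriented" else {
      if (rankB[[g$gene[2L]]] > rankB[[g$gene[1L]]]) "+" else "-"
    }
    list(chromA = g$chrom[1L], chromB = chromB[[g$gene[1L]]],
         startA = min(g$start), endA = max(g$end), n_genes = nrow(g),
         orientation = orientation, genes = g$gene)
  })
  seg <- data.frame(
    id = paste0("seg", seq_along(rows)),
    chromA = vapply(rows, `[[`, character(1), "chromA"),
    chromB = vapply(rows, `[[`, character(1), "chromB"),
    startA = vapply(rows, `[[`, numeric(1), "startA"),
    endA = vapply(rows, `[[`, numeric(1), "endA"),
    n_genes = vapply(rows, `[[`, integer(1), "n_genes"),
    orientation = vapply(rows, `[[`, character(1), "orientation"),
    stringsAsFactors = FALSE)
  seg$genes <- I(lapply(rows, `[[`, "genes"))
  rownames(seg) <- NULL
  class(seg) <- c("homology_segments", "data.frame")
  seg
}

empty_segments <- function() {
  s <- data.frame(id = character(0), chromA = character(0), chromB = character(0),
                  startA = numeric(0), endA = numeric(0), n_genes = integer(0),
                  orientation = character(0), stringsAsFactors = FALSE)
  s$genes <- I(list())
  class(s) <- c("homology_segments", "data.frame")
  s
}

#' Count conserved segments
#'
#' Trivial cardinality, exposed because the segment count between two maps is
#' a headline statistic of genome fragmentation by rearrangement.
#'
#' @param segments a `homology_segments` data.frame from [build_segments()].
#' @return integer segment count.
#' @export
count_segments <- function(segments) {
  if (is.null(segments)) return(0L)
  nrow(segments)
}

#' Assign painting-segment labels to homology segments and call boundaries
#'
#' Each segment receives the majority painting label of its genes (ties break
#' lexicographically; segments with no labelled gene get `"unknown"`).
#' Boundaries are emitted between adjacent segments on one species-A
#' chromosome whose labels differ. A boundary is `"ambiguous"` when either
#' flanking segment contains interleaved labels (minority genes of another
#' label inside the run) or when two or more labels alternate within a window
#' of `window` genes on each side of the junction; otherwise it is
#' `"definitive"`. No boundary is ever emitted inside a run of identically
#' labelled genes.
#'
#' @param segments a `homology_segments` data.frame from [build_segments()].
#' @param labels gene-to-label table: data.frame with columns `gene`, `label`,
#'   or a named character vector. Genes absent from the table are `"unknown"`.
#' @param window ambiguity window in genes (default 3).
#' @return list with elements `segments` (input with added `painting_label`
#'   column) and `boundaries` (data.frame: `chromosome`, `left_gene`,
#'   `right_gene`, `left_label`, `right_label`, `status`).
#' @export
assign_painting <- function(segments, labels, window = 3) {
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$gene)
  gene_label <- function(g) {
    l <- unname(labels[g])
    l[is.na(l)] <- "unknown"
    l
  }
  majority <- function(g) {
    l <- gene_label(g)
    l <- l[l != "unknown"]
    if (!length(l)) return("unknown")
    tb <- table(l)
    names(tb)[tb == max(tb)][1L]        # lexicographic tie-break (table is sorted)
  }
  seg <- segments
  seg$painting_label <- vapply(seg$genes, majority, character(1))
  interleaved <- vapply(seg$genes, function(g) {
    l <- gene_label(g); l <- l[l != "unknown"]
    length(unique(l)) > 1L
  }, logical(1))

  bnd <- list()
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      j <- i + 1L
      if (seg$chromA[i] != seg$chromA[j]) next
      if (seg$painting_label[i] == seg$painting_label[j]) next
      gl <- seg$genes[[i]]; gr <- seg$genes[[j]]
      win <- c(utils::tail(gl, window), utils::head(gr, window))
      wl <- gene_label(win); wl <- wl[wl != "unknown"]
      alternations <- if (length(wl)) length(rle(wl)$values) - 1L else 0L
      status <- if (interleaved[i] || interleaved[j] || alternations >= 2L)
        "ambiguous" else "definitive"
      bnd[[length(bnd) + 1L]] <- data.frame(
        chromosome = seg$chromA[i],
        left_gene = utils::tail(gl, 1L), right_gene = gr[1L],
        left_label = seg$painting_label[i], right_label = seg$painting_label[j],
        status = status, stringsAsFactors = FALSE)
    }
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(chromosome = character(0), left_gene = character(0),
               right_gene = character(0), left_label = character(0),
               right_label = character(0), status = character(0),
               stringsAsFactors = FALSE)
  rownames(boundaries) <- NULL
  list(segments = seg, boundaries = boundaries)
}
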