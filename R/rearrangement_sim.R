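#' Simulation configuration for signed-genome evolution
#'
#' Defines the conditions of a rearrangement simulation: the species tree,
#' the ancestral genome at its root, the per-unit-branch-length event rate
#' and the event-type mix. Event counts per branch are Poisson(rate x branch
#' length), optionally truncated at `max_events_per_branch` (rejection
#' sampling). Defaults mirror the marsupial study system: a 19-marker,
#' 7-chromosome ancestor, a 6-leaf unit-branch tree with one outgroup, a low
#' event rate, and an inversion-dominated mix with translocation excluded
#' (inversion:fission:fusion = 0.6:0.2:0.2), since marsupial karyotype
#' evolution is dominated by inversions with occasional fissions/fusions.
#'
#' @param tree rooted `phylo` tree with branch lengths; default
#'   [default_sim_tree()].
#' @param ancestor [signed_genome()] at the root; default
#'   [default_sim_ancestor()].
#' @param rate events per unit branch length (default 1).
#' @param mix named probabilities over
#'   `c("inversion", "fission", "fusion", "translocation")`, summing to 1.
#' @param max_events_per_branch truncation of per-branch event counts
#'   (default 2).
#' @param seed integer random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree = default_sim_tree(),
                       ancestor = default_sim_ancestor(),
                       rate = 1,
                       mix = c(inversion = 0.6, fission = 0.2,
                               fusion = 0.2, translocation = 0),
                       max_events_per_branch = 2,
                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(ancestor, "signed_genome"),
            rate >= 0)
  mix <- mix[c("inversion", "fission", "fusion", "translocation")]
  if (anyNA(mix)) stop("`mix` must name inversion, fission, fusion, translocation")
  if (abs(sum(mix) - 1) > 1e-9) stop("event mix probabilities must sum to 1")
  structure(list(tree = tree, ancestor = ancestor, rate = rate, mix = mix,
                 max_events_per_branch = max_events_per_branch,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation tree: one outgroup plus five ingroup species
#'
#' Six leaves, unit branch lengths, labelled internal nodes; the ingroup most
#' recent common ancestor is node `"ingroup"`. Unit branch lengths are a
#' documented convention (no branch-length estimates exist for the fixture
#' taxa at segment resolution).
#'
#' @return a `phylo` tree.
#' @export
default_sim_tree <- function() {
  ape::read.tree(text = paste0(
    "(outgroup:1,(((ing1:1,ing2:1)n1:1,(ing3:1,ing4:1)n2:1)n3:1,ing5:1)",
    "ingroup:1)root;"))
}

#' Default simulation ancestor: 19 conserved segments on 7 chromosomes
#'
#' The marsupial-like configuration: six autosomes carrying the 18 autosomal
#' conserved segments plus a sex chromosome, the arrangement inferred for the
#' 2n = 14 marsupial ancestor.
#'
#' @return a [signed_genome()].
#' @export
default_sim_ancestor <- function() {
  signed_genome("ancestor", list(
    chr1 = c("C1", "C2", "C3", "C4", "C5", "C6"),
    chr2 = c("C13", "C14"),
    chr3 = c("C10", "C12", "C11"),
    chr4 = c("C8", "C7", "C9"),
    chr5 = c("C15", "C16"),
    chr6 = c("C17", "C18"),
    chrX = c("X")))
}

## stable 31-bit hash of a string, independent of R's RNG
stable_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

derive_branch_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(label)) %% 2147483647)
}

## ---- elementary rearrangement events ---------------------------------

apply_event <- function(g, ev) {
  chs <- g$chromosomes
  switch(ev$type,
    inversion = {
      ch <- chs[[ev$chrom]]
      seg <- ev$from:ev$to
      ch[seg] <- reverse_markers(ch[seg])
      chs[[ev$chrom]] <- ch
    },
    fission = {
      ch <- chs[[ev$chrom]]
      left <- ch[seq_len(ev$junction)]
      right <- ch[(ev$junction + 1L):length(ch)]
      chs[[ev$chrom]] <- left
      chs[[ev$new_name]] <- right
    },
    fusion = {
      a <- chs[[ev$chrom1]]; b <- chs[[ev$chrom2]]
      if (ev$rev1) a <- reverse_markers(a)
      if (ev$rev2) b <- reverse_markers(b)
      chs[[ev$chrom1]] <- c(a, b)
      chs[[ev$chrom2]] <- NULL
    },
    translocation = {
      a <- chs[[ev$chrom1]]; b <- chs[[ev$chrom2]]
      sa <- if (ev$p1 < length(a)) a[(ev$p1 + 1L):length(a)] else character(0)
      sb <- if (ev$p2 < length(b)) b[(ev$p2 + 1L):length(b)] else character(0)
      na <- c(a[seq_len(ev$p1)], sb)
      nb <- c(b[seq_len(ev$p2)], sa)
      if (!length(na) || !length(nb)) stop("translocation produced an empty chromosome")
      chs[[ev$chrom1]] <- na
      chs[[ev$chrom2]] <- nb
    },
    stop("unknown event type: ", ev$type))
  signed_genome(g$species, chs)
}

fresh_chrom_name <- function(base, existing) {
  nm <- paste0(base, "b")
  while (nm %in% existing) nm <- paste0(nm, "b")
  nm
}

## draw one event for genome g given the (renormalized) mix
draw_event <- function(g, mix) {
  chs <- g$chromosomes
  k_all <- vapply(chs, length, integer(1))
  avail <- c(
    inversion = length(chs) >= 1L,
    fission = any(k_all >= 2L),
    fusion = length(chs) >= 2L,
    # a reciprocal exchange needs a partner and at least one multi-marker
    # chromosome (two singletons admit only no-op swaps)
    translocation = length(chs) >= 2L && any(k_all >= 2L))
  p <- mix * avail
  if (sum(p) <= 0) {
    stop("no event type available under the requested mix for genome '",
         g$species, "'")
  }
  p <- p / sum(p)
  type <- sample(names(p), 1L, prob = p)
  nms <- names(chs)
  switch(type,
    inversion = {
      ch <- sample(nms, 1L)
      k <- length(chs[[ch]])
      i <- sample.int(k, 1L); j <- sample.int(k, 1L)
      list(type = "inversion", chrom = ch, from = min(i, j), to = max(i, j))
    },
    fission = {
      big <- nms[vapply(chs, length, integer(1)) >= 2L]
      ch <- if (length(big) == 1L) big else sample(big, 1L)
      junction <- sample.int(length(chs[[ch]]) - 1L, 1L)
      list(type = "fission", chrom = ch, junction = junction,
           new_name = fresh_chrom_name(ch, nms))
    },
    fusion = {
      pick <- sample(nms, 2L)
      list(type = "fusion", chrom1 = pick[1L], chrom2 = pick[2L],
           rev1 = stats::runif(1) < 0.5, rev2 = stats::runif(1) < 0.5)
    },
    translocation = {
      # first partner must have >= 2 markers so a genuine exchange exists
      multi <- nms[k_all >= 2L]
      c1 <- if (length(multi) == 1L) multi else sample(multi, 1L)
      c2 <- sample(setdiff(nms, c1), 1L)
      k1 <- length(chs[[c1]]); k2 <- length(chs[[c2]])
      # enumerate cut pairs giving two non-empty, changed chromosomes
      cand <- expand.grid(p1 = 0:k1, p2 = 0:k2)
      ok <- with(cand, (p1 > 0L | p2 > 0L) & (p1 < k1 | p2 < k2) &
                       (p1 + (k2 - p2) > 0L) & (p2 + (k1 - p1) > 0L))
      cand <- cand[ok, , drop = FALSE]
      pickrow <- cand[sample.int(nrow(cand), 1L), ]
      list(type = "translocation", chrom1 = c1, chrom2 = c2,
           p1 = pickrow$p1, p2 = pickrow$p2)
    })
}

rtrunc_pois <- function(lambda, max_n) {
  if (!is.finite(max_n)) return(stats::rpois(1L, lambda))
  for (i in 1:100) {
    x <- stats::rpois(1L, lambda)
    if (x <= max_n) return(x)
  }
  as.integer(max_n)
}

#' Simulate signed-genome evolution along a tree
#'
#' Starting from the configured ancestor at the root, each branch receives a
#' Poisson(rate x branch length) number of events (truncated at
#' `max_events_per_branch`), applied sequentially with types drawn from the
#' event mix (renormalized over the types available to the current genome:
#' fusion is unavailable with one chromosome, fission with only single-marker
#' chromosomes). Every marker is conserved (no gain/loss model). The run is
#' fully reproducible from the seed: each branch uses an RNG substream derived
#' by stable hashing of the child node's label, so traversal order cannot
#' change results.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result`: `leaves` (named list of genomes),
#'   `internal` (named list of genomes at internal nodes, incl. the root),
#'   `history` (per-branch event lists, named by child node label), `config`.
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  node_label <- function(id) {
    if (id <= ntip) tree$tip.label[id]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[id - ntip]))
      tree$node.label[id - ntip]
    else paste0("node", id)
  }
  root <- ntip + 1L
  genomes <- list()
  genomes[[node_label(root)]] <- signed_genome(node_label(root),
                                               cfg$ancestor$chromosomes)
  history <- list()
  # preorder: parents before children
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(edges))) {
    par <- node_label(edges[e, 1L]); child <- node_label(edges[e, 2L])
    g <- genomes[[par]]
    set.seed(derive_branch_seed(cfg$seed, child))
    n_ev <- rtrunc_pois(cfg$rate * lens[e], cfg$max_events_per_branch)
    evs <- list()
    if (n_ev > 0L) {
      for (k in seq_len(n_ev)) {
        ev <- draw_event(g, cfg$mix)
        g <- apply_event(g, ev)
        evs[[k]] <- ev
      }
    }
    g <- signed_genome(child, g$chromosomes)
    genomes[[child]] <- g
    history[[child]] <- evs
  }
  leaf_names <- tree$tip.label
  internal_names <- setdiff(names(genomes), leaf_names)
  structure(list(leaves = genomes[leaf_names],
                 internal = genomes[internal_names],
                 history = history,
                 config = cfg),
            class = "sim_result")
}

#' Replay a simulation history
#'
#' Re-applies the logged per-branch events from the root ancestor, without
#' touching the RNG. Replay reproduces every node genome exactly; this is the
#' integrity contract of the history log.
#'
#' @param cfg the [sim_config()] used for the run.
#' @param history the `history` element of a `sim_result`.
#' @return named list of genomes at every node.
#' @export
replay_history <- function(cfg, history) {
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  node_label <- function(id) {
    if (id <= ntip) tree$tip.label[id]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[id - ntip]))
      tree$node.label[id - ntip]
    else paste0("node", id)
  }
  root <- ntip + 1L
  genomes <- list()
  genomes[[node_label(root)]] <- signed_genome(node_label(root),
                                               cfg$ancestor$chromosomes)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    par <- node_label(edges[e, 1L]); child <- node_label(edges[e, 2L])
    g <- genomes[[par]]
    for (ev in history[[child]]) g <- apply_event(g, ev)
    genomes[[child]] <- signed_genome(child, g$chromosomes)
  }
  genomes
}

#' Expand two signed genomes into an ortholog position table
#'
#' Each shared marker is expanded into `genes_per_marker` evenly spaced genes
#' and coordinates are laid out additively per chromosome (each marker
#' occupying `marker_length_mb` megabases). A marker carried in reverse
#' orientation lists its genes in mirrored order, so block/segment detection
#' on the output recovers the marker-level structure including orientation.
#'
#' @param genomeA,genomeB [signed_genome()] objects sharing markers.
#' @param genes_per_marker genes per marker (default 5).
#' @param marker_length_mb marker length in Mb (default 16.2, a realistic
#'   conserved-block scale).
#' @return ortholog table data.frame (`gene`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`), 0-based half-open coordinates.
#' @export
make_ortholog_table <- function(genomeA, genomeB, genes_per_marker = 5,
                                marker_length_mb = 16.2) {
  shared <- intersect(genome_markers(genomeA), genome_markers(genomeB))
  if (!length(shared)) stop("genomes share no markers")
  side <- function(g) {
    L <- marker_length_mb * 1e6
    k <- genes_per_marker
    slot <- L / k
    rows <- list()
    for (nm in names(g$chromosomes)) {
      ch <- g$chromosomes[[nm]]
      off <- 0
      for (m in ch) {
        base <- marker_name(m)
        if (base %in% shared) {
          j <- seq_len(k)
          s_rel <- (j - 1) * slot + 0.25 * slot
          e_rel <- s_rel + 0.5 * slot
          if (marker_sign(m) < 0) {
            s2 <- L - e_rel; e2 <- L - s_rel
            s_rel <- s2; e_rel <- e2
          }
          rows[[length(rows) + 1L]] <- data.frame(
            gene = paste0(base, "_g", j), chrom = nm,
            start = off + s_rel, end = off + e_rel, stringsAsFactors = FALSE)
        }
        off <- off + L
      }
    }
    do.call(rbind, rows)
  }
  a <- side(genomeA); b <- side(genomeB)
  m <- match(a$gene, b$gene)
  out <- data.frame(gene = a$gene,
                    chromA = a$chrom, startA = a$start, endA = a$end,
                    chromB = b$chrom[m], startB = b$start[m], endB = b$end[m],
                    stringsAsFactors = FALSE)
  out[order(out$chromA, out$startA), , drop = FALSE]
}

#' Expand a signed genome into a gene map
#'
#' Companion to [make_ortholog_table()] for the map-based stages: each marker
#' becomes `genes_per_marker` genes, labelled with the marker name (so
#' painting-label assignment can be tested against planted truth).
#'
#' @param genome a [signed_genome()].
#' @param genes_per_marker genes per marker (default 5).
#' @param marker_length_mb marker length in Mb (default 16.2).
#' @return a [gene_map()].
#' @export
genome_to_gene_map <- function(genome, genes_per_marker = 5,
                               marker_length_mb = 16.2) {
  L <- marker_length_mb * 1e6
  k <- genes_per_marker
  slot <- L / k
  rows <- list()
  for (nm in names(genome$chromosomes)) {
    ch <- genome$chromosomes[[nm]]
    off <- 0
    for (m in ch) {
      base <- marker_name(m)
      j <- seq_len(k)
      s_rel <- (j - 1) * slot + 0.25 * slot
      e_rel <- s_rel + 0.5 * slot
      if (marker_sign(m) < 0) {
        s2 <- L - e_rel; e2 <- L - s_rel
        s_rel <- s2; e_rel <- e2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = paste0(base, "_g", j), chrom = nm, start = off + s_rel,
        end = off + e_rel, label = base, stringsAsFactors = FALSE)
      off <- off + L
    }
  }
  df <- do.call(rbind, rows)
  gene_map(genome$species, gene = df$gene, chrom = df$chrom, start = df$start,
           end = df$end, label = df$label)
}

#' Compare a reconstructed karyotype with the true ancestral genome
#'
#' Adjacency precision and recall over internal adjacencies, plus the CAR
#' count error.
#'
#' @param truth the true [signed_genome()] at the reconstructed node.
#' @param estimate an `ancestral_karyotype` (or a [signed_genome()]).
#' @return list: `precision`, `recall`, `car_count_error`, `n_true`, `n_est`.
#' @export
recovery_report <- function(truth, estimate) {
  est_g <- if (inherits(estimate, "ancestral_karyotype"))
    karyotype_to_genome(estimate) else estimate
  true_adj <- genome_to_adjacencies(truth, telomeres = FALSE)
  est_adj <- genome_to_adjacencies(est_g, telomeres = FALSE)
  tp <- length(intersect(est_adj, true_adj))
  precision <- if (length(est_adj)) tp / length(est_adj) else NA_real_
  recall <- if (length(true_adj)) tp / length(true_adj) else NA_real_
  list(precision = precision, recall = recall,
       car_count_error = n_chromosomes(est_g) - n_chromosomes(truth),
       n_true = length(true_adj), n_est = length(est_adj))
}
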