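#' Reconstruct an ancestral karyotype by adjacency parsimony
#'
#' Implements outgroup-anchored adjacency parsimony over signed segment
#' arrangements. Candidate adjacencies are the union of internal marker
#' adjacencies over all leaf genomes. Each candidate is treated as a binary
#' presence/absence character and scored by unit-cost parsimony on the rooted
#' species tree (a Sankoff down/up pass, equivalent to two-pass Fitch for a
#' binary character); the most-parsimonious state set at the target node is
#' read out. Leaves in which either marker of an adjacency is absent
#' contribute no evidence (missing data). Weights: unambiguously present = 1;
#' ambiguous but present in the outgroup = 1 (outgroup presence breaks
#' ambiguity toward present); otherwise ambiguous = 0.5; absent = 0.
#'
#' Contiguous ancestral regions (CARs) are then assembled greedily:
#' adjacencies sorted by weight (descending) then lexicographically are
#' accepted iff both extremities are still free and acceptance does not close
#' a cycle (chromosomes are linear; an adjacency that would close a circular
#' CAR is skipped and recorded). Sex-linked markers (matching `x_pattern`)
#' are constrained to a single CAR: candidate adjacencies joining an X marker
#' to an autosomal marker are excluded, and multiple X markers are pre-chained.
#'
#' @param tree rooted `phylo` species tree; internal nodes named via
#'   `node.label`.
#' @param genomes named list of [signed_genome()] objects covering every tip.
#' @param node name of the internal node to reconstruct.
#' @param outgroup optional tip name whose state arbitrates ambiguity.
#' @param x_pattern regex identifying sex-linked markers (default `"^X"`).
#' @return object of class `ancestral_karyotype`: list with `node`, `cars`
#'   (list of signed marker vectors), `adjacency_weights` (data.frame:
#'   `adjacency`, `weight`, `accepted`), `diploid_number`, `skipped_cycles`.
#' @export
reconstruct_ancestor <- function(tree, genomes, node, outgroup = NULL,
                                 x_pattern = "^X") {
  stopifnot(inherits(tree, "phylo"))
  node_id <- match_internal_node(tree, node)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(genomes))
  if (length(missing)) stop("no genome supplied for tip(s): ",
                            paste(missing, collapse = ", "))
  genomes <- genomes[tips]
  if (!is.null(outgroup) && !(outgroup %in% tips)) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  all_markers <- sort(unique(unlist(lapply(genomes, genome_markers))))
  if (!length(all_markers)) stop("no markers in any genome")

  # candidate adjacencies: union over genomes (internal only)
  per_genome_adj <- lapply(genomes, genome_to_adjacencies, telomeres = FALSE)
  candidates <- sort(unique(unlist(per_genome_adj)))
  marker_sets <- lapply(genomes, genome_markers)

  adj_markers <- function(adj) marker_name(sub(":[th]$", "",
                                               strsplit(adj, "|", fixed = TRUE)[[1L]]))
  leaf_state <- function(adj) {
    mk <- adj_markers(adj)
    vapply(tips, function(sp) {
      if (!all(mk %in% marker_sets[[sp]])) return(NA_integer_)
      as.integer(adj %in% per_genome_adj[[sp]])
    }, integer(1))
  }

  weights <- vapply(candidates, function(adj) {
    states <- leaf_state(adj)
    mpr <- parsimony_states(tree, states, node_id)
    if (identical(mpr, 1L)) return(1)
    if (identical(mpr, 0L)) return(0)
    # ambiguous
    if (!is.null(outgroup)) {
      og <- states[[outgroup]]
      if (!is.na(og) && og == 1L) return(1)
    }
    0.5
  }, numeric(1))

  # X pre-grouping: exclude X-autosome junctions, pre-chain multiple X markers
  x_mk <- grep(x_pattern, all_markers, value = TRUE)
  mixed <- vapply(candidates, function(adj) {
    mk <- adj_markers(adj)
    length(x_mk) > 0 && xor(mk[1] %in% x_mk, mk[2] %in% x_mk)
  }, logical(1))
  weights[mixed] <- 0

  ord <- order(-weights, candidates)
  parent <- stats::setNames(seq_along(all_markers), all_markers)  # union-find
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  used_ext <- character(0)
  accepted <- character(0)
  skipped_cycles <- character(0)

  accept <- function(adj) {
    exts <- strsplit(adj, "|", fixed = TRUE)[[1L]]
    mk <- marker_name(sub(":[th]$", "", exts))
    if (any(exts %in% used_ext)) return(FALSE)
    ra <- find(match(mk[1], all_markers)); rb <- find(match(mk[2], all_markers))
    if (ra == rb) { skipped_cycles <<- c(skipped_cycles, adj); return(FALSE) }
    parent[ra] <<- rb
    used_ext <<- c(used_ext, exts)
    accepted <<- c(accepted, adj)
    TRUE
  }

  if (length(x_mk) > 1L) {
    xs <- sort(x_mk)
    for (i in seq_len(length(xs) - 1L)) {
      accept(canonical_adjacency(paste0(xs[i], ":h"), paste0(xs[i + 1L], ":t")))
    }
  }
  for (i in ord) {
    if (weights[i] <= 0) next
    accept(candidates[i])
  }

  cars <- assemble_cars(all_markers, accepted)
  structure(list(node = node,
                 cars = cars,
                 adjacency_weights = data.frame(adjacency = candidates,
                                                weight = unname(weights),
                                                accepted = candidates %in% accepted,
                                                stringsAsFactors = FALSE),
                 diploid_number = 2L * length(cars),
                 skipped_cycles = skipped_cycles),
            class = "ancestral_karyotype")
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("ancestral_karyotype at node '", x$node, "': ", length(x$cars),
      " CAR(s), 2n = ", x$diploid_number, "\n", sep = "")
  for (i in seq_along(x$cars)) {
    cat("  CAR", i, ": ", paste(x$cars[[i]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Diploid number of an ancestral karyotype
#'
#' Twice the CAR count: each autosomal CAR represents a chromosome pair and
#' the sex-chromosome CAR is counted as a pair by the same convention (so 7
#' CARs, 6 autosomes plus X, encode 2n = 14).
#'
#' @param k an `ancestral_karyotype` from [reconstruct_ancestor()].
#' @return even integer.
#' @export
diploid_number <- function(k) {
  stopifnot(inherits(k, "ancestral_karyotype"))
  2L * length(k$cars)
}

#' Convert an ancestral karyotype to a signed genome
#' @param k an `ancestral_karyotype`.
#' @param species species name for the resulting genome (default: node name).
#' @return a [signed_genome()] whose chromosomes are the CARs.
#' @export
karyotype_to_genome <- function(k, species = NULL) {
  stopifnot(inherits(k, "ancestral_karyotype"))
  if (is.null(species)) species <- k$node
  chs <- k$cars
  names(chs) <- paste0("CAR", seq_along(chs))
  signed_genome(species, chs)
}

## resolve an internal node by name; returns node id
match_internal_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) stop("tree has no internal node labels; cannot resolve '", node, "'")
  hit <- which(labs == node)
  if (!length(hit)) stop("internal node '", node, "' not found in tree")
  ntip + hit[1L]
}

## Most-parsimonious state set for a binary character at one node.
## states: named integer vector over tips (0/1/NA); returns 0L, 1L, or c(0L,1L).
parsimony_states <- function(tree, states, node_id) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  INF <- 1e9
  below <- matrix(0, nrow = nnode, ncol = 2)     # cols: state 0, state 1
  for (i in seq_len(ntip)) {
    s <- states[[tree$tip.label[i]]]
    if (!is.na(s)) {
      below[i, ] <- INF
      below[i, s + 1L] <- 0
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(po[, 2], po[, 1])
  # in postorder every child edge precedes the edge to the parent, so the
  # first-appearance order of parents is a valid bottom-up schedule
  parents_in_order <- unique(po[, 1])
  for (v in parents_in_order) {
    ch <- kids[[as.character(v)]]
    for (s in 0:1) {
      below[v, s + 1L] <- sum(vapply(ch, function(c0) {
        min(below[c0, 1] + (s != 0), below[c0, 2] + (s != 1))
      }, numeric(1)))
    }
  }
  root <- ntip + 1L
  above <- matrix(0, nrow = nnode, ncol = 2)
  pre <- rev(seq_len(nrow(po)))                  # preorder over edges
  for (e in pre) {
    v <- po[e, 1]; c0 <- po[e, 2]
    sibs <- setdiff(kids[[as.character(v)]], c0)
    for (s in 0:1) {
      best <- Inf
      for (t in 0:1) {
        cost <- above[v, t + 1L] + (t != s)
        for (o in sibs) {
          cost <- cost + min(below[o, 1] + (t != 0), below[o, 2] + (t != 1))
        }
        best <- min(best, cost)
      }
      above[c0, s + 1L] <- best
    }
  }
  tot <- below[node_id, ] + above[node_id, ]
  mn <- min(tot)
  out <- which(tot <= mn + 1e-9) - 1L
  if (length(out) == 2L) c(0L, 1L) else as.integer(out[1L])
}

## assemble linear CARs (signed marker paths) from accepted adjacencies
assemble_cars <- function(all_markers, accepted) {
  partner <- new.env(parent = emptyenv())
  for (adj in accepted) {
    exts <- strsplit(adj, "|", fixed = TRUE)[[1L]]
    assign(exts[1L], exts[2L], envir = partner)
    assign(exts[2L], exts[1L], envir = partner)
  }
  has_partner <- function(e) !is.null(get0(e, envir = partner))
  visited <- stats::setNames(rep(FALSE, length(all_markers)), all_markers)
  cars <- list()
  for (m in all_markers) {
    if (visited[[m]]) next
    tail_e <- paste0(m, ":t"); head_e <- paste0(m, ":h")
    # find the free end of this marker's path
    start_ext <- if (!has_partner(tail_e)) tail_e else if (!has_partner(head_e)) head_e else NULL
    if (is.null(start_ext)) next   # would be a cycle; forbidden by assembly
    car <- character(0)
    cur_m <- m; enter <- start_ext
    repeat {
      visited[[cur_m]] <- TRUE
      sign_pos <- endsWith(enter, ":t")
      car <- c(car, if (sign_pos) cur_m else paste0("-", cur_m))
      exit <- paste0(cur_m, if (sign_pos) ":h" else ":t")
      nxt <- get0(exit, envir = partner)
      if (is.null(nxt)) break
      cur_m <- sub(":[th]$", "", nxt)
      enter <- nxt
    }
    # canonical direction: prefer the reading with more forward-oriented
    # markers; break ties lexicographically
    bwd_car <- reverse_markers(car)
    pos_f <- sum(marker_sign(car) > 0); pos_b <- sum(marker_sign(bwd_car) > 0)
    if (pos_b > pos_f ||
        (pos_b == pos_f &&
         paste(bwd_car, collapse = " ") < paste(car, collapse = " "))) {
      car <- bwd_car
    }
    cars[[length(cars) + 1L]] <- car
  }
  cars[order(vapply(cars, function(ch) paste(ch, collapse = " "), character(1)))]
}

#' DCJ distance between two signed genomes
#'
#' Minimal number of double-cut-and-join operations transforming one genome
#' into the other, computed in closed form from the cycle/path decomposition
#' of the adjacency graph: `d = N - C - I/2`, where `N` is the number of
#' shared markers, `C` the number of cycles and `I` the number of odd paths
#' in the graph whose vertices are the adjacencies and telomeres of the two
#' genomes and whose edges join vertices sharing a marker extremity. The
#' distance is symmetric and zero iff the genomes are equal up to chromosome
#' order and whole-chromosome reversal.
#'
#' @param a,b [signed_genome()] objects over identical marker sets.
#' @return non-negative integer.
#' @export
dcj_distance <- function(a, b) {
  ma <- sort(genome_markers(a)); mb <- sort(genome_markers(b))
  if (!identical(ma, mb)) {
    stop("marker sets differ between '", a$species, "' and '", b$species, "'")
  }
  n <- length(ma)
  if (n == 0L) return(0L)
  verts_a <- genome_vertices(a)
  verts_b <- genome_vertices(b)
  # map extremity -> vertex index, per genome
  vmap <- function(verts) {
    m <- new.env(parent = emptyenv())
    for (i in seq_along(verts)) for (e in verts[[i]]) assign(e, i, envir = m)
    m
  }
  map_a <- vmap(verts_a); map_b <- vmap(verts_b)
  exts <- c(paste0(ma, ":t"), paste0(ma, ":h"))
  seen_edge <- stats::setNames(rep(FALSE, length(exts)), exts)
  visited_a <- rep(FALSE, length(verts_a))
  visited_b <- rep(FALSE, length(verts_b))
  cycles <- 0L; odd_paths <- 0L

  walk <- function(side, vi) {
    # traverse the component containing vertex vi; returns c(edges, is_cycle)
    edges <- 0L
    start <- c(side, vi)
    repeat {
      verts <- if (side == 1L) verts_a else verts_b
      if (side == 1L) visited_a[vi] <<- TRUE else visited_b[vi] <<- TRUE
      nxt_e <- NULL
      for (e in verts[[vi]]) if (!seen_edge[[e]]) { nxt_e <- e; break }
      if (is.null(nxt_e)) return(c(edges, 0L))
      seen_edge[[nxt_e]] <<- TRUE
      edges <- edges + 1L
      side <- 3L - side
      vi <- get(nxt_e, envir = if (side == 1L) map_a else map_b)
      if (side == start[1L] && vi == start[2L]) return(c(edges, 1L))
    }
  }
  # paths first: start from degree-1 (telomere) vertices
  for (i in seq_along(verts_a)) {
    if (!visited_a[i] && length(verts_a[[i]]) == 1L) {
      r <- walk(1L, i)
      if (r[1L] %% 2L == 1L) odd_paths <- odd_paths + 1L
    }
  }
  for (i in seq_along(verts_b)) {
    if (!visited_b[i] && length(verts_b[[i]]) == 1L) {
      r <- walk(2L, i)
      if (r[1L] %% 2L == 1L) odd_paths <- odd_paths + 1L
    }
  }
  # remaining components are cycles
  for (i in seq_along(verts_a)) {
    if (!visited_a[i]) {
      r <- walk(1L, i)
      if (r[2L] == 1L || r[1L] > 0L) cycles <- cycles + 1L
    }
  }
  as.integer(n - cycles - odd_paths / 2L)
}

## vertices of one genome's side of the adjacency graph: internal adjacencies
## (two extremities) and telomeres (one extremity each)
genome_vertices <- function(g) {
  verts <- list()
  for (ch in g$chromosomes) {
    k <- length(ch)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        verts[[length(verts) + 1L]] <- c(right_extremity(ch[i]), left_extremity(ch[i + 1L]))
      }
    }
    verts[[length(verts) + 1L]] <- left_extremity(ch[1L])
    verts[[length(verts) + 1L]] <- right_extremity(ch[k])
  }
  verts
}

#' Infer a rearrangement scenario from an ancestor to an extant genome
#'
#' Computes the DCJ distance from the reconstructed ancestor (its CARs taken
#' as chromosomes) to an extant genome, and splits it into chromosome-number
#' events and the remainder: `net = chromosomes(extant) - CARs(ancestor)`,
#' `fissions = max(0, net)`, `fusions = max(0, -net)`, and all residual
#' operations attributed to inversions or other intrachromosomal events.
#'
#' @param ancestor an `ancestral_karyotype` or a [signed_genome()].
#' @param extant a [signed_genome()] over the same marker set.
#' @return object of class `event_scenario`: list with `source`, `target`,
#'   `dcj_distance`, `net_chromosome_change`, `fusions`, `fissions`,
#'   `inversions_or_other`, `narrative`.
#' @export
infer_events <- function(ancestor, extant) {
  anc_g <- if (inherits(ancestor, "ancestral_karyotype"))
    karyotype_to_genome(ancestor) else ancestor
  stopifnot(inherits(anc_g, "signed_genome"), inherits(extant, "signed_genome"))
  d <- dcj_distance(anc_g, extant)
  net <- n_chromosomes(extant) - n_chromosomes(anc_g)
  fissions <- max(0L, net); fusions <- max(0L, -net)
  other <- d - fissions - fusions
  narrative <- sprintf(
    "%s -> %s: %d DCJ operation(s): %d fission(s), %d fusion(s), %d inversion(s)/other.",
    anc_g$species, extant$species, d, fissions, fusions, other)
  structure(list(source = anc_g$species, target = extant$species,
                 dcj_distance = d, net_chromosome_change = net,
                 fusions = fusions, fissions = fissions,
                 inversions_or_other = other, narrative = narrative),
            class = "event_scenario")
}

#' @export
print.event_scenario <- function(x, ...) {
  cat(x$narrative, "\n")
  invisible(x)
}
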