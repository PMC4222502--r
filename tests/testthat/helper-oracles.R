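# Independent brute-force / enumeration oracles. These deliberately re-derive
# every quantity from first principles, sharing no code with the package
# implementation beyond the public data containers.

## ---- extremity / adjacency-set encoding (oracle-side) -----------------

o_name <- function(x) sub("^-", "", x)
o_pos <- function(x) !grepl("^-", x)
o_left <- function(x) paste0(o_name(x), ifelse(o_pos(x), ":t", ":h"))
o_right <- function(x) paste0(o_name(x), ifelse(o_pos(x), ":h", ":t"))
o_adj <- function(e1, e2) paste(pmin(e1, e2), pmax(e1, e2), sep = "|")

## internal adjacency set of a genome, as a sorted character vector
o_state <- function(g) {
  adj <- character(0)
  for (ch in g$chromosomes) {
    k <- length(ch)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) adj <- c(adj, o_adj(o_right(ch[i]), o_left(ch[i + 1L])))
    }
  }
  sort(adj)
}

o_state_key <- function(adj) {
  if (!length(adj)) return("EMPTY")
  paste(sort(adj), collapse = ";")
}
o_key_to_adj <- function(key) {
  if (key == "EMPTY") character(0) else strsplit(key, ";", fixed = TRUE)[[1L]]
}

o_all_extremities <- function(markers) c(paste0(markers, ":t"), paste0(markers, ":h"))

## all DCJ successor states (adjacency multisets) of one state
o_dcj_neighbors <- function(adj, exts) {
  pairs <- strsplit(adj, "|", fixed = TRUE)
  used <- unlist(pairs)
  telo <- setdiff(exts, used)
  out <- character(0)
  n <- length(adj)
  rewire <- function(drop_idx, add) {
    o_state_key(c(adj[-drop_idx], add))
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      p <- pairs[[i]][1]; q <- pairs[[i]][2]; r <- pairs[[j]][1]; s <- pairs[[j]][2]
      out <- c(out,
               rewire(c(i, j), c(o_adj(p, r), o_adj(q, s))),
               rewire(c(i, j), c(o_adj(p, s), o_adj(q, r))))
    }
  }
  if (n >= 1L) {
    for (i in seq_len(n)) {
      p <- pairs[[i]][1]; q <- pairs[[i]][2]
      for (t in telo) {
        out <- c(out, rewire(i, o_adj(p, t)), rewire(i, o_adj(q, t)))
      }
      out <- c(out, rewire(i, character(0)))   # cut into two telomeres
    }
  }
  if (length(telo) >= 2L) {
    for (i in seq_len(length(telo) - 1L)) for (j in (i + 1L):length(telo)) {
      out <- c(out, o_state_key(c(adj, o_adj(telo[i], telo[j]))))
    }
  }
  unique(out)
}

## full-space BFS from one genome; returns environment keyed by state with
## integer distances (DCJ is connected over all matchings, incl. circulars)
o_dcj_bfs_all <- function(g, markers = NULL) {
  if (is.null(markers)) markers <- sort(o_name(unlist(g$chromosomes)))
  exts <- o_all_extremities(markers)
  dist <- new.env(parent = emptyenv())
  start <- o_state_key(o_state(g))
  assign(start, 0L, envir = dist)
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    nxt <- character(0)
    for (key in frontier) {
      for (nb in o_dcj_neighbors(o_key_to_adj(key), exts)) {
        if (is.null(get0(nb, envir = dist))) {
          assign(nb, d + 1L, envir = dist)
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

## point-to-point BFS distance (early exit)
o_dcj_bfs <- function(a, b) {
  markers <- sort(o_name(unlist(a$chromosomes)))
  exts <- o_all_extremities(markers)
  target <- o_state_key(o_state(b))
  start <- o_state_key(o_state(a))
  if (start == target) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(start, TRUE, envir = seen)
  frontier <- start
  d <- 0L
  repeat {
    nxt <- character(0)
    for (key in frontier) {
      for (nb in o_dcj_neighbors(o_key_to_adj(key), exts)) {
        if (nb == target) return(d + 1L)
        if (is.null(get0(nb, envir = seen))) {
          assign(nb, TRUE, envir = seen)
          nxt <- c(nxt, nb)
        }
      }
    }
    if (!length(nxt)) stop("target unreachable (should not happen)")
    frontier <- nxt
    d <- d + 1L
  }
}

## does a state (adjacency set) describe a purely linear genome?
o_state_is_linear <- function(adj, markers) {
  parent <- stats::setNames(seq_along(markers), markers)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in adj) {
    exts <- strsplit(a, "|", fixed = TRUE)[[1L]]
    mk <- o_name(sub(":[th]$", "", exts))
    ra <- find(match(mk[1], markers)); rb <- find(match(mk[2], markers))
    if (ra == rb) return(FALSE)    # closes a cycle (incl. single-marker circle)
    parent[ra] <- rb
  }
  TRUE
}

## decode a linear state into a signed_genome
o_state_to_genome <- function(adj, markers, species = "decoded") {
  partner <- new.env(parent = emptyenv())
  for (a in adj) {
    exts <- strsplit(a, "|", fixed = TRUE)[[1L]]
    assign(exts[1L], exts[2L], envir = partner)
    assign(exts[2L], exts[1L], envir = partner)
  }
  visited <- stats::setNames(rep(FALSE, length(markers)), markers)
  chs <- list()
  for (m in markers) {                       # walk each path from a free end
    if (visited[[m]]) next
    te <- paste0(m, ":t"); he <- paste0(m, ":h")
    start <- if (is.null(get0(te, envir = partner))) te
             else if (is.null(get0(he, envir = partner))) he
             else next                        # mid-path marker; reached later
    ch <- character(0); cur <- m; enter <- start
    repeat {
      visited[[cur]] <- TRUE
      fwd <- endsWith(enter, ":t")
      ch <- c(ch, if (fwd) cur else paste0("-", cur))
      exit <- paste0(cur, if (fwd) ":h" else ":t")
      nxt <- get0(exit, envir = partner)
      if (is.null(nxt)) break
      cur <- sub(":[th]$", "", nxt)
      enter <- nxt
    }
    chs[[length(chs) + 1L]] <- ch
  }
  if (any(!visited)) stop("state is not linear")
  names(chs) <- paste0("c", seq_along(chs))
  signed_genome(species, chs)
}

## ---- exhaustive minimum-change parsimony oracle ------------------------

## MPR state set for a binary character at `node_label` by enumerating every
## internal labeling of the tree (leaf state NA = unconstrained)
o_mpr_states <- function(tree, states, node_label) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labs <- tree$node.label
  node_id <- ntip + which(labs == node_label)[1L]
  grid <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  cost <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    st <- function(id) if (id <= ntip) states[[tree$tip.label[id]]] else lab[id - ntip]
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- st(tree$edge[e, 1]); c0 <- st(tree$edge[e, 2])
      if (!is.na(p) && !is.na(c0) && p != c0) tot <- tot + 1
    }
    cost[r] <- tot
  }
  best <- which(cost == min(cost))
  sort(unique(grid[best, node_id - ntip]))
}

## ---- brute-force run enumeration oracles -------------------------------

## maximal constant-(chromA, chromB) runs along species A, then span filter
o_detect_blocks <- function(table, min_span_kb = 100) {
  tab <- table[!(is.na(table$chromB) | !nzchar(table$chromB) | is.na(table$startB)), ]
  tab <- tab[order(tab$chromA, tab$startA, tab$gene), ]
  n <- nrow(tab)
  same <- function(i, j) tab$chromA[i] == tab$chromA[j] && tab$chromB[i] == tab$chromB[j]
  runs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    ok <- all(vapply((i:j)[-1], function(k) same(i, k), logical(1)))
    if (!ok) next
    maximal <- (i == 1 || !same(i - 1, i)) && (j == n || !same(j, j + 1))
    if (maximal) runs[[length(runs) + 1L]] <- i:j
  }
  runs <- unique(runs)
  keep <- list()
  for (r in runs) {
    span <- max(tab$endA[r]) - min(tab$startA[r])
    if (span / 1e3 >= min_span_kb) keep[[length(keep) + 1L]] <- tab$gene[r]
  }
  keep
}

## maximal runs consecutive in both maps with consistent direction
o_build_segments <- function(mapA, mapB) {
  a <- as.data.frame(mapA); b <- as.data.frame(mapB)
  shared <- intersect(a$gene, b$gene)
  a <- a[a$gene %in% shared, ]; b <- b[b$gene %in% shared, ]
  a <- a[order(a$chrom, a$start, a$gene), ]
  b <- b[order(b$chrom, b$start, b$gene), ]
  rk <- stats::setNames(seq_len(nrow(b)), b$gene)
  bch <- stats::setNames(b$chrom, b$gene)
  n <- nrow(a)
  valid <- function(i, j) {
    if (any(a$chrom[i:j] != a$chrom[i])) return(FALSE)
    g <- a$gene[i:j]
    if (any(bch[g] != bch[g[1]])) return(FALSE)
    if (j == i) return(TRUE)
    d <- diff(unname(rk[g]))
    all(d == 1L) || all(d == -1L)
  }
  segs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!valid(i, j)) next
    if ((i > 1 && valid(i - 1, j)) || (j < n && valid(i, j + 1))) next
    segs[[length(segs) + 1L]] <- a$gene[i:j]
  }
  unique(segs)
}

## ---- random instance generators ----------------------------------------

r_ortholog_table <- function(n_genes, n_chrA = 3, n_chrB = 3, gene_mb = 1) {
  chrA <- sort(sample(paste0("a", seq_len(n_chrA)), n_genes, replace = TRUE))
  startA <- stats::ave(seq_len(n_genes), chrA, FUN = seq_along) * gene_mb * 1e6
  data.frame(gene = paste0("g", seq_len(n_genes)),
             chromA = chrA, startA = startA, endA = startA + 5e4,
             chromB = sample(paste0("b", seq_len(n_chrB)), n_genes, replace = TRUE),
             startB = sample.int(1e8, n_genes), stringsAsFactors = FALSE)
}

r_gene_map_pair <- function(n_genes, n_chrA = 2, n_chrB = 2) {
  genes <- paste0("g", seq_len(n_genes))
  mk <- function(species, n_chr) {
    chrom <- sort(sample(paste0(species, seq_len(n_chr)), n_genes, replace = TRUE))
    ord <- sample(genes)
    gene_map(species, gene = ord, chrom = chrom,
             start = stats::ave(seq_len(n_genes), chrom, FUN = seq_along) * 2e6)
  }
  list(a = mk("A", n_chrA), b = mk("B", n_chrB))
}

r_signed_genome <- function(markers, species = "rand", max_chrom = 3) {
  perm <- sample(markers)
  signs <- sample(c("", "-"), length(markers), replace = TRUE)
  signed <- paste0(signs, perm)
  n_chr <- sample.int(min(max_chrom, length(markers)), 1L)
  if (n_chr == 1L) {
    chs <- list(signed)
  } else {
    cuts <- sort(sample(seq_len(length(markers) - 1L), n_chr - 1L))
    bounds <- c(0L, cuts, length(markers))
    chs <- lapply(seq_len(n_chr), function(i) signed[(bounds[i] + 1L):bounds[i + 1L]])
  }
  names(chs) <- paste0("c", seq_along(chs))
  signed_genome(species, chs)
}

## enumerate every linear signed genome over a marker set (list of genomes)
o_all_linear_genomes <- function(markers) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  out <- list()
  n <- length(markers)
  seen <- new.env(parent = emptyenv())
  for (p in perms(markers)) {
    for (s in seq_len(2^n) - 1L) {
      signs <- ifelse(bitwAnd(s, 2^(seq_len(n) - 1L)) > 0, "-", "")
      signed <- paste0(signs, p)
      for (b in seq_len(2^(n - 1L)) - 1L) {
        cuts <- which(bitwAnd(b, 2^(seq_len(n - 1L) - 1L)) > 0)
        bounds <- c(0L, cuts, n)
        chs <- lapply(seq_len(length(bounds) - 1L),
                      function(i) signed[(bounds[i] + 1L):bounds[i + 1L]])
        names(chs) <- paste0("c", seq_along(chs))
        g <- signed_genome("enum", chs)
        key <- o_state_key(o_state(g))  # dedupe by adjacency set
        if (is.null(get0(key, envir = seen))) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- g
        }
      }
    }
  }
  out
}
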