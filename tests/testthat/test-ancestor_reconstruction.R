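test_that("adjacency decomposition follows the extremity construction", {
  g <- signed_genome("dunnart", list(chr3 = c("C10", "C12", "C11")))
  internal <- genome_to_adjacencies(g, telomeres = FALSE)
  expect_setequal(internal, c("C10:h|C12:t", "C11:t|C12:h"))
  all_adj <- genome_to_adjacencies(g)
  expect_equal(sum(grepl("TEL", all_adj)), 2)

  single <- signed_genome("s", list(c1 = "C1"))
  expect_length(genome_to_adjacencies(single, telomeres = FALSE), 0)
  expect_length(genome_to_adjacencies(single), 2)

  set.seed(41)
  for (rep in 1:10) {
    g <- r_signed_genome(paste0("m", 1:8))
    k <- vapply(g$chromosomes, length, integer(1))
    expect_length(genome_to_adjacencies(g, telomeres = FALSE), sum(k - 1L))
    # reversal of any chromosome leaves the adjacency set unchanged
    chs <- g$chromosomes
    chs[[1]] <- rev(ifelse(grepl("^-", chs[[1]]),
                           sub("^-", "", chs[[1]]), paste0("-", chs[[1]])))
    g2 <- signed_genome("r", chs)
    expect_setequal(genome_to_adjacencies(g2), genome_to_adjacencies(g))
  }
})

test_that("DCJ distance handles the canonical small cases", {
  a <- signed_genome("a", list(c1 = c("C1", "C2", "C3")))
  expect_equal(dcj_distance(a, a), 0L)
  split <- signed_genome("s", list(c1 = "C1", c2 = c("C2", "C3")))
  expect_equal(dcj_distance(a, split), 1L)
  rev_a <- signed_genome("r", list(c1 = c("-C3", "-C2", "-C1")))
  expect_equal(dcj_distance(a, rev_a), 0L)
  inv <- signed_genome("i", list(c1 = c("C1", "-C2", "C3")))
  expect_equal(dcj_distance(a, inv), 1L)
  expect_error(dcj_distance(a, signed_genome("x", list(c1 = "Z1"))),
               "marker sets differ")
})

test_that("DCJ distance equals BFS shortest path on random small pairs", {
  set.seed(47)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    mk <- paste0("m", seq_len(n))
    a <- r_signed_genome(mk, "a")
    b <- r_signed_genome(mk, "b")
    expect_equal(dcj_distance(a, b), o_dcj_bfs(a, b))
  }
})

test_that("DCJ distance is a metric on sampled triples", {
  set.seed(53)
  for (rep in 1:15) {
    mk <- paste0("m", 1:6)
    a <- r_signed_genome(mk, "a"); b <- r_signed_genome(mk, "b")
    c0 <- r_signed_genome(mk, "c")
    dab <- dcj_distance(a, b); dba <- dcj_distance(b, a)
    expect_equal(dab, dba)
    expect_equal(dcj_distance(a, a), 0L)
    expect_true(dcj_distance(a, c0) <= dab + dcj_distance(b, c0))
    if (dab == 0L) expect_true(same_genome(a, b))
    if (same_genome(a, b)) expect_equal(dab, 0L)
  }
})

test_that("identical leaves reconstruct to themselves on any tree shape", {
  g <- signed_genome("x", list(c1 = c("C1", "C2", "C3"), c2 = c("C4", "C5")))
  trees <- c("((a:1,b:1)n1:1,(c:1,d:1)n2:1)root;",
             "(a:1,(b:1,(c:1,d:1)n2:1)n1:1)root;")
  for (txt in trees) {
    tree <- ape::read.tree(text = txt)
    genomes <- lapply(c(a = "a", b = "b", c = "c", d = "d"),
                      function(s) signed_genome(s, g$chromosomes))
    for (node in c("root", "n1", "n2")) {
      k <- reconstruct_ancestor(tree, genomes, node)
      expect_true(same_genome(karyotype_to_genome(k), g))
      expect_true(all(k$adjacency_weights$weight == 1))
    }
  }
})

test_that("parsimony adjacency weights match exhaustive minimum-change labelings", {
  set.seed(59)
  tree <- ape::read.tree(text = "((a:1,b:1)n1:1,(c:1,d:1)n2:1)root;")
  for (rep in 1:25) {
    mk <- paste0("m", seq_len(sample(3:6, 1)))
    genomes <- lapply(c(a = "a", b = "b", c = "c", d = "d"),
                      function(s) r_signed_genome(mk, s))
    candidates <- sort(unique(unlist(lapply(genomes, genome_to_adjacencies,
                                            telomeres = FALSE))))
    for (node in c("root", "n1", "n2")) {
      k <- reconstruct_ancestor(tree, genomes, node)
      for (adj in candidates) {
        states <- vapply(genomes, function(g)
          as.integer(adj %in% genome_to_adjacencies(g, telomeres = FALSE)),
          integer(1))
        mpr <- o_mpr_states(tree, as.list(states), node)
        w <- k$adjacency_weights$weight[k$adjacency_weights$adjacency == adj]
        want <- if (identical(mpr, 1L)) 1 else if (identical(mpr, 0L)) 0 else 0.5
        expect_equal(w, want, info = paste(node, adj))
      }
    }
  }
})

test_that("outgroup presence breaks ambiguity toward present", {
  tree <- ape::read.tree(text = "(out:1,((a:1,b:1)n1:1,c:1)ing:1)root;")
  base <- list(c1 = c("C1", "C2"), c2 = "C3")     # carries C1-C2
  split <- list(c1 = "C1", c2 = "C2", c3 = "C3")  # lacks it
  genomes <- list(out = signed_genome("out", base),
                  a = signed_genome("a", base),
                  b = signed_genome("b", split),
                  c = signed_genome("c", split))
  adj <- genome_to_adjacencies(genomes$a, telomeres = FALSE)
  # without the outgroup argument the adjacency is ambiguous at 'ing'
  k0 <- reconstruct_ancestor(tree, genomes, "ing")
  w0 <- k0$adjacency_weights$weight[k0$adjacency_weights$adjacency == adj]
  expect_equal(w0, 0.5)
  k1 <- reconstruct_ancestor(tree, genomes, "ing", outgroup = "out")
  w1 <- k1$adjacency_weights$weight[k1$adjacency_weights$adjacency == adj]
  expect_equal(w1, 1)
})

test_that("CAR assembly never reuses an extremity and never closes a cycle", {
  set.seed(61)
  tree <- ape::read.tree(text = "(out:1,((a:1,b:1)n1:1,(c:1,d:1)n2:1)ing:1)root;")
  for (rep in 1:10) {
    mk <- paste0("m", 1:7)
    genomes <- lapply(c(out = "out", a = "a", b = "b", c = "c", d = "d"),
                      function(s) r_signed_genome(mk, s))
    k <- reconstruct_ancestor(tree, genomes, "ing", outgroup = "out")
    acc <- k$adjacency_weights$adjacency[k$adjacency_weights$accepted]
    exts <- unlist(strsplit(acc, "|", fixed = TRUE))
    expect_false(anyDuplicated(exts) > 0)
    # CARs partition the marker set and are linear (paths, not cycles)
    expect_setequal(unlist(lapply(k$cars, function(ch) sub("^-", "", ch))), mk)
    expect_equal(diploid_number(k), 2L * length(k$cars))
  }
})

test_that("X-linked markers are confined to their own CAR", {
  tree <- ape::read.tree(text = "((a:1,b:1)n1:1,c:1)root;")
  fused <- list(c1 = c("C1", "X"))               # X fused to an autosome
  genomes <- list(a = signed_genome("a", fused),
                  b = signed_genome("b", fused),
                  c = signed_genome("c", fused))
  k <- reconstruct_ancestor(tree, genomes, "root")
  x_car <- Filter(function(ch) any(grepl("^X$", sub("^-", "", ch))), k$cars)
  expect_length(x_car, 1)
  expect_equal(sub("^-", "", x_car[[1]]), "X")   # no autosome joined to X
})

test_that("event scenarios decompose DCJ into fissions, fusions and the rest", {
  anc <- signed_genome("anc", list(c1 = c("C10", "C12", "C11")))
  split <- signed_genome("opossum_like", list(c1 = c("C10", "C12"), c2 = "C11"))
  ev <- infer_events(anc, split)
  expect_equal(ev$dcj_distance, 1L)
  expect_equal(ev$fissions, 1L)
  expect_equal(ev$fusions, 0L)
  expect_equal(ev$inversions_or_other, 0L)

  same <- infer_events(anc, signed_genome("same", list(c1 = c("C10", "C12", "C11"))))
  expect_equal(same$dcj_distance, 0L)
  expect_equal(same$net_chromosome_change, 0L)
  expect_equal(same$fissions + same$fusions + same$inversions_or_other, 0L)
})

test_that("scenario chromosome-change counts match planted simulation truth", {
  set.seed(67)
  for (rep in 1:10) {
    cfg <- sim_config(rate = 1.5, max_events_per_branch = 2, seed = rep)
    sim <- simulate_genomes(cfg)
    truth_root <- sim$internal$root
    for (leaf in names(sim$leaves)) {
      ev <- infer_events(truth_root, sim$leaves[[leaf]])
      expect_equal(ev$net_chromosome_change,
                   n_chromosomes(sim$leaves[[leaf]]) - n_chromosomes(truth_root))
      expect_true(ev$dcj_distance >= abs(ev$net_chromosome_change))
      expect_true(ev$inversions_or_other >= 0L)
    }
  }
})

test_that("diploid number is twice the CAR count", {
  fx <- marsupial_fixture()
  k <- reconstruct_ancestor(fx$tree, fx$genomes, fx$node, outgroup = fx$outgroup)
  expect_equal(diploid_number(k), 2L * length(k$cars))
  # an opossum-like 9-CAR karyotype encodes 2n = 18
  k9 <- structure(list(node = "toy",
                       cars = lapply(paste0("C", 1:9), function(m) m),
                       diploid_number = 18L),
                  class = "ancestral_karyotype")
  expect_equal(diploid_number(k9), 18L)
  k0 <- structure(list(node = "empty", cars = list(), diploid_number = 0L),
                  class = "ancestral_karyotype")
  expect_equal(diploid_number(k0), 0L)
})
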