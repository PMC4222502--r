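test_that("rate zero propagates the ancestor unchanged to every node", {
  cfg <- sim_config(rate = 0, seed = 5)
  sim <- simulate_genomes(cfg)
  for (g in c(sim$leaves, sim$internal)) {
    expect_true(same_genome(g, cfg$ancestor))
  }
  expect_true(all(vapply(sim$history, length, integer(1)) == 0L))
})

test_that("simulation is reproducible from the seed and differs across seeds", {
  cfg <- sim_config(rate = 1, seed = 99)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(lapply(s1$leaves, `[[`, "chromosomes"),
                   lapply(s2$leaves, `[[`, "chromosomes"))
  s3 <- simulate_genomes(sim_config(rate = 1, seed = 100))
  expect_false(identical(s1$history, s3$history))
})

test_that("a pure-fission branch raises the chromosome count by the event count", {
  tree <- ape::read.tree(text = "(leaf:1)root;")
  cfg <- sim_config(tree = tree, rate = 50,
                    mix = c(inversion = 0, fission = 1, fusion = 0,
                            translocation = 0),
                    max_events_per_branch = 3, seed = 8)
  sim <- simulate_genomes(cfg)
  expect_equal(length(sim$history$leaf), 3L)
  expect_equal(n_chromosomes(sim$leaves$leaf),
               n_chromosomes(cfg$ancestor) + 3L)
})

test_that("an impossible event mix raises an error", {
  one_chrom <- signed_genome("anc", list(c1 = c("C1", "C2")))
  tree <- ape::read.tree(text = "(leaf:1)root;")
  cfg <- sim_config(tree = tree, ancestor = one_chrom, rate = 50,
                    mix = c(inversion = 0, fission = 0, fusion = 1,
                            translocation = 0),
                    max_events_per_branch = 1, seed = 3)
  expect_error(simulate_genomes(cfg), "no event type available")
  expect_error(sim_config(mix = c(inversion = 0.5, fission = 0.2,
                                  fusion = 0.2, translocation = 0)),
               "sum to 1")
})

test_that("history replay reproduces every node genome exactly", {
  for (seed in c(2, 17, 123)) {
    cfg <- sim_config(rate = 1.5, max_events_per_branch = Inf, seed = seed)
    sim <- simulate_genomes(cfg)
    replayed <- replay_history(cfg, sim$history)
    for (nm in names(sim$leaves)) {
      expect_identical(replayed[[nm]]$chromosomes, sim$leaves[[nm]]$chromosomes)
    }
    for (nm in names(sim$internal)) {
      expect_identical(replayed[[nm]]$chromosomes, sim$internal[[nm]]$chromosomes)
    }
  }
})

test_that("every event preserves the marker multiset", {
  set.seed(71)
  g <- default_sim_ancestor()
  mk <- sort(genome_markers(g))
  # hammer the genome with random events of every type, including translocation
  cfg_mix <- c(inversion = 0.4, fission = 0.2, fusion = 0.2, translocation = 0.2)
  for (i in 1:200) {
    ev <- karyorec:::draw_event(g, cfg_mix)
    g <- karyorec:::apply_event(g, ev)
    expect_equal(sort(genome_markers(g)), mk)
  }
})

test_that("ortholog-table expansion recovers planted marker structure", {
  anc <- signed_genome("A", list(c1 = c("C1", "C2"), c2 = "C3"))
  same <- signed_genome("B", anc$chromosomes)
  tab <- make_ortholog_table(anc, same, genes_per_marker = 5)
  expect_equal(nrow(tab), 15)
  blocks <- detect_blocks(tab, min_span_kb = 0)
  expect_equal(nrow(blocks), 2)                      # one block per chromosome
  expect_equal(sort(blocks$n_genes), c(5L, 10L))

  # single inversion: three homology segments recovered from the maps
  inv <- signed_genome("B", list(c1 = c("C1", "-C2", "C3")))
  anc3 <- signed_genome("A", list(c1 = c("C1", "C2", "C3")))
  segs <- build_segments(genome_to_gene_map(anc3), genome_to_gene_map(inv))
  expect_equal(count_segments(segs), 3L)
  expect_equal(segs$orientation, c("+", "-", "+"))

  tab1 <- make_ortholog_table(anc, same, genes_per_marker = 1)
  expect_equal(nrow(tab1), 3)
})

test_that("reversed markers mirror their gene order in the expanded table", {
  a <- signed_genome("A", list(c1 = c("C1", "C2")))
  b <- signed_genome("B", list(c1 = c("C1", "-C2")))
  tab <- make_ortholog_table(a, b, genes_per_marker = 3)
  c2 <- tab[grepl("^C2_", tab$gene), ]
  expect_equal(order(c2$startA), rev(order(c2$startB)))
})

test_that("recovery metrics match hand-computed confusion counts", {
  truth <- default_sim_ancestor()
  r <- recovery_report(truth, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$car_count_error, 0L)

  # estimate with every marker on its own CAR: no adjacencies at all
  markers <- genome_markers(truth)
  loose <- signed_genome("loose",
                         stats::setNames(as.list(markers), paste0("c", seq_along(markers))))
  r0 <- recovery_report(truth, loose)
  expect_equal(r0$recall, 0)

  set.seed(73)
  for (rep in 1:10) {
    est <- r_signed_genome(markers, "est")
    r2 <- recovery_report(truth, est)
    ta <- genome_to_adjacencies(truth, telomeres = FALSE)
    ea <- genome_to_adjacencies(est, telomeres = FALSE)
    tp <- sum(ea %in% ta)
    expect_equal(r2$precision, tp / length(ea))
    expect_equal(r2$recall, tp / length(ta))
    expect_equal(r2$car_count_error,
                 n_chromosomes(est) - n_chromosomes(truth))
  }
})
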