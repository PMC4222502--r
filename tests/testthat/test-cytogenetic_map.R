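mk_map <- function(species, genes, chrom, start, provenance = "current_study") {
  gene_map(species, gene = genes, chrom = chrom, start = start,
           provenance = rep(provenance, length.out = length(genes)))
}

test_that("map merging unions disjoint records and keeps provenance", {
  cur <- mk_map("w", paste0("c", 1:5), "1", (1:5) * 1e6, "current_study")
  prev <- mk_map("w", paste0("p", 1:3), "2", (1:3) * 1e6, "previous")
  m <- merge_maps(cur, prev)
  expect_equal(nrow(m), 8)
  expect_equal(sum(m$provenance == "current_study"), 5)

  m2 <- merge_maps(cur, mk_map("w", character(0), character(0), numeric(0)))
  expect_equal(as.data.frame(m2)[names(m2) != "provenance"],
               as.data.frame(cur)[names(cur) != "provenance"])

  # shared gene, same location: one record attributed to the earlier study
  shared <- merge_maps(cur, mk_map("w", "c1", "1", 1e6, "previous"))
  expect_equal(nrow(shared), 5)
  expect_equal(shared$provenance[shared$gene == "c1"], "previous")

  # same gene, two locations: error naming both
  expect_error(merge_maps(cur, mk_map("w", "c1", "3", 9e6, "previous")),
               "two locations.*c1")
  expect_error(merge_maps(cur, mk_map("other", "q", "1", 1e6)), "different species")
})

test_that("merging disjoint maps is associative and order-insensitive", {
  set.seed(21)
  a <- mk_map("s", paste0("a", 1:6), sample(c("1", "2"), 6, TRUE), sample.int(1e7, 6))
  b <- mk_map("s", paste0("b", 1:4), sample(c("1", "2"), 4, TRUE), sample.int(1e7, 4))
  c0 <- mk_map("s", paste0("c", 1:5), sample(c("1", "2"), 5, TRUE), sample.int(1e7, 5))
  norm <- function(m) { d <- as.data.frame(m); d[order(d$gene), ] }
  m1 <- merge_maps(merge_maps(a, b), c0)
  m2 <- merge_maps(a, merge_maps(b, c0))
  m3 <- merge_maps(merge_maps(c0, b), a)
  expect_equal(norm(m1)[c("gene", "chrom", "start")], norm(m2)[c("gene", "chrom", "start")])
  expect_equal(norm(m1)[c("gene", "chrom", "start")], norm(m3)[c("gene", "chrom", "start")])
})

test_that("map summaries count by provenance and total correctly", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    m <- gene_map("w", gene = paste0("g", 1:n),
                  chrom = sample(c("1", "2", "X"), n, TRUE),
                  start = sample.int(1e8, n),
                  provenance = sample(c("current_study", "previous"), n, TRUE))
    s <- summarize_map(m)
    body <- s[s$chromosome != "Total", ]
    tot <- s[s$chromosome == "Total", ]
    expect_equal(body$n_total, body$n_current + body$n_previous)
    expect_equal(tot$n_current, sum(body$n_current))
    expect_equal(tot$n_total, n)
  }
  empty <- gene_map("w", character(0), character(0), numeric(0))
  s0 <- summarize_map(empty)
  expect_equal(s0$n_total, 0)   # single all-zero totals row
})

test_that("discrepancy flagging reports only genes off their homologous chromosome", {
  homology <- data.frame(expected_chrom = c("o3", "o5"),
                         observed_chrom = c("w3", "w2"),
                         stringsAsFactors = FALSE)
  # the classic case: expected (via o3) on w3, observed on w2 instead
  observed <- mk_map("w", c("AIP", "ok1"), c("w2", "w3"), c(1e6, 2e6))
  expected <- mk_map("o", c("AIP", "ok1"), c("o3", "o3"), c(5e6, 6e6))
  r <- flag_discrepancies(observed, expected, homology)
  expect_equal(r$discrepancies$gene, "AIP")
  expect_equal(r$discrepancies$observed_chromosome, "w2")
  expect_equal(r$discrepancies$classification, "assembly_error_candidate")

  conc <- flag_discrepancies(mk_map("w", "ok1", "w3", 1e6),
                             mk_map("o", "ok1", "o3", 1e6), homology)
  expect_equal(nrow(conc$discrepancies), 0)

  # genes without an expected location resolve blank spots
  blank <- flag_discrepancies(mk_map("w", c("new1", "ok1"), c("w2", "w3"), c(1e6, 2e6)),
                              mk_map("o", "ok1", "o3", 1e6), homology)
  expect_equal(blank$blank_spots, "new1")
})

test_that("planted relocations are recovered exactly, neighbours drive classification", {
  set.seed(77)
  n <- 100
  exp_chrom <- sample(c("o1", "o2", "o3"), n, TRUE)
  homology <- data.frame(expected_chrom = c("o1", "o2", "o3"),
                         observed_chrom = c("w1", "w2", "w3"))
  obs_chrom <- homology$observed_chrom[match(exp_chrom, homology$expected_chrom)]
  planted <- sample(n, 5)
  for (i in planted) {
    obs_chrom[i] <- sample(setdiff(c("w1", "w2", "w3"), obs_chrom[i]), 1)
  }
  observed <- mk_map("w", paste0("g", 1:n), obs_chrom, seq_len(n) * 1e6)
  expected <- mk_map("o", paste0("g", 1:n), exp_chrom, seq_len(n) * 1e6)
  r <- flag_discrepancies(observed, expected, homology)
  expect_equal(sort(r$discrepancies$gene), sort(paste0("g", planted)))
  expect_true(all(r$discrepancies$classification %in%
                  c("transposition_candidate", "assembly_error_candidate")))
})

test_that("order-confidence grouping matches the transitive-closure oracle", {
  close_map <- mk_map("w", paste0("g", 1:4), "1", c(0, 0.5e6, 0.9e6, 1.3e6))
  g1 <- order_confidence(close_map, resolution_mb = 1)
  expect_equal(length(unique(g1$order_group)), 1)   # chained below resolution

  far <- mk_map("w", paste0("g", 1:4), "1", c(0, 5e6, 10e6, 15e6))
  g2 <- order_confidence(far, resolution_mb = 1)
  expect_equal(length(unique(g2$order_group)), 4)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    m <- mk_map("w", paste0("g", 1:n),
                sample(c("1", "2"), n, TRUE), sample.int(2e7, n))
    got <- order_confidence(m, resolution_mb = 1)
    # oracle: connected components of the all-pairs <1 Mb relation per chromosome
    oracle_groups <- local({
      d <- got[order(got$chrom, got$start), ]
      lab <- seq_len(nrow(d))
      repeat {
        changed <- FALSE
        for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
          if (d$chrom[i] == d$chrom[j] && abs(d$start[i] - d$start[j]) < 1e6 &&
              lab[j] != lab[i]) {
            lab[c(i, j)] <- min(lab[i], lab[j]); changed <- TRUE
          }
        }
        if (!changed) break
      }
      lab
    })
    expect_equal(unname(as.integer(factor(got$order_group))),
                 unname(as.integer(factor(oracle_groups, levels = unique(oracle_groups)))))
    # groups never span chromosomes
    expect_true(all(tapply(got$chrom, got$order_group,
                           function(x) length(unique(x))) == 1))
  }
})
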