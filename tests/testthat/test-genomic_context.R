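test_that("classify_position applies the promoter/gene-body/intergenic rules", {
  ann <- make_annotations(999, 2000)  # plus-strand ORF [999, 2000)
  res <- classify_position("c1", c(950, 1500, 500, 999, 900, 998), ann)
  expect_equal(res$label, c("promoter", "gene_body", "intergenic", "gene_body",
                            "promoter", "promoter"))
  expect_equal(res$distance_to_start[1], -49)
  expect_equal(res$distance_to_start[2], 501)
  expect_equal(res$feature_id[1], "g1")
  # the window is strictly < 100 bp upstream: distance 100 is intergenic
  expect_equal(classify_position("c1", 899, ann)$label, "intergenic")
  expect_equal(classify_position("c1", 900, ann)$label, "promoter")
})

test_that("promoter windows are strand-aware", {
  ann <- make_annotations(1000, 2000, strand = "-")
  # start codon of a minus gene is at end - 1; upstream is to the right
  expect_equal(classify_position("c1", 2000, ann)$label, "promoter")
  expect_equal(classify_position("c1", 2098, ann)$label, "promoter")
  expect_equal(classify_position("c1", 2099, ann)$label, "intergenic")
  expect_equal(classify_position("c1", 980, ann)$label, "intergenic")
  expect_equal(classify_position("c1", 2000, ann)$distance_to_start, -1)
})

test_that("promoter takes precedence over gene body", {
  ann <- make_annotations(c(0, 1050), c(1000, 2000))
  # position 960 is inside gene 1 but 90 bp upstream of gene 2's start
  res <- classify_position("c1", 960, ann)
  expect_equal(res$label, "promoter")
  expect_equal(res$feature_id, "g2")
})

test_that("classification errors on out-of-contig positions and partitions", {
  ann <- make_annotations(100, 500)
  expect_error(classify_position("c1", 1000, ann, contig_length = 600),
               "outside contig")
  g <- random_genome(20000, seed = 2)
  cfg <- sim_config(genome_length = 20000, seed = 2)
  ann2 <- generate_annotations(cfg, g)
  occ <- scan_motif(g, motif_spec("GATC", 1, "m6A"))
  counts <- tabulate_contexts(occ, ann2)
  expect_equal(sum(counts), nrow(occ))
  expect_equal(tabulate_contexts(occ[0, ], ann2),
               c(promoter = 0L, gene_body = 0L, intergenic = 0L))
})

test_that("classification is invariant under genome mirroring", {
  L <- 5000
  set.seed(8)
  starts <- sort(sample(seq(100, L - 600, by = 50), 6))
  ann <- make_annotations(starts, starts + 400,
                          strand = sample(c("+", "-"), 6, replace = TRUE))
  pos <- sample(0:(L - 1), 300)
  fwd <- classify_position("c1", pos, ann)
  # mirror: position p -> L-1-p, interval [s,e) -> [L-e, L-s), strands flip
  ann_m <- ann
  ann_m$start <- L - ann$end
  ann_m$end <- L - ann$start
  ann_m$strand <- ifelse(ann$strand == "+", "-", "+")
  rev <- classify_position("c1", L - 1 - pos, ann_m)
  expect_equal(fwd$label, rev$label)
  expect_equal(fwd$distance_to_start, rev$distance_to_start)
})

test_that("fisher_exact reproduces exact enumeration and handles degeneracy", {
  # margins (4,4,4,4): five tables, two-sided p = 34/70
  res <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)
  # degenerate row: no information
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  # symmetry: simultaneous row and column swap preserves the two-sided p
  set.seed(77)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact(tab)$p_value, fisher_exact(swapped)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(123)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:15, 1)), 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact(tab)$p_value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
  # one-sided alternatives too
  tab <- matrix(c(8, 2, 3, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab, "greater")$p_value,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab, "less")$p_value,
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
})

test_that("promoter_enrichment builds the promoter-vs-gene-body table", {
  sim <- simulate_unmeth_regime(seed = 3, u = 60, theta = 10,
                                genome_length = 150000)
  occ <- scan_motif(sim$genome, motif_spec("GATC", 1, "m6A"))
  st <- assign_calls(occ, filter_calls(sim$met$calls), sim$genome)$states
  un <- find_unmethylated(st)
  res <- promoter_enrichment(un, occ, sim$annotations)
  expect_equal(rownames(res$table), c("unmethylated", "reference"))
  expect_equal(colnames(res$table), c("promoter", "gene_body"))
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.005)
  # vs_methylated agrees in direction
  res2 <- promoter_enrichment(un, occ, sim$annotations, mode = "vs_methylated")
  expect_gt(res2$odds_ratio, 1)
  expect_error(promoter_enrichment(un[0, ], occ, sim$annotations), "empty")
})

test_that("unmethylated set equal to all sites gives OR 1 and p 1", {
  ann <- make_annotations(c(500, 2000), c(1500, 3000))
  occ <- data.frame(contig = "c1", strand = "+",
                    match_start = c(450, 600, 2100, 1950),
                    methyl_pos = c(451, 601, 2101, 1951),
                    motif = "GATC", stringsAsFactors = FALSE)
  res <- promoter_enrichment(occ, occ, ann)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
})
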