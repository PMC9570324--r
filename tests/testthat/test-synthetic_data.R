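test_that("generate_genome is deterministic, honours GC and length", {
  cfg <- sim_config(genome_length = 10000, gc_content = 0.44, seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence), 10000)
  expect_true(g1$circular)

  at_only <- generate_genome(sim_config(genome_length = 2000, gc_content = 0,
                                        seed = 2))
  expect_false(grepl("[GC]", at_only$sequence))

  # expected per-strand GATC density is (gc/2)^2 ((1-gc)/2)^2
  cfg3 <- sim_config(genome_length = 200000, gc_content = 0.44, seed = 3)
  g3 <- generate_genome(cfg3)
  n <- nrow(scan_motif(g3, motif_spec("GATC", 1, "m6A")))
  p <- (0.44 / 2)^2 * (0.56 / 2)^2
  expected <- 2 * 200000 * p
  expect_lt(abs(n - expected), 4 * sqrt(expected))
})

test_that("generate_annotations tiles non-overlapping genes with gaps", {
  cfg <- sim_config(genome_length = 12500, gene_length_range = c(900, 900),
                    intergenic_gap_range = c(300, 300), seed = 4)
  g <- generate_genome(cfg)
  ann <- generate_annotations(cfg, g)
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$end - ann$start == 900))
  expect_true(all(diff(ann$start) >= 900))  # no overlap
  expect_true(all(ann$end <= 12500))
  expect_error(generate_annotations(sim_config(genome_length = 500, seed = 1),
                                    generate_genome(sim_config(genome_length = 500,
                                                               gene_length_range = c(600, 1200),
                                                               seed = 1))),
               "infeasible")
})

test_that("gene strands are balanced over seeds", {
  plus <- 0; total <- 0
  for (seed in 1:6) {
    cfg <- sim_config(genome_length = 30000, seed = seed)
    ann <- generate_annotations(cfg, generate_genome(cfg))
    plus <- plus + sum(ann$strand == "+")
    total <- total + nrow(ann)
  }
  expect_lt(abs(plus / total - 0.5), 4 * sqrt(0.25 / total))
})

test_that("generate_methylome plants the configured unmethylated count", {
  sim <- simulate_unmeth_regime(seed = 6, u = 40, genome_length = 120000)
  truth <- sim$truth
  expect_equal(sum(!truth$methylated), 40)
  # truth sites equal an independent scan
  occ <- scan_motif(sim$genome, motif_spec("GATC", 1, "m6A"))
  expect_equal(truth$methyl_pos, occ$methyl_pos)
  # every methylated site has an above-threshold call, none of the
  # unmethylated do once filtered
  calls <- filter_calls(sim$met$calls)
  st <- assign_calls(occ, calls, sim$genome)$states
  expect_equal(st$methylated, truth$methylated)
})

test_that("sub-threshold calls exercise the filter boundary", {
  sim <- simulate_unmeth_regime(seed = 10, u = 200, genome_length = 150000)
  raw <- sim$met$calls
  sub <- raw[raw$score < 30, ]
  expect_gt(nrow(sub), 0)           # some unmethylated sites emit weak calls
  expect_true(all(sub$score < 30))
  expect_equal(nrow(filter_calls(raw)) + nrow(sub), nrow(raw))
})

test_that("recovered fraction estimates the planted fraction", {
  errs <- vapply(1:10, function(seed) {
    cfg <- sim_config(genome_length = 60000, seed = seed,
                      motifs = list(list(spec = motif_spec("GATC", 1, "m6A"),
                                         fraction = 0.95)))
    g <- generate_genome(cfg)
    ann <- generate_annotations(cfg, g)
    met <- generate_methylome(cfg, g, ann)
    occ <- scan_motif(g, motif_spec("GATC", 1, "m6A"))
    st <- assign_calls(occ, filter_calls(met$calls), g)$states
    summarize_motif(st)$fraction_raw - 0.95
  }, numeric(1))
  n_sites <- 450  # order of GATC sites in 60 kb
  expect_lt(abs(mean(errs)), 2 * sqrt(0.95 * 0.05 / n_sites))
})

test_that("promoter odds ratio of unmethylated sites tracks theta", {
  # convergence to theta needs the sparse regime (u small relative to the
  # promoter class), hence the paper-like 2 Mb genome here
  sim <- simulate_unmeth_regime(seed = 11, u = 500, theta = 10,
                                genome_length = 2e6)
  truth <- sim$truth
  un <- truth[!truth$methylated, ]
  res <- promoter_enrichment(un, truth, sim$annotations,
                             mode = "vs_methylated")
  expect_gt(res$odds_ratio, 10 * 0.7)
  expect_lt(res$odds_ratio, 10 * 1.3)
})

test_that("make_fixture round-trips through the I/O layer", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 20000, seed = 12)
  fx <- make_fixture(cfg, dir)
  expect_true(all(file.exists(fx$paths)))

  g <- read_fasta(fx$paths[["fasta"]])[[1]]
  expect_identical(g$sequence, fx$genome$sequence)
  expect_true(g$circular)

  ann <- read_gff3_annotations(fx$paths[["gff"]], keep_types = "CDS")
  expect_equal(ann[c("feature_id", "start", "end", "strand")],
               fx$annotations[c("feature_id", "start", "end", "strand")])

  calls <- expect_silent(read_modifications(fx$paths[["mods"]]))
  expect_equal(calls[c("contig", "position", "strand", "mod_type", "score")],
               fx$calls[c("contig", "position", "strand", "mod_type", "score")])

  truth <- jsonlite::read_json(fx$paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$sites$GATC),
               nrow(scan_motif(g, motif_spec("GATC", 1, "m6A"))))
})

test_that("seed changes the draws but preserves summary statistics", {
  s1 <- simulate_unmeth_regime(seed = 1, u = 20, genome_length = 50000)
  s2 <- simulate_unmeth_regime(seed = 2, u = 20, genome_length = 50000)
  expect_false(identical(s1$genome$sequence, s2$genome$sequence))
  expect_equal(sum(!s1$truth$methylated), sum(!s2$truth$methylated))
  m1 <- mean(filter_calls(s1$met$calls)$score)
  m2 <- mean(filter_calls(s2$met$calls)$score)
  expect_lt(abs(m1 - m2), 10)
})
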