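# Shared fixture builders; everything is generated in code, no data files.

# A tiny deterministic genome with a planted motif at known positions.
tiny_genome <- function(seq, id = "c1", circular = FALSE) {
  seq_record(id, seq, circular = circular)
}

# Random ACGT genome at given GC, without going through sim_config.
random_genome <- function(n, gc = 0.44, seed = 1, circular = FALSE) {
  set.seed(seed)
  seq_record("rg1",
             paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                   collapse = ""),
             circular = circular)
}

# Build modification records directly.
make_calls <- function(contig, position, strand, mod_type = "m6A",
                       score = 50, ipd_ratio = 5, coverage = 50,
                       context = NA_character_) {
  data.frame(contig = contig, position = as.integer(position), strand = strand,
             mod_type = mod_type, score = score, ipd_ratio = ipd_ratio,
             coverage = as.integer(coverage), context = context,
             stringsAsFactors = FALSE)
}

# Site states without going through assign_calls.
make_states <- function(n_genome, n_detected, motif = "GATC",
                        score = 95, ipd_ratio = 5.5, coverage = 57) {
  methylated <- rep(c(TRUE, FALSE), c(n_detected, n_genome - n_detected))
  data.frame(contig = "c1", strand = "+",
             match_start = seq_len(n_genome) * 10L,
             methyl_pos = seq_len(n_genome) * 10L + 1L,
             motif = motif, methylated = methylated,
             score = ifelse(methylated, score, NA_real_),
             ipd_ratio = ifelse(methylated, ipd_ratio, NA_real_),
             coverage = ifelse(methylated, coverage, NA_real_),
             stringsAsFactors = FALSE)
}

# One plus-strand annotation data.frame in the internal convention.
make_annotations <- function(start, end, strand = "+", contig = "c1") {
  data.frame(feature_id = sprintf("g%d", seq_along(start)), contig = contig,
             start = as.integer(start), end = as.integer(end), strand = strand,
             type = "CDS", stringsAsFactors = FALSE)
}

# A simulation with u unmethylated GATC sites exactly, theta as given; the
# methylation fraction is derived from the realised site count so that u is
# pinned (the regime of interest fixes the count of unmethylated sites).
simulate_unmeth_regime <- function(seed, u = 77, theta = 10,
                                   genome_length = 250000) {
  cfg0 <- sim_config(genome_length = genome_length, seed = seed,
                     promoter_unmeth_weight = theta)
  genome <- generate_genome(cfg0)
  ann <- generate_annotations(cfg0, genome)
  n <- nrow(scan_motif(genome, cfg0$motifs[[1]]$spec))
  cfg <- sim_config(genome_length = genome_length, seed = seed,
                    promoter_unmeth_weight = theta,
                    motifs = list(list(spec = motif_spec("GATC", 1, "m6A"),
                                       fraction = 1 - u / n)))
  met <- generate_methylome(cfg, genome, ann)
  list(genome = genome, annotations = ann, met = met,
       truth = met$truth$sites$GATC)
}
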