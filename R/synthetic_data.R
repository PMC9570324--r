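# Seeded synthetic-data generator: genome, ORF annotations, and a methylome
# with known ground truth. The defaults state the world the analysis is built
# for: a GC ~ 0.44 bacterial chromosome whose GATC sites are methylated at
# fraction 0.998 with modification QVs around 95.6, IPD ratios around 5.52
# and coverage around 56.9, and a controllable excess (odds weight theta) of
# unmethylated sites in putative promoter windows.

#' Simulation configuration
#'
#' @param genome_length Genome length in bp.
#' @param gc_content GC fraction of the i.i.d. base model.
#' @param circular Is the simulated chromosome circular?
#' @param gene_length_range,intergenic_gap_range Uniform ranges (bp) for ORF
#'   lengths and intergenic gaps.
#' @param n_genes Optional cap on the number of ORFs (default: tile the whole
#'   genome).
#' @param motifs List of \code{list(spec = motif_spec(...), fraction = f)}
#'   entries; each motif is methylated at fraction \code{f}.
#' @param promoter_unmeth_weight Odds multiplier (theta >= 0) for an
#'   unmethylated site landing in a promoter window; 1 = no enrichment.
#' @param score_dist,ipd_dist,coverage_dist \code{c(mean, sd)} of the
#'   methylated-call QV, IPD ratio and coverage distributions.
#' @param duplex_linked For palindromic motifs, draw one state per duplex
#'   (both strands share it) instead of independent per-strand states.
#' @param seed Integer seed fixing every draw (per-stage sub-seeds are derived
#'   from it).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 100000, gc_content = 0.44,
                       circular = TRUE,
                       gene_length_range = c(600, 1200),
                       intergenic_gap_range = c(100, 400),
                       n_genes = NULL,
                       motifs = list(list(spec = motif_spec("GATC", 1, "m6A"),
                                          fraction = 0.998)),
                       promoter_unmeth_weight = 1,
                       score_dist = c(mean = 95.6, sd = 20),
                       ipd_dist = c(mean = 5.52, sd = 1),
                       coverage_dist = c(mean = 56.9, sd = 10),
                       duplex_linked = FALSE,
                       seed = 1) {
  stopifnot(genome_length > 0, gc_content >= 0, gc_content <= 1,
            promoter_unmeth_weight >= 0,
            all(vapply(motifs, function(m)
              inherits(m$spec, "motif_spec") && m$fraction > 0 && m$fraction <= 1,
              logical(1))))
  seed <- as.integer(seed)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, circular = circular,
                 gene_length_range = gene_length_range,
                 intergenic_gap_range = intergenic_gap_range,
                 n_genes = n_genes, motifs = motifs,
                 promoter_unmeth_weight = promoter_unmeth_weight,
                 score_dist = score_dist, ipd_dist = ipd_dist,
                 coverage_dist = coverage_dist,
                 duplex_linked = isTRUE(duplex_linked), seed = seed),
            class = "sim_config")
}

#' The bundled "paper-like" preset
#'
#' A 2 Mb circular genome whose GATC methylome matches the published summary
#' statistics for a Dam methylome (fraction 0.998, mean QV 95.6, mean IPD
#' ratio 5.52, mean coverage 56.9) with promoter-enriched unmethylated sites.
#'
#' @param seed Integer seed.
#' @param genome_length Override the 2 Mb default (e.g. for quick runs).
#' @return A [sim_config].
#' @export
paper_like_config <- function(seed = 1, genome_length = 2e6) {
  sim_config(genome_length = genome_length, promoter_unmeth_weight = 10,
             seed = seed)
}

#' @noRd
stage_seed <- function(config, stage) {
  (config$seed %% 1000003L) * 1009L + stage
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC content; deterministic under the seed.
#'
#' @param config A [sim_config].
#' @return A [seq_record] named \code{"sim_contig_1"}.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 1L))
  gc <- config$gc_content
  bases <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq_record("sim_contig_1", paste(bases, collapse = ""),
             circular = config$circular)
}

#' Generate non-overlapping ORF annotations
#'
#' ORFs are tiled along the genome with intergenic gaps drawn from the
#' configured range and random strands, so that every gene has a well-defined
#' upstream promoter window.
#'
#' @param config A [sim_config].
#' @param genome The [seq_record] from [generate_genome()].
#' @return Annotation data.frame (0-based half-open), feature type CDS.
#' @export
generate_annotations <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "seq_record"))
  set.seed(stage_seed(config, 2L))
  L <- nchar(genome$sequence)
  glr <- config$gene_length_range
  igr <- config$intergenic_gap_range
  if (glr[1] + igr[1] > L) stop("infeasible config: one gene does not fit")
  pos <- 0L
  starts <- integer(); ends <- integer(); strands <- character()
  repeat {
    gap <- if (igr[2] > igr[1]) sample(igr[1]:igr[2], 1L) else igr[1]
    len <- if (glr[2] > glr[1]) sample(glr[1]:glr[2], 1L) else glr[1]
    s <- pos + gap
    e <- s + len
    if (e > L) break
    if (!is.null(config$n_genes) && length(starts) >= config$n_genes) break
    starts <- c(starts, s); ends <- c(ends, e)
    strands <- c(strands, sample(c("+", "-"), 1L))
    pos <- e
  }
  if (length(starts) == 0L) stop("infeasible config: no gene fits")
  data.frame(feature_id = sprintf("gene_%04d", seq_along(starts)),
             contig = genome$id, start = starts, end = ends,
             strand = strands, type = "CDS", stringsAsFactors = FALSE)
}

#' Generate a methylome with ground truth
#'
#' For each configured motif all sites are enumerated; \code{u =
#' round((1 - f) * nGenome)} unmethylated sites are drawn without replacement
#' with per-site weight theta for promoter-context sites and 1 otherwise.
#' Methylated sites emit calls with QV drawn from the score distribution and
#' floored just above the QV-30 threshold, truncated-normal IPD ratios (> 1)
#' and coverage (>= 1). Unmethylated sites emit either nothing or, with
#' probability 0.5, a sub-threshold call (QV < 30), so the filter boundary is
#' exercised. Calls carry +/-20 bp context strings in call orientation.
#'
#' @param config A [sim_config].
#' @param genome,annotations Output of the generator stages above.
#' @return List with \code{calls} (modification-record data.frame, above- and
#'   sub-threshold together) and \code{truth} (per-motif site tables with true
#'   state and context label, plus the planted specs).
#' @export
generate_methylome <- function(config, genome, annotations) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "seq_record"))
  set.seed(stage_seed(config, 3L))
  theta <- config$promoter_unmeth_weight
  all_calls <- list()
  truth_sites <- list()
  for (mi in seq_along(config$motifs)) {
    spec <- config$motifs[[mi]]$spec
    f <- config$motifs[[mi]]$fraction
    occ <- scan_motif(genome, spec)
    n <- nrow(occ)
    if (n == 0L) stop("motif ", spec$iupac, " does not occur in the genome")
    lab <- classify_position(genome$id, occ$methyl_pos, annotations)$label
    u <- round((1 - f) * n)
    if (u > n) stop("unmethylated count exceeds site count")
    methylated <- rep(TRUE, n)
    if (u > 0L) {
      w <- ifelse(lab == "promoter", theta, 1)
      if (sum(w > 0) < u) stop("infeasible: not enough positive-weight sites")
      unmeth_idx <- sample.int(n, u, prob = w)
      if (config$duplex_linked && is_partner(spec, spec)) {
        # one state per duplex: mirror the drawn states onto the paired strand
        unmeth_idx <- which(occ$match_start %in% occ$match_start[unmeth_idx])
      }
      methylated[unmeth_idx] <- FALSE
    }
    nm <- sum(methylated)
    qv <- pmax(rnorm(nm, config$score_dist[["mean"]], config$score_dist[["sd"]]),
               30 + runif(nm))
    ipd <- pmax(rnorm(nm, config$ipd_dist[["mean"]], config$ipd_dist[["sd"]]),
                1 + runif(nm, 0.01, 0.5))
    cov <- pmax(round(rnorm(nm, config$coverage_dist[["mean"]],
                            config$coverage_dist[["sd"]])), 1)
    ctx <- call_contexts(
      data.frame(position = occ$methyl_pos, strand = occ$strand,
                 context = NA_character_, stringsAsFactors = FALSE),
      genome, 20L)
    m_calls <- data.frame(contig = occ$contig[methylated],
                          position = occ$methyl_pos[methylated],
                          strand = occ$strand[methylated],
                          mod_type = spec$mod_type,
                          score = round(qv),
                          ipd_ratio = round(ipd, 2),
                          coverage = as.integer(cov),
                          context = ctx[methylated],
                          stringsAsFactors = FALSE)
    un <- which(!methylated)
    sub <- un[runif(length(un)) < 0.5]
    u_calls <- if (length(sub)) {
      data.frame(contig = occ$contig[sub],
                 position = occ$methyl_pos[sub],
                 strand = occ$strand[sub],
                 mod_type = spec$mod_type,
                 score = round(runif(length(sub), 5, 29)),
                 ipd_ratio = round(pmax(rnorm(length(sub), 1.5, 0.3), 1.01), 2),
                 coverage = as.integer(pmax(round(
                   rnorm(length(sub), config$coverage_dist[["mean"]],
                         config$coverage_dist[["sd"]])), 1)),
                 context = ctx[sub],
                 stringsAsFactors = FALSE)
    } else NULL
    all_calls[[mi]] <- rbind(m_calls, u_calls)
    site_tab <- occ
    site_tab$methylated <- methylated
    site_tab$context_label <- lab
    truth_sites[[spec$iupac]] <- site_tab
  }
  calls <- do.call(rbind, all_calls)
  calls <- calls[order(calls$position, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       truth = list(sites = truth_sites,
                    motifs = lapply(config$motifs, `[[`, "spec")))
}

#' Write a complete synthetic fixture to a directory
#'
#' Emits \code{genome.fasta}, \code{annotations.gff3},
#' \code{modifications.gff} and \code{truth.json}; the files parse back
#' through the I/O layer into the generated objects.
#'
#' @param config A [sim_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory objects
#'   (\code{genome}, \code{annotations}, \code{calls}, \code{truth}).
#' @export
make_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  ann <- generate_annotations(config, genome)
  met <- generate_methylome(config, genome, ann)
  paths <- c(fasta = file.path(out_dir, "genome.fasta"),
             gff = file.path(out_dir, "annotations.gff3"),
             mods = file.path(out_dir, "modifications.gff"),
             truth = file.path(out_dir, "truth.json"))
  write_fasta(genome, paths[["fasta"]])
  write_gff3_annotations(ann, paths[["gff"]])
  write_modifications_gff(met$calls, paths[["mods"]])
  truth_json <- list(
    motifs = lapply(met$truth$motifs, function(s)
      list(iupac = s$iupac, methyl_offset = s$methyl_offset,
           mod_type = s$mod_type)),
    sites = lapply(met$truth$sites, function(df)
      df[c("contig", "strand", "match_start", "methyl_pos", "methylated",
           "context_label")])
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, genome = genome, annotations = ann,
                 calls = met$calls, truth = met$truth))
}
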