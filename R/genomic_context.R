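# Classification of motif sites relative to ORFs (putative promoter /
# gene body / intergenic) and Fisher exact testing of promoter enrichment of
# unmethylated sites. "Putative promoter" is the window strictly less than
# 100 bp upstream of an annotated start codon (distances 1..99 bp by default,
# strand-aware); positions >= 100 bp from a start or downstream of an ORF are
# intergenic unless inside an ORF.

#' Classify genomic positions relative to ORFs
#'
#' A position is \code{promoter} iff it lies 1..\code{promoter_window} bp
#' upstream of some ORF start codon (for a plus-strand gene the window is
#' \code{[start - w, start - 1]}; for a minus-strand gene \code{[end, end + w
#' - 1]} in plus coordinates); otherwise \code{gene_body} iff inside an ORF
#' interval; otherwise \code{intergenic}. Promoter takes precedence over
#' gene body. The reported feature is the ORF justifying the label (closest
#' start on ties) and \code{distance_to_start} is signed, negative upstream.
#'
#' @param contig Contig id (scalar).
#' @param pos Vector of 0-based positions.
#' @param annotations Annotation data.frame from [read_gff3_annotations()].
#' @param promoter_window Upstream window width in bp (default 99).
#' @param contig_length Optional length for bounds checking.
#' @return Data.frame with \code{position, label, feature_id,
#'   distance_to_start}.
#' @export
classify_position <- function(contig, pos, annotations, promoter_window = 99,
                              contig_length = NULL) {
  if (!is.null(contig_length) && any(pos < 0L | pos >= contig_length)) {
    stop("position outside contig ", contig)
  }
  ann <- annotations[annotations$contig == contig, , drop = FALSE]
  n <- length(pos)
  out <- data.frame(position = pos,
                    label = rep("intergenic", n),
                    feature_id = NA_character_,
                    distance_to_start = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) return(out)

  plus <- ann$strand == "+"
  # start codon position, 0-based
  start_codon <- ifelse(plus, ann$start, ann$end - 1L)
  # promoter windows, 1-based inclusive IRanges
  prom_start <- ifelse(plus, ann$start - promoter_window, ann$end) + 1L
  prom_end <- ifelse(plus, ann$start - 1L, ann$end + promoter_window - 1L) + 1L
  prom <- IRanges::IRanges(start = pmax(prom_start, 1L), end = prom_end)
  body <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)

  hit_p <- IRanges::findOverlaps(q, prom)
  if (length(hit_p)) {
    qi <- S4Vectors::queryHits(hit_p)
    si <- S4Vectors::subjectHits(hit_p)
    updist <- abs(pos[qi] - start_codon[si])  # 1..promoter_window
    best <- tapply(seq_along(qi), qi, function(ii) ii[which.min(updist[ii])])
    qi_b <- qi[unlist(best)]
    si_b <- si[unlist(best)]
    out$label[qi_b] <- "promoter"
    out$feature_id[qi_b] <- ann$feature_id[si_b]
    out$distance_to_start[qi_b] <- -abs(pos[qi_b] - start_codon[si_b])
  }

  rest <- out$label != "promoter"
  hit_b <- IRanges::findOverlaps(q[rest], body)
  if (length(hit_b)) {
    idx_rest <- which(rest)
    qi <- idx_rest[S4Vectors::queryHits(hit_b)]
    si <- S4Vectors::subjectHits(hit_b)
    d <- abs(pos[qi] - start_codon[si])
    best <- tapply(seq_along(qi), qi, function(ii) ii[which.min(d[ii])])
    qi_b <- qi[unlist(best)]
    si_b <- si[unlist(best)]
    out$label[qi_b] <- "gene_body"
    out$feature_id[qi_b] <- ann$feature_id[si_b]
    out$distance_to_start[qi_b] <- abs(pos[qi_b] - start_codon[si_b])
  }
  out
}

#' Tabulate context labels of motif occurrences
#'
#' Classifies each occurrence at its methylated position; the three counts
#' always partition the input.
#'
#' @param occurrences Occurrence data.frame from [scan_motif()].
#' @param annotations Annotation data.frame.
#' @param promoter_window Upstream window width, see [classify_position()].
#' @return Named integer vector \code{c(promoter, gene_body, intergenic)}.
#' @export
tabulate_contexts <- function(occurrences, annotations, promoter_window = 99) {
  counts <- c(promoter = 0L, gene_body = 0L, intergenic = 0L)
  if (nrow(occurrences) == 0L) return(counts)
  for (ctg in unique(occurrences$contig)) {
    sel <- occurrences$contig == ctg
    lab <- classify_position(ctg, occurrences$methyl_pos[sel], annotations,
                             promoter_window)$label
    t <- table(factor(lab, levels = names(counts)))
    counts <- counts + as.integer(t)
  }
  counts
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test with fixed margins. The two-sided p-value
#' follows the point-probability rule: the sum over all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7). The odds ratio is the sample odds ratio
#' \code{(a d)/(b c)}, \code{Inf} when \code{b c = 0} and \code{a d > 0}.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"} (for the [1,1] cell).
#' @return List with \code{p_value}, \code{odds_ratio}, \code{alternative}.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (sum(table) == 0L) stop("all-zero contingency table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
              greater = sum(probs[x >= a]),
              less = sum(probs[x <= a]))
  p <- min(p, 1)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  list(p_value = p, odds_ratio = or, alternative = alternative)
}

#' Test promoter enrichment of unmethylated motif sites
#'
#' Builds the 2x2 table of promoter vs gene-body counts (intergenic sites are
#' excluded, matching the convention of comparing "upstream region vs gene
#' body") for the unmethylated set against a reference set — all motif sites
#' (default) or the methylated sites only — and runs the two-sided Fisher
#' exact test.
#'
#' @param unmethylated Occurrences of unmethylated sites
#'   (see [find_unmethylated()]); must be a subset of \code{all_sites}.
#' @param all_sites All occurrences of the motif.
#' @param annotations Annotation data.frame.
#' @param mode \code{"vs_all"} (reference = all sites, as the published figure
#'   convention does, unmethylated included) or \code{"vs_methylated"}.
#' @param promoter_window Upstream window width, see [classify_position()].
#' @return List with \code{table} (2x2), \code{odds_ratio}, \code{p_value},
#'   \code{alternative}.
#' @export
promoter_enrichment <- function(unmethylated, all_sites, annotations,
                                mode = c("vs_all", "vs_methylated"),
                                promoter_window = 99) {
  mode <- match.arg(mode)
  if (nrow(unmethylated) == 0L) stop("empty unmethylated set")
  reference <- if (mode == "vs_all") {
    all_sites
  } else {
    key <- function(d) paste(d$contig, d$methyl_pos, d$strand, sep = "\r")
    all_sites[!key(all_sites) %in% key(unmethylated), , drop = FALSE]
  }
  cu <- tabulate_contexts(unmethylated, annotations, promoter_window)
  cr <- tabulate_contexts(reference, annotations, promoter_window)
  tab <- matrix(c(cu[["promoter"]], cu[["gene_body"]],
                  cr[["promoter"]], cr[["gene_body"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("unmethylated", "reference"),
                                c("promoter", "gene_body")))
  ft <- fisher_exact(tab, "two.sided")
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       alternative = "two.sided")
}
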