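# Simplified kinetic modification calling. SMRT polymerase kinetics slow down
# at methylated bases, elevating inter-pulse durations (IPDs); sites are
# scored by a one-sided Welch t-test of the observed IPDs against an
# in-silico reference (supplied as per-position moments), and the p-value is
# expressed as a Phred-scaled modification QV. QV >= 30 (p <= 0.001) is the
# conventional calling threshold.

#' Welch's t-test of sample IPDs against reference moments
#'
#' One-sided: the alternative is that the sample mean exceeds the reference
#' mean (methylation elevates IPD).
#'
#' @param sample_ipds Numeric vector of observed IPDs (length >= 1).
#' @param ref_mean,ref_sd In-silico reference IPD moments for this position.
#' @param ref_n Effective reference sample size.
#' @return List with \code{t}, \code{df} (Welch-Satterthwaite) and the
#'   one-sided upper-tail \code{p}, clamped to \code{[1e-300, 1]}.
#' @export
welch_test <- function(sample_ipds, ref_mean, ref_sd, ref_n) {
  n <- length(sample_ipds)
  stopifnot(n >= 1L, ref_sd >= 0, ref_n >= 1)
  s2 <- if (n >= 2L) stats::var(sample_ipds) else 0
  if (n < 2L && ref_sd == 0) {
    stop("undefined test: sample size < 2 with zero reference variance")
  }
  res <- welch_moments(mean(sample_ipds), s2, n, ref_mean, ref_sd^2, ref_n)
  list(t = res$t, df = res$df, p = res$p)
}

# Vectorised Welch test on moments; the workhorse behind welch_test() and
# detect_modifications().
#' @noRd
welch_moments <- function(m, s2, n, ref_mean, ref_var, ref_n) {
  v1 <- s2 / n
  v2 <- ref_var / ref_n
  se2 <- v1 + v2
  t <- ifelse(se2 > 0, (m - ref_mean) / sqrt(se2),
              ifelse(m == ref_mean, 0, sign(m - ref_mean) * Inf))
  df_num <- se2^2
  df_den <- ifelse(n > 1, v1^2 / (n - 1), 0) +
    ifelse(ref_n > 1, v2^2 / (ref_n - 1), 0)
  df <- ifelse(df_den > 0, df_num / df_den, 1)
  p <- ifelse(se2 > 0, stats::pt(t, df, lower.tail = FALSE),
              ifelse(m == ref_mean, 1, ifelse(m > ref_mean, 0, 1)))
  p <- pmin(pmax(p, 1e-300), 1)
  list(t = t, df = df, p = p)
}

#' Convert a p-value to a Phred-scaled modification QV
#'
#' \code{QV = -10 log10(p)}; QV 30 corresponds to p = 0.001. The value is
#' returned unrounded (filtering is done on the unrounded QV); set
#' \code{round = TRUE} for the integer reporting convention.
#'
#' @param p P-value(s) in (0, 1].
#' @param round Round to the nearest integer for reporting.
#' @return Numeric QV(s).
#' @export
pvalue_to_qv <- function(p, round = FALSE) {
  if (any(p <= 0)) stop("p-value must be > 0")
  qv <- -10 * log10(p)
  if (round) round(qv) else qv
}

#' Convert a modification QV back to a p-value
#' @param qv Phred QV(s), >= 0.
#' @return \code{10^(-qv/10)}.
#' @export
qv_to_pvalue <- function(qv) {
  if (any(qv < 0)) stop("QV must be >= 0")
  10^(-qv / 10)
}

#' Construct a call filter
#'
#' The default keeps adenine/cytosine modification calls with QV >= 30; the
#' coverage constraints of the sequencing protocol apply upstream of this
#' artifact, so \code{min_coverage} defaults to 0.
#'
#' @param min_qv Minimum Phred QV (applied to the unrounded score).
#' @param allowed_types Retained modification types.
#' @param min_coverage Minimum read coverage.
#' @return An object of class \code{call_filter}.
#' @export
call_filter <- function(min_qv = 30, allowed_types = c("m6A", "m4C"),
                        min_coverage = 0) {
  stopifnot(min_qv >= 0, all(allowed_types %in% MOD_TYPES), min_coverage >= 0)
  structure(list(min_qv = min_qv, allowed_types = allowed_types,
                 min_coverage = min_coverage),
            class = "call_filter")
}

#' Call modified bases from IPD observations
#'
#' One candidate per (position, strand); the score is the Phred QV of the
#' one-sided Welch p-value, the modification type is assigned from the genomic
#' base under the call in read orientation (A -> m6A, C -> m4C, anything else
#' \code{modified_base}), the IPD ratio is \code{sampleMean/refMean} and the
#' coverage is the number of IPD observations. Filtering happens on the
#' unrounded QV; the returned score is rounded to the nearest integer
#' (reporting convention).
#'
#' @param observations Data.frame with columns \code{contig, position, strand,
#'   ipds} (list column of numeric vectors, or a ";"-separated string),
#'   \code{ref_mean, ref_sd, ref_n}.
#' @param genome A [seq_record].
#' @param filter A [call_filter]; pass \code{call_filter(min_qv = 0,
#'   allowed_types = MOD_TYPES)} to keep every candidate.
#' @return A modification-record data.frame (see [read_modifications()]).
#' @export
detect_modifications <- function(observations, genome, filter = call_filter()) {
  stopifnot(inherits(genome, "seq_record"), inherits(filter, "call_filter"))
  obs <- observations
  if (nrow(obs) == 0L) return(empty_modifications())
  L <- nchar(genome$sequence)
  if (any(obs$position < 0L | obs$position >= L)) {
    stop("observation position outside contig ", genome$id)
  }
  ipds <- obs$ipds
  if (!is.list(ipds)) {
    ipds <- lapply(strsplit(as.character(ipds), ";", fixed = TRUE), as.numeric)
  }
  n <- lengths(ipds)
  m <- vapply(ipds, mean, numeric(1))
  s2 <- vapply(ipds, function(x) if (length(x) >= 2L) stats::var(x) else 0,
               numeric(1))
  res <- welch_moments(m, s2, n, obs$ref_mean, obs$ref_sd^2, obs$ref_n)
  qv <- pvalue_to_qv(res$p)

  base <- substring(genome$sequence, obs$position + 1L, obs$position + 1L)
  minus <- obs$strand == "-"
  base[minus] <- unname(IUPAC_COMPLEMENT[base[minus]])
  mod_type <- ifelse(base == "A", "m6A", ifelse(base == "C", "m4C", "modified_base"))

  keep <- qv >= filter$min_qv & mod_type %in% filter$allowed_types &
    n >= filter$min_coverage
  data.frame(contig = obs$contig[keep],
             position = obs$position[keep],
             strand = obs$strand[keep],
             mod_type = mod_type[keep],
             score = round(qv[keep]),
             ipd_ratio = m[keep] / obs$ref_mean[keep],
             coverage = as.integer(n[keep]),
             context = rep(NA_character_, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Filter modification records
#'
#' Keeps records with \code{score >= min_qv}, an allowed modification type and
#' \code{coverage >= min_coverage}; the threshold is inclusive and input order
#' is preserved.
#'
#' @param records Modification-record data.frame.
#' @param filter A [call_filter].
#' @return The filtered data.frame.
#' @export
filter_calls <- function(records, filter = call_filter()) {
  stopifnot(inherits(filter, "call_filter"))
  keep <- records$score >= filter$min_qv &
    records$mod_type %in% filter$allowed_types &
    records$coverage >= filter$min_coverage
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
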