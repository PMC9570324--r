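# IUPAC motif representation and strand-aware genome scanning. A motif is an
# IUPAC string plus the 0-based offset of its methylated base; scanning
# enumerates per-strand sites (a palindromic duplex locus yields two sites,
# one per strand), which is the counting convention behind nGenome in
# methylome summary tables.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

#' Create a motif specification
#'
#' @param iupac Motif string over the IUPAC alphabet, length >= 2.
#' @param methyl_offset 0-based index into \code{iupac} of the methylated base.
#' @param mod_type \code{"m6A"} or \code{"m4C"}; the IUPAC code at
#'   \code{methyl_offset} must be able to emit an A (m6A) or a C (m4C).
#' @param partner_iupac Optional partner motif string (the reverse complement
#'   marking the opposite strand of the same duplex recognition site).
#' @return An object of class \code{motif_spec}.
#' @export
motif_spec <- function(iupac, methyl_offset, mod_type = c("m6A", "m4C"),
                       partner_iupac = NULL) {
  mod_type <- match.arg(mod_type)
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) stop("motif must be at least 2 bp: ", iupac)
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown)) stop("unknown IUPAC code(s): ", paste(unknown, collapse = ""))
  methyl_offset <- as.integer(methyl_offset)
  if (methyl_offset < 0L || methyl_offset >= length(chars)) {
    stop("methyl_offset out of range for motif ", iupac)
  }
  need <- if (mod_type == "m6A") "A" else "C"
  if (!need %in% IUPAC_SETS[[chars[methyl_offset + 1L]]]) {
    stop("base at methyl_offset (", chars[methyl_offset + 1L],
         ") cannot be ", need, " as required for ", mod_type)
  }
  structure(list(iupac = iupac, methyl_offset = methyl_offset,
                 mod_type = mod_type, partner_iupac = partner_iupac),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s (offset %d, %s)%s\n", x$iupac, x$methyl_offset,
              x$mod_type,
              if (!is.null(x$partner_iupac)) paste0(" / ", x$partner_iupac) else ""))
  invisible(x)
}

#' Parse a motif given as "IUPAC:methylOffset:modType"
#' @param text e.g. \code{"GATC:1:m6A"}.
#' @return A [motif_spec].
#' @export
parse_motif <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("motif syntax is IUPAC:methylOffset:modType, got ", text)
  motif_spec(parts[[1]], as.integer(parts[[2]]), parts[[3]])
}

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' Complements every IUPAC code (N to N, R to Y, K to M, B to V, D to H, ...)
#' and reverses. The empty string maps to itself.
#'
#' @param seq IUPAC DNA string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  if (!nzchar(seq)) return(seq)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("unknown letter(s) in sequence: ",
         paste(unique(chars[is.na(comp)]), collapse = ""))
  }
  paste(rev(unname(comp)), collapse = "")
}

#' Test whether a genome window matches an IUPAC pattern
#'
#' A window letter matches iff it lies in the degeneracy set of the pattern
#' code. Pattern N matches A/C/G/T only: an N (or any ambiguity code) in the
#' genome never matches, since a modification call cannot sit on an ambiguous
#' base.
#'
#' @param pattern IUPAC string.
#' @param window Genome substring of equal length.
#' @return Logical scalar.
#' @export
iupac_match <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window lengths differ (", nchar(pattern), " vs ",
         nchar(window), ")")
  }
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  wc <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (!all(pc %in% names(IUPAC_SETS))) stop("unknown IUPAC code in pattern")
  all(mapply(function(p, w) w %in% IUPAC_SETS[[p]], pc, wc))
}

#' Are two motifs partners?
#'
#' Partner motifs are reverse complements of each other as IUPAC strings; they
#' mark the two strands of the same duplex recognition site. A palindrome is
#' its own partner.
#'
#' @param a,b [motif_spec] objects (or plain IUPAC strings).
#' @return Logical scalar.
#' @export
is_partner <- function(a, b) {
  sa <- if (inherits(a, "motif_spec")) a$iupac else toupper(a)
  sb <- if (inherits(b, "motif_spec")) b$iupac else toupper(b)
  identical(reverse_complement(sa), sb)
}

#' @noRd
empty_occurrences <- function(motif) {
  data.frame(contig = character(), strand = character(),
             match_start = integer(), methyl_pos = integer(),
             motif = character(), stringsAsFactors = FALSE)
}

#' Scan a genome for a motif on both strands
#'
#' A plus-strand occurrence starting at \code{s} has its methylatable base at
#' \code{s + methyl_offset}; a minus-strand occurrence (the pattern matches the
#' reverse complement of the window) at \code{s + L - 1 - methyl_offset}, all
#' in plus-strand 0-based coordinates. On circular contigs, windows spanning
#' the origin are scanned exactly once. Genome letters outside A/C/G/T never
#' match. Occurrences are sorted by (methyl_pos, strand).
#'
#' @param genome A [seq_record].
#' @param motif A [motif_spec].
#' @return Data.frame with columns \code{contig, strand, match_start,
#'   methyl_pos, motif}; the spec is attached as attribute \code{"motif_spec"}.
#' @export
scan_motif <- function(genome, motif) {
  stopifnot(inherits(genome, "seq_record"), inherits(motif, "motif_spec"))
  seq <- genome$sequence
  L <- nchar(seq)
  Lm <- nchar(motif$iupac)
  if (Lm > L) stop("motif longer than genome")
  subject_str <- if (genome$circular && Lm > 1L) {
    paste0(seq, substr(seq, 1L, Lm - 1L))
  } else {
    seq
  }
  subject <- Biostrings::DNAString(subject_str)
  bad_pos <- find_non_acgt(subject_str)

  starts_for <- function(pattern) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                     fixed = FALSE)
    s0 <- Biostrings::start(hits) - 1L   # 0-based window starts
    s0 <- s0[s0 < L]                     # each circular window counted once
    if (length(bad_pos) && length(s0)) {
      # drop windows containing any non-ACGT genome letter
      hit_bad <- vapply(s0, function(s) {
        any(bad_pos > s & bad_pos <= s + Lm)
      }, logical(1))
      s0 <- s0[!hit_bad]
    }
    s0
  }

  s_plus <- starts_for(motif$iupac)
  s_minus <- starts_for(reverse_complement(motif$iupac))

  occ <- data.frame(
    contig = rep(genome$id, length(s_plus) + length(s_minus)),
    strand = c(rep("+", length(s_plus)), rep("-", length(s_minus))),
    match_start = c(s_plus, s_minus),
    methyl_pos = c((s_plus + motif$methyl_offset) %% L,
                   (s_minus + Lm - 1L - motif$methyl_offset) %% L),
    motif = rep(motif$iupac, length(s_plus) + length(s_minus)),
    stringsAsFactors = FALSE
  )
  occ <- occ[order(occ$methyl_pos, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL
  attr(occ, "motif_spec") <- motif
  occ
}

#' @noRd
find_non_acgt <- function(s) {
  m <- gregexpr("[^ACGT]", s)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)  # 1-based positions
}
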