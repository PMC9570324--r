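# I/O layer: FASTA, GFF3 annotations, PacBio-style modifications.gff (and its
# CSV twin), BED6 / summary CSV / newick writers. This is the only file that
# converts between the internal 0-based half-open convention and the 1-based
# inclusive coordinates of GFF; everything downstream is 0-based.

MOD_TYPES <- c("m6A", "m4C", "modified_base")

# -- sequence records ----------------------------------------------------

#' Create a sequence record
#'
#' A minimal container for one contig: an id, an uppercase DNA sequence over
#' \code{A,C,G,T,N}, and a circularity flag (bacterial chromosomes are usually
#' a single circular contig).
#'
#' @param id Contig identifier.
#' @param sequence DNA string; lowercase accepted, uppercased on construction.
#' @param circular Logical flag, default \code{FALSE}.
#' @return An object of class \code{seq_record}.
#' @export
seq_record <- function(id, sequence, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty for contig '", id, "'")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("illegal letter '", substr(sequence, bad, bad), "' at position ",
         bad, " (1-based) in contig '", id, "'")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp%s\n", x$id, nchar(x$sequence),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a FASTA file into sequence records
#'
#' Circularity is taken from a \code{circular=true} token in the header line if
#' present, otherwise \code{FALSE}.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record] objects, in file order.
#' @export
read_fasta <- function(path) {
  # parsed by hand: the usual readers silently drop illegal letters, while
  # this contract requires a format error naming the offending position
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("FASTA format error: no records in ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[[1]]) stop("FASTA format error: missing header in ", path)
  rec_idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  lapply(seq_along(headers), function(i) {
    h <- headers[[i]]
    id <- sub("\\s.*$", "", h)
    circ <- grepl("circular=true", h, ignore.case = TRUE)
    body <- lines[rec_idx == i & !hdr]
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    tryCatch(seq_record(id, seq, circular = circ),
             error = function(e) stop("FASTA format error in ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
}

#' Write sequence records to FASTA
#' @param records List of [seq_record].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    tok <- if (r$circular) " circular=true" else ""
    writeLines(paste0(">", r$id, tok), con)
    # wrap at 70 columns
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(r$sequence, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}

# -- annotations ---------------------------------------------------------

#' Read gene annotations from GFF3
#'
#' Coordinates are converted from GFF3 1-based inclusive to the internal
#' 0-based half-open convention. Features whose type is not in
#' \code{keep_types} are dropped; kept features with undefined strand
#' (\code{"."}) are rejected with a warning reporting the count.
#'
#' @param path GFF3 file.
#' @param keep_types Character vector of feature types to retain.
#' @return A data.frame with columns \code{feature_id, contig, start, end,
#'   strand, type} (\code{start}/\code{end} 0-based half-open).
#' @export
read_gff3_annotations <- function(path, keep_types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[as.character(df$type) %in% keep_types, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(feature_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), type = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- as.character(df$strand)
  undef <- strand == "*"
  if (any(undef)) {
    warning(sum(undef), " feature(s) with undefined strand rejected")
    df <- df[!undef, , drop = FALSE]
    strand <- strand[!undef]
  }
  start0 <- df$start - 1L
  end0 <- df$end
  if (any(start0 >= end0)) stop("GFF3 format error: start > end")
  id <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  fallback <- sprintf("%s:%d-%d", as.character(df$seqnames), start0, end0)
  id <- ifelse(is.na(id) | !nzchar(id), fallback, id)
  out <- data.frame(feature_id = id,
                    contig = as.character(df$seqnames),
                    start = start0, end = end0,
                    strand = strand,
                    type = as.character(df$type),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write annotations as GFF3
#' @param annotations Annotation data.frame (0-based half-open).
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_gff3_annotations <- function(annotations, path, source = "methscan") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                     annotations$contig, source, annotations$type,
                     annotations$start + 1L, annotations$end,
                     annotations$strand, annotations$feature_id))
  writeLines(lines, path)
  invisible(path)
}

# -- modification calls --------------------------------------------------

#' @noRd
empty_modifications <- function() {
  data.frame(contig = character(), position = integer(), strand = character(),
             mod_type = character(), score = numeric(), ipd_ratio = numeric(),
             coverage = integer(), context = character(),
             stringsAsFactors = FALSE)
}

#' Read per-base modification calls
#'
#' Accepts the PacBio \code{modifications.gff} dialect (type column one of
#' \code{m6A}, \code{m4C}, \code{modified_base}; score column the modification
#' QV; \code{coverage}, \code{IPDRatio} and optionally \code{context} in the
#' attributes) as well as an equivalent CSV with headers
#' \code{contig,pos0,strand,type,score,ipdRatio,coverage}. GFF positions are
#' 1-based and converted to 0-based; CSV positions are already 0-based.
#' Records with an unknown type or missing coverage/IPDRatio attributes are
#' rejected with a warning reporting the counts.
#'
#' @param path Input file (dialect auto-detected).
#' @return A data.frame of modification records with columns
#'   \code{contig, position, strand, mod_type, score, ipd_ratio, coverage,
#'   context}.
#' @export
read_modifications <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) stop("modification format error: no records in ", path)
  if (grepl("contig\\s*,\\s*pos0", body[[1]])) {
    return(read_modifications_csv(path))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_cols <- lengths(fields) >= 9L
  if (!any(ok_cols)) stop("modification format error: not tab-delimited GFF in ", path)
  fields <- fields[ok_cols]
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  type <- m[, 3L]
  known <- type %in% MOD_TYPES
  if (any(!known)) warning(sum(!known), " record(s) with unknown call type rejected")
  attr9 <- m[, 9L]
  cov <- extract_attr(attr9, "coverage")
  ipd <- extract_attr(attr9, "IPDRatio")
  ctx <- extract_attr(attr9, "context", numeric = FALSE)
  has_attrs <- !is.na(cov) & !is.na(ipd)
  if (any(known & !has_attrs)) {
    warning(sum(known & !has_attrs),
            " record(s) missing coverage/IPDRatio attribute rejected")
  }
  keep <- known & has_attrs
  if (!any(keep)) stop("modification format error: no parsable records in ", path)
  out <- data.frame(contig = m[keep, 1L],
                    position = as.integer(m[keep, 4L]) - 1L,
                    strand = m[keep, 7L],
                    mod_type = type[keep],
                    score = as.numeric(m[keep, 6L]),
                    ipd_ratio = as.numeric(ipd[keep]),
                    coverage = as.integer(round(as.numeric(cov[keep]))),
                    context = ctx[keep],
                    stringsAsFactors = FALSE)
  validate_modifications(out)
}

#' @noRd
extract_attr <- function(attr_strings, key, numeric = TRUE) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regexec(pat, attr_strings)
  vals <- vapply(regmatches(attr_strings, m), function(x) {
    if (length(x) == 2L) x[[2L]] else NA_character_
  }, character(1))
  vals
}

#' @noRd
read_modifications_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos0", "strand", "type", "score", "ipdRatio", "coverage")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("modification CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  known <- df$type %in% MOD_TYPES
  if (any(!known)) warning(sum(!known), " record(s) with unknown call type rejected")
  df <- df[known, , drop = FALSE]
  if (nrow(df) == 0L) stop("modification format error: no parsable records in ", path)
  out <- data.frame(contig = as.character(df$contig),
                    position = as.integer(df$pos0),
                    strand = as.character(df$strand),
                    mod_type = as.character(df$type),
                    score = as.numeric(df$score),
                    ipd_ratio = as.numeric(df$ipdRatio),
                    coverage = as.integer(df$coverage),
                    context = if ("context" %in% names(df))
                      as.character(df$context) else NA_character_,
                    stringsAsFactors = FALSE)
  validate_modifications(out)
}

#' @noRd
validate_modifications <- function(df) {
  stopifnot(all(df$strand %in% c("+", "-")),
            all(df$score >= 0), all(df$coverage >= 1),
            all(df$ipd_ratio >= 0), all(df$position >= 0))
  rownames(df) <- NULL
  df
}

#' Write modification calls in the modifications.gff dialect
#' @param calls Modification record data.frame.
#' @param path Output path.
#' @export
write_modifications_gff <- function(calls, path) {
  ctx <- ifelse(is.na(calls$context) | !nzchar(calls$context), "",
                sprintf(";context=%s", calls$context))
  lines <- c("##gff-version 3",
             sprintf("%s\tkinModCall\t%s\t%d\t%d\t%s\t%s\t.\tcoverage=%d;IPDRatio=%.2f%s",
                     calls$contig, calls$mod_type,
                     calls$position + 1L, calls$position + 1L,
                     format(calls$score, trim = TRUE), calls$strand,
                     calls$coverage, calls$ipd_ratio, ctx))
  writeLines(lines, path)
  invisible(path)
}

# -- result writers ------------------------------------------------------

#' Write per-motif summaries as CSV
#'
#' Emits exactly the conventional eight-column summary table: Motif, Fraction,
#' nDetected, nGenome, Mean Score, Mean Ipd Ratio, Mean Coverage, Objective
#' Score.
#'
#' @param summaries Data.frame from [summarize_motif()] (rows may be stacked).
#' @param path Output path.
#' @export
write_motif_summaries <- function(summaries, path) {
  out <- data.frame(Motif = summaries$motif,
                    Fraction = summaries$fraction,
                    nDetected = summaries$n_detected,
                    nGenome = summaries$n_genome,
                    `Mean Score` = summaries$mean_score,
                    `Mean Ipd Ratio` = summaries$mean_ipd_ratio,
                    `Mean Coverage` = summaries$mean_coverage,
                    `Objective Score` = summaries$objective_score,
                    check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write motif site states as BED6
#'
#' One line per motif site, 0-based half-open over the methylated base. The
#' name column is the motif string, the score column \code{min(QV, 1000)} (0
#' for sites without a call).
#'
#' @param states Site-state data.frame from [assign_calls()].
#' @param path Output path.
#' @export
write_sites_bed <- function(states, path) {
  score <- ifelse(states$methylated, pmin(round(states$score), 1000), 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   states$contig, states$methyl_pos, states$methyl_pos + 1L,
                   states$motif, as.integer(score), states$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a tree as newick with branch lengths
#' @param tree An \code{ape} \code{phylo} object.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the standard result bundle to a directory
#'
#' @param out_dir Output directory (created if needed).
#' @param summaries Optional summary data.frame.
#' @param states Optional site-state data.frame (methylated and unmethylated
#'   sites go to one BED track).
#' @param tree Optional \code{phylo} tree.
#' @return Named character vector of the files written.
#' @export
write_outputs <- function(out_dir, summaries = NULL, states = NULL, tree = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(summaries)) {
    written["summary"] <- write_motif_summaries(summaries,
                                                file.path(out_dir, "motif_summary.csv"))
  }
  if (!is.null(states)) {
    written["sites"] <- write_sites_bed(states, file.path(out_dir, "motif_sites.bed"))
  }
  if (!is.null(tree)) {
    written["tree"] <- write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
  }
  written
}
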