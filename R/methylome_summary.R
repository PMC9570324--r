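# Joining filtered modification calls to motif sites, summary-table rows,
# unmethylated-site listing, and greedy de-novo motif discovery from call
# contexts.

#' Assign modification calls to motif sites
#'
#' A site is methylated iff a call exists at exactly its (contig, methyl_pos,
#' strand) with a modification type compatible with the motif: identical type,
#' or \code{modified_base} when the genomic base under the call (if a genome is
#' supplied) equals the motif's methylated base. Calls matching no site are
#' returned separately as off-motif calls. Duplicate calls at one (contig,
#' position, strand) keep the highest score, with a warning.
#'
#' @param occurrences Output of [scan_motif()].
#' @param calls Filtered modification records (see [filter_calls()]).
#' @param genome Optional [seq_record] used to resolve \code{modified_base}
#'   compatibility; without it, \code{modified_base} calls are accepted as
#'   compatible.
#' @return List with \code{states} (the occurrences plus \code{methylated},
#'   \code{score}, \code{ipd_ratio}, \code{coverage}) and \code{off_motif}
#'   (unassigned calls).
#' @export
assign_calls <- function(occurrences, calls, genome = NULL) {
  motif <- attr(occurrences, "motif_spec")
  key <- function(contig, pos, strand) paste(contig, pos, strand, sep = "\r")

  if (nrow(calls)) {
    ck <- key(calls$contig, calls$position, calls$strand)
    if (anyDuplicated(ck)) {
      warning(sum(duplicated(ck)), " duplicate call(s) at the same site; ",
              "keeping the highest score")
      o <- order(ck, -calls$score)
      calls <- calls[o, , drop = FALSE]
      ck <- ck[o]
      calls <- calls[!duplicated(ck), , drop = FALSE]
      ck <- ck[!duplicated(ck)]
    }
  } else {
    ck <- character()
  }

  compatible <- rep(TRUE, nrow(calls))
  if (!is.null(motif) && nrow(calls)) {
    same <- calls$mod_type == motif$mod_type
    modb <- calls$mod_type == "modified_base"
    if (!is.null(genome)) {
      base <- substring(genome$sequence, calls$position + 1L, calls$position + 1L)
      minus <- calls$strand == "-"
      base[minus] <- unname(IUPAC_COMPLEMENT[base[minus]])
      need <- if (motif$mod_type == "m6A") "A" else "C"
      modb <- modb & base == need
    }
    compatible <- same | modb
  }

  ok <- key(occurrences$contig, occurrences$methyl_pos, occurrences$strand)
  idx <- match(ok, ifelse(compatible, ck, NA_character_))
  states <- occurrences
  states$methylated <- !is.na(idx)
  states$score <- calls$score[idx]
  states$ipd_ratio <- calls$ipd_ratio[idx]
  states$coverage <- calls$coverage[idx]

  assigned <- stats::na.omit(idx)
  off <- calls[setdiff(seq_len(nrow(calls)), assigned), , drop = FALSE]
  rownames(off) <- NULL
  attr(states, "motif_spec") <- motif
  list(states = states, off_motif = off)
}

#' Summarise the methylation state of one motif
#'
#' Produces the conventional summary-table row: fraction (reported rounded
#' half-up to 3 decimals, kept unrounded in \code{fraction_raw}), detected and
#' genome-wide site counts, means of score / IPD ratio / coverage over
#' detected sites, and the heuristic objective score
#' \code{round(fraction * sum(detected scores))}.
#'
#' @param states Site-state data.frame from [assign_calls()], all sharing one
#'   motif.
#' @return One-row data.frame.
#' @export
summarize_motif <- function(states) {
  if (nrow(states) == 0L) stop("no sites: motif absent from genome")
  n_genome <- nrow(states)
  n_detected <- sum(states$methylated)
  fraction_raw <- n_detected / n_genome
  detected <- states[states$methylated, , drop = FALSE]
  score_sum <- sum(detected$score)
  data.frame(
    motif = states$motif[[1]],
    fraction = round_half_up(fraction_raw, 3),
    n_detected = n_detected,
    n_genome = n_genome,
    mean_score = if (n_detected) round_half_up(mean(detected$score), 1) else NA_real_,
    mean_ipd_ratio = if (n_detected) round_half_up(mean(detected$ipd_ratio), 2) else NA_real_,
    mean_coverage = if (n_detected) round_half_up(mean(detected$coverage), 1) else NA_real_,
    objective_score = round(fraction_raw * score_sum),
    fraction_raw = fraction_raw,
    stringsAsFactors = FALSE
  )
}

#' List unmethylated motif sites
#'
#' The exact complement of the methylated set, sorted by position.
#'
#' @param states Site-state data.frame from [assign_calls()].
#' @return Occurrence data.frame of the unmethylated sites.
#' @export
find_unmethylated <- function(states) {
  out <- states[!states$methylated,
                c("contig", "strand", "match_start", "methyl_pos", "motif"),
                drop = FALSE]
  out <- out[order(out$methyl_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_spec") <- attr(states, "motif_spec")
  out
}

# -- de novo motif discovery --------------------------------------------

#' Discover methylated motifs from call contexts
#'
#' Greedy discovery: every candidate pattern anchored at the methylated base
#' (contiguous ACGT words up to \code{max_contiguous_len}, plus bipartite
#' forms word1-N{g}-word2 with gap \code{g <= max_gap} and words up to
#' \code{max_word} bp) is supported by the calls whose context contains it at
#' the anchor. Candidates are evaluated genome-wide (scan + call assignment);
#' the candidate maximising the objective score subject to
#' \code{fraction >= min_fraction} is accepted, its explained calls removed,
#' and the loop repeats. Accepted non-palindromic motifs trigger a search for
#' their reverse-complement partner. Ties break to the higher objective score,
#' then the shorter pattern, then lexicographically.
#'
#' @param calls Filtered modification records; contexts are taken from the
#'   \code{context} column when present (odd length, call base centred, read
#'   in call orientation) and extracted from the genome otherwise.
#' @param genome A [seq_record].
#' @param min_fraction Minimum genome-wide methylated fraction for acceptance.
#' @param max_contiguous_len Maximum contiguous candidate length.
#' @param max_gap Maximum N-gap of bipartite candidates.
#' @param max_word Maximum word length of bipartite candidates.
#' @param min_sites Minimum genome-wide site count for a candidate; guards
#'   against near-unique long patterns that trivially reach fraction 1.
#' @param context_flank Context half-width used when extracting from genome.
#' @return List of accepted [motif_spec] objects (possibly empty); partners
#'   carry \code{partner_iupac}.
#' @export
discover_motifs <- function(calls, genome, min_fraction = 0.5,
                            max_contiguous_len = 8, max_gap = 9, max_word = 5,
                            min_sites = 5, context_flank = 20) {
  stopifnot(inherits(genome, "seq_record"))
  remaining <- calls
  accepted <- list()
  for (round in 1:10) {
    if (nrow(remaining) == 0L) break
    ctx <- call_contexts(remaining, genome, context_flank)
    usable <- !is.na(ctx)
    if (!any(usable)) break
    cand <- candidate_support(ctx[usable], remaining$score[usable],
                              max_contiguous_len, max_gap, max_word)
    best <- evaluate_candidates(cand, remaining, genome, min_fraction, min_sites)
    if (is.null(best)) break
    spec <- best$spec
    remaining <- remove_explained(remaining, genome, spec)
    partner <- NULL
    rc <- reverse_complement(spec$iupac)
    if (!identical(rc, spec$iupac)) {
      partner <- find_partner_motif(rc, remaining, genome, min_fraction, min_sites)
      if (!is.null(partner)) {
        spec$partner_iupac <- partner$iupac
        partner$partner_iupac <- spec$iupac
        remaining <- remove_explained(remaining, genome, partner)
      }
    } else {
      spec$partner_iupac <- spec$iupac
    }
    accepted <- c(accepted, list(spec), if (!is.null(partner)) list(partner))
  }
  accepted
}

# Context string per call, centred on the methylated base, read 5'->3' on the
# call's strand; NA when it cannot be extracted (linear genome edge).
#' @noRd
call_contexts <- function(calls, genome, flank) {
  have <- !is.na(calls$context) & nchar(calls$context) %% 2L == 1L &
    nchar(calls$context) >= 2L * flank + 1L
  ctx <- rep(NA_character_, nrow(calls))
  if (any(have)) {
    w <- calls$context[have]
    mid <- (nchar(w) + 1L) %/% 2L
    ctx[have] <- substring(w, mid - flank, mid + flank)
  }
  need <- !have
  if (any(need)) {
    seq <- genome$sequence
    L <- nchar(seq)
    p <- calls$position[need]
    if (genome$circular) {
      ext <- paste0(seq, seq, seq)
      win <- substring(ext, L + p + 1L - flank, L + p + 1L + flank)
    } else {
      lo <- p + 1L - flank
      hi <- p + 1L + flank
      win <- ifelse(lo >= 1L & hi <= L, substring(seq, lo, hi), NA_character_)
    }
    minus <- calls$strand[need] == "-"
    win[minus & !is.na(win)] <- vapply(win[minus & !is.na(win)],
                                       reverse_complement, character(1))
    ctx[need] <- win
  }
  ctx
}

# Enumerate anchored candidate patterns across contexts and accumulate, per
# unique (pattern, offset), the number of supporting calls and the sum of
# their scores (an upper bound on any objective score the candidate can get).
#' @noRd
candidate_support <- function(contexts, scores, max_k, max_gap, max_word) {
  flank <- (nchar(contexts[[1]]) - 1L) %/% 2L
  center <- flank + 1L  # 1-based anchor index in the context

  # relative candidate layouts, computed once
  layouts <- list()
  for (k in 2:max_k) {
    for (o in 0:(k - 1L)) {
      layouts[[length(layouts) + 1L]] <-
        list(s1 = center - o, e1 = center - o + k - 1L, gap = 0L,
             s2 = NA, e2 = NA, offset = o)
    }
  }
  for (a in 1:max_word) for (o1 in 0:(a - 1L)) for (g in 1:max_gap) {
    for (b in 1:max_word) {
      s1 <- center - o1
      layouts[[length(layouts) + 1L]] <-
        list(s1 = s1, e1 = s1 + a - 1L, gap = g,
             s2 = s1 + a + g, e2 = s1 + a + g + b - 1L, offset = o1)
    }
  }
  for (b in 1:max_word) for (o2 in 0:(b - 1L)) for (g in 1:max_gap) {
    for (a in 1:max_word) {
      s2 <- center - o2
      layouts[[length(layouts) + 1L]] <-
        list(s1 = s2 - g - a, e1 = s2 - g - 1L, gap = g,
             s2 = s2, e2 = s2 + b - 1L, offset = a + g + o2)
    }
  }

  width <- 2L * flank + 1L
  gapN <- vapply(1:max_gap, function(g) strrep("N", g), character(1))
  pat_list <- vector("list", length(layouts))
  for (i in seq_along(layouts)) {
    ly <- layouts[[i]]
    lo <- ly$s1
    hi <- if (is.na(ly$s2)) ly$e1 else ly$e2
    if (lo < 1L || hi > width) next
    w1 <- substring(contexts, ly$s1, ly$e1)
    pat <- if (is.na(ly$s2)) w1 else {
      paste0(w1, gapN[[ly$gap]], substring(contexts, ly$s2, ly$e2))
    }
    valid <- !grepl("[^ACGT]", if (is.na(ly$s2)) w1 else
      paste0(w1, substring(contexts, ly$s2, ly$e2)))
    if (!any(valid)) next
    pat_list[[i]] <- data.frame(id = paste0(pat[valid], ":", ly$offset),
                                score = scores[valid],
                                stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, pat_list[!vapply(pat_list, is.null, logical(1))])
  if (is.null(all) || nrow(all) == 0L) return(NULL)
  support <- rowsum(cbind(n = 1, s = all$score), all$id)
  data.frame(id = rownames(support), n = support[, "n"],
             score_sum = support[, "s"], stringsAsFactors = FALSE,
             row.names = NULL)
}

# Evaluate candidates in decreasing upper-bound order, with branch-and-bound
# pruning: a candidate's objective cannot exceed the summed scores of its
# supporting calls.
#' @noRd
evaluate_candidates <- function(cand, calls, genome, min_fraction,
                                min_sites = 5, max_eval = 200L) {
  if (is.null(cand)) return(NULL)
  cand <- cand[order(-cand$score_sum, nchar(cand$id), cand$id), , drop = FALSE]
  best <- NULL
  best_obj <- -Inf
  n_eval <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$score_sum[i] <= best_obj) break
    if (n_eval >= max_eval) break
    parts <- strsplit(cand$id[i], ":", fixed = TRUE)[[1]]
    pattern <- parts[[1]]
    offset <- as.integer(parts[[2]])
    anchor <- substr(pattern, offset + 1L, offset + 1L)
    if (!anchor %in% c("A", "C")) next
    mod_type <- if (anchor == "A") "m6A" else "m4C"
    spec <- motif_spec(pattern, offset, mod_type)
    occ <- scan_motif(genome, spec)
    if (nrow(occ) < min_sites) next
    st <- assign_calls(occ, calls, genome)$states
    frac <- mean(st$methylated)
    obj <- frac * sum(st$score[st$methylated])
    n_eval <- n_eval + 1L
    if (frac >= min_fraction) {
      better <- obj > best_obj ||
        (obj == best_obj && !is.null(best) &&
           (nchar(pattern) < nchar(best$spec$iupac) ||
              (nchar(pattern) == nchar(best$spec$iupac) &&
                 pattern < best$spec$iupac)))
      if (better) {
        best <- list(spec = spec, fraction = frac, objective = obj)
        best_obj <- obj
      }
    }
  }
  best
}

#' @noRd
remove_explained <- function(calls, genome, spec) {
  occ <- scan_motif(genome, spec)
  res <- assign_calls(occ, calls, genome)
  res$off_motif
}

# Look for the reverse-complement partner among the remaining calls: try every
# A/C anchor offset of the partner pattern and keep the best passing one.
#' @noRd
find_partner_motif <- function(rc_pattern, calls, genome, min_fraction,
                               min_sites = 5) {
  if (nrow(calls) == 0L) return(NULL)
  chars <- strsplit(rc_pattern, "", fixed = TRUE)[[1]]
  best <- NULL
  best_obj <- -Inf
  for (o in which(chars %in% c("A", "C")) - 1L) {
    spec <- motif_spec(rc_pattern, o, if (chars[o + 1L] == "A") "m6A" else "m4C")
    occ <- scan_motif(genome, spec)
    if (nrow(occ) < min_sites) next
    st <- assign_calls(occ, calls, genome)$states
    frac <- mean(st$methylated)
    obj <- frac * sum(st$score[st$methylated])
    if (frac >= min_fraction && obj > best_obj) {
      best <- spec
      best_obj <- obj
    }
  }
  best
}
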