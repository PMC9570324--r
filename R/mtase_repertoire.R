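# Comparative genomics of methyltransferase (MTase) repertoires:
# presence/absence profiling from ortholog-identity tables (BlastP-style,
# >70% identity), persistence across a genus, Jaccard-distance UPGMA
# clustering of MTase profiles, neighbor-joining genome trees from
# Mash-style distance matrices (D ~ 1 - ANI), and species clustering at a
# distance threshold.

#' Build an MTase presence/absence matrix from ortholog hits
#'
#' A cell is present iff some hit for that (MTase, genome) has percent
#' identity strictly greater than the threshold. The query's own genome, when
#' given via \code{origins}, is always present. MTase rows that end up absent
#' everywhere are dropped with a warning. Optionally, mutually orthologous
#' MTases can be collapsed into one row keyed by the lexicographically
#' smallest member id.
#'
#' @param hits Data.frame with columns \code{query_mtase, genome,
#'   percent_identity} (identities in \code{[0, 100]}).
#' @param threshold Identity threshold, default 70 (strict \code{>}).
#' @param origins Optional named character vector mapping MTase id to the
#'   genome that encodes it.
#' @param ortholog_groups Optional list of character vectors of MTase ids to
#'   merge (rows are OR-ed).
#' @return Logical matrix, MTase rows x genome columns.
#' @export
build_presence_absence <- function(hits, threshold = 70, origins = NULL,
                                   ortholog_groups = NULL) {
  stopifnot(all(c("query_mtase", "genome", "percent_identity") %in% names(hits)),
            all(hits$percent_identity >= 0 & hits$percent_identity <= 100))
  mtases <- sort(unique(c(hits$query_mtase, names(origins))))
  genomes <- sort(unique(c(hits$genome, unname(origins))))
  mat <- matrix(FALSE, nrow = length(mtases), ncol = length(genomes),
                dimnames = list(mtases, genomes))
  pass <- hits[hits$percent_identity > threshold, , drop = FALSE]
  if (nrow(pass)) {
    mat[cbind(match(pass$query_mtase, mtases), match(pass$genome, genomes))] <- TRUE
  }
  if (!is.null(origins)) {
    mat[cbind(match(names(origins), mtases), match(unname(origins), genomes))] <- TRUE
  }
  if (!is.null(ortholog_groups)) {
    for (grp in ortholog_groups) {
      grp <- sort(intersect(grp, rownames(mat)))
      if (length(grp) < 2L) next
      merged <- apply(mat[grp, , drop = FALSE], 2, any)
      mat <- mat[setdiff(rownames(mat), grp[-1]), , drop = FALSE]
      mat[grp[[1]], ] <- merged
    }
  }
  empty <- rowSums(mat) == 0L
  if (any(empty)) {
    warning(sum(empty), " MTase row(s) with no presence dropped")
    mat <- mat[!empty, , drop = FALSE]
  }
  mat
}

#' MTases present in every genome
#'
#' A persistent MTase is an ortholog present in all genomes of the set under
#' study (in the motivating genus, the solitary Dam MTase is the single
#' persistent one).
#'
#' @param matrix Logical presence/absence matrix (MTase x genome).
#' @return Character vector of persistent MTase ids (possibly empty).
#' @export
persistent_mtases <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1L)
  rownames(matrix)[rowSums(!matrix) == 0L]
}

#' Jaccard distance between two boolean profiles
#'
#' \code{1 - |A intersect B| / |A union B|}; two empty profiles are at
#' distance 0 by convention.
#'
#' @param a,b Logical vectors of equal length.
#' @return Distance in \code{[0, 1]}.
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profile lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  1 - sum(a & b) / u
}

#' Pairwise Jaccard distance matrix of presence/absence rows
#' @param matrix Logical matrix; distances are computed between rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jaccard_distance_matrix <- function(matrix) {
  n <- nrow(matrix)
  d <- base::matrix(0, n, n, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- jaccard_distance(matrix[i, ], matrix[j, ])
  }
  d
}

#' @noRd
check_dist_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            !is.null(rownames(d)), identical(rownames(d), colnames(d)))
  if (any(is.na(d))) stop("NaN/NA distance in matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a merged
#' cluster to the others is the size-weighted average, and the merge node sits
#' at height d/2 (so the output tree is ultrametric). Ties break to the pair
#' containing the lexicographically smallest member id.
#'
#' @param d Symmetric distance matrix with id dimnames, >= 2 ids.
#' @return A rooted ultrametric \code{ape} \code{phylo} tree.
#' @export
upgma <- function(d) {
  d <- check_dist_matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L)
  labels <- rownames(d)
  clusters <- lapply(labels, function(l) {
    list(newick = l, height = 0, size = 1L, min_id = l)
  })
  names(clusters) <- labels
  dd <- d
  while (length(clusters) > 1L) {
    ids <- names(clusters)
    k <- length(ids)
    best <- NULL
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dij <- dd[ids[i], ids[j]]
      cand_key <- sort(c(clusters[[ids[i]]]$min_id, clusters[[ids[j]]]$min_id))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (cand_key[1] < best$key[1] ||
            (cand_key[1] == best$key[1] && cand_key[2] < best$key[2])))) {
        best <- list(i = ids[i], j = ids[j], d = dij, key = cand_key)
      }
    }
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    h <- best$d / 2
    newick <- sprintf("(%s:%.10g,%s:%.10g)", ci$newick, max(h - ci$height, 0),
                      cj$newick, max(h - cj$height, 0))
    merged <- list(newick = newick, height = h, size = ci$size + cj$size,
                   min_id = min(ci$min_id, cj$min_id))
    others <- setdiff(names(clusters), c(best$i, best$j))
    new_id <- paste0("(", best$i, "+", best$j, ")")
    nd <- matrix(0, length(others) + 1L, length(others) + 1L,
                 dimnames = list(c(others, new_id), c(others, new_id)))
    if (length(others)) {
      nd[others, others] <- dd[others, others]
      w <- (ci$size * dd[best$i, others] + cj$size * dd[best$j, others]) /
        (ci$size + cj$size)
      nd[new_id, others] <- nd[others, new_id] <- w
    }
    clusters[[best$i]] <- NULL
    clusters[[best$j]] <- NULL
    clusters[[new_id]] <- merged
    dd <- nd
  }
  root <- clusters[[1]]
  ape::read.tree(text = paste0(root$newick, ";"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-matrix pair selection and
#' branch-length formulas; negative branch lengths are clamped to zero. Ties
#' in Q break to the lexicographically smallest id pair. Use [upgma()] for
#' fewer than 3 taxa.
#'
#' @param d Symmetric distance matrix with id dimnames, >= 3 ids.
#' @return An unrooted \code{ape} \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- check_dist_matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa; use upgma()")
  nodes <- as.list(rownames(d))
  names(nodes) <- rownames(d)
  dd <- d
  while (length(nodes) > 3L) {
    ids <- names(nodes)
    k <- length(ids)
    r <- rowSums(dd)
    best <- NULL
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      q <- (k - 2) * dd[i, j] - r[i] - r[j]
      key <- sort(c(ids[i], ids[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, q = q, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- 0.5 * dd[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    lj <- dd[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], li, nodes[[j]], lj)
    keep <- setdiff(seq_len(k), c(i, j))
    dnew <- 0.5 * (dd[i, keep] + dd[j, keep] - dd[i, j])
    new_id <- paste0("(", ids[i], "+", ids[j], ")")
    nd <- matrix(0, length(keep) + 1L, length(keep) + 1L,
                 dimnames = list(c(ids[keep], new_id), c(ids[keep], new_id)))
    nd[seq_along(keep), seq_along(keep)] <- dd[keep, keep]
    nd[new_id, seq_along(keep)] <- nd[seq_along(keep), new_id] <- pmax(dnew, 0)
    nodes <- c(nodes[keep], stats::setNames(list(newick), new_id))
    dd <- nd
  }
  ids <- names(nodes)
  la <- max(0.5 * (dd[1, 2] + dd[1, 3] - dd[2, 3]), 0)
  lb <- max(0.5 * (dd[1, 2] + dd[2, 3] - dd[1, 3]), 0)
  lc <- max(0.5 * (dd[1, 3] + dd[2, 3] - dd[1, 2]), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[[1]], la, nodes[[2]], lb, nodes[[3]], lc)
  ape::read.tree(text = newick)
}

#' Cluster genomes into species at a distance threshold
#'
#' Single-linkage connected components of the graph whose edges join genomes
#' with pairwise distance \code{<= threshold} (0.06, i.e. about 94% ANI, by
#' default).
#'
#' @param d Symmetric distance matrix with id dimnames.
#' @param threshold Inclusive distance threshold.
#' @return List of character vectors, one per cluster, each sorted; clusters
#'   ordered by their first id.
#' @export
cluster_species <- function(d, threshold = 0.06) {
  d <- check_dist_matrix(d)
  ids <- rownames(d)
  n <- length(ids)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] <= threshold) {
      old <- comp[j]; new <- comp[i]
      comp[comp == old] <- new
    }
  }
  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  names(groups) <- NULL
  groups
}
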