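test_that("build_presence_absence applies the strict >70% identity rule", {
  hits <- data.frame(query_mtase = c("M1", "M1", "M2"),
                     genome = c("gA", "gB", "gA"),
                     percent_identity = c(70.0, 70.1, 95),
                     stringsAsFactors = FALSE)
  mat <- build_presence_absence(hits)
  expect_false(mat["M1", "gA"])   # 70.0 is not > 70
  expect_true(mat["M1", "gB"])
  expect_true(mat["M2", "gA"])
})

test_that("origins force presence and empty rows are dropped with warning", {
  hits <- data.frame(query_mtase = c("M1", "M2"), genome = c("gB", "gB"),
                     percent_identity = c(80, 10), stringsAsFactors = FALSE)
  expect_warning(mat <- build_presence_absence(hits), "dropped")
  expect_equal(rownames(mat), "M1")
  mat2 <- build_presence_absence(hits, origins = c(M1 = "gA", M2 = "gA"))
  expect_true(mat2["M2", "gA"])   # own genome always present
  expect_false(mat2["M2", "gB"])
})

test_that("ortholog groups are OR-merged under the smallest id", {
  hits <- data.frame(query_mtase = c("M_b", "M_a"), genome = c("g1", "g2"),
                     percent_identity = c(90, 90), stringsAsFactors = FALSE)
  mat <- build_presence_absence(hits, ortholog_groups = list(c("M_b", "M_a")))
  expect_equal(rownames(mat), "M_a")
  expect_true(all(mat["M_a", c("g1", "g2")]))
})

test_that("persistent_mtases returns all-true rows", {
  mat <- rbind(dam = c(TRUE, TRUE, TRUE),
               hsdM = c(TRUE, FALSE, TRUE),
               rare = c(FALSE, FALSE, TRUE))
  colnames(mat) <- paste0("g", 1:3)
  expect_equal(persistent_mtases(mat), "dam")
  ident <- diag(3) > 0
  dimnames(ident) <- list(paste0("M", 1:3), paste0("g", 1:3))
  expect_length(persistent_mtases(ident), 0)
  single <- matrix(c(TRUE, TRUE), 2, 1,
                   dimnames = list(c("M1", "M2"), "g1"))
  expect_equal(persistent_mtases(single), c("M1", "M2"))
  # oracle identity: persistence = intersection of per-genome presence sets
  set.seed(17)
  m <- matrix(runif(60) > 0.35, 10, 6,
              dimnames = list(paste0("M", 1:10), paste0("g", 1:6)))
  inter <- Reduce(intersect, lapply(1:6, function(j) rownames(m)[m[, j]]))
  expect_setequal(persistent_mtases(m), inter)
})

test_that("jaccard_distance counts intersections over unions", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 0, 1)), 2 / 3)
  expect_equal(jaccard_distance(c(TRUE, FALSE), c(TRUE, FALSE)), 0)
  expect_equal(jaccard_distance(c(TRUE, FALSE), c(FALSE, TRUE)), 1)
  expect_equal(jaccard_distance(logical(3), logical(3)), 0)  # empty convention
  expect_error(jaccard_distance(c(TRUE), c(TRUE, FALSE)), "lengths differ")
})

test_that("jaccard_distance satisfies the triangle inequality (exhaustive, length 6)", {
  profiles <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
  # drop the empty profile: the metric property is claimed on non-empty ones
  profiles <- profiles[rowSums(profiles) > 0, ]
  n <- nrow(profiles)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- jaccard_distance(profiles[i, ], profiles[j, ])
  }
  viol <- 0
  for (j in seq_len(n)) {
    lhs <- d
    rhs <- outer(d[, j], d[j, ], `+`)
    viol <- viol + sum(lhs > rhs + 1e-12)
  }
  expect_equal(viol, 0)
})

test_that("upgma reproduces hand-computed merges", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  ids <- c("A", "B", "C")
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, dimnames = list(ids, ids))
  t3 <- upgma(d3)
  # ((A,B),C): A and B join at height .1, C at height .3
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.6)
  expect_equal(cp["B", "C"], 0.6)

  # duplicate profiles join first at height 0
  d0 <- matrix(c(0, 0, .5, 0, 0, .5, .5, .5, 0), 3, dimnames = list(ids, ids))
  t0 <- upgma(d0)
  expect_equal(ape::cophenetic.phylo(t0)["A", "B"], 0)
})

test_that("upgma trees are ultrametric and match average-linkage heights", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(4:9, 1)
    ids <- paste0("t", seq_len(n))
    x <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(ids, ids)
    tr <- upgma(d)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    # independent oracle: cophenetic distances from stats::hclust average linkage
    hc <- stats::hclust(as.dist(d), method = "average")
    expect_equal(as.matrix(stats::cophenetic(hc))[ids, ids],
                 ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-8)
  }
  dNA <- matrix(c(0, NaN, NaN, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(dNA), "NaN")
})

test_that("nj_tree matches the three-taxon closed form", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, dimnames = list(ids, ids))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "upgma")
})

test_that("nj_tree reconstructs additive distances exactly", {
  set.seed(12)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(tree)
    ids <- sort(rownames(d))
    d <- d[ids, ids]
    rec <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(rec)[ids, ids], d, tolerance = 1e-9)
  }
})

test_that("nj_tree agrees with the ape::nj oracle on random matrices", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    ids <- paste0("s", seq_len(n))
    x <- matrix(runif(n * 4), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(ids, ids)
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))[[1]], 0)
  }
})

test_that("NJ topology equals UPGMA topology on ultrametric input", {
  set.seed(31)
  for (i in 1:4) {
    n <- sample(4:7, 1)
    tree <- ape::rcoal(n)  # coalescent trees are ultrametric
    d <- ape::cophenetic.phylo(tree)
    ids <- sort(rownames(d))
    d <- d[ids, ids]
    nj_t <- nj_tree(d)
    up_t <- upgma(d)
    expect_equal(ape::dist.topo(ape::unroot(nj_t), ape::unroot(up_t))[[1]], 0)
  }
})

test_that("cluster_species builds single-linkage components at <= threshold", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, .05, .09, .05, 0, .05, .09, .05, 0), 3,
              dimnames = list(ids, ids))
  expect_equal(cluster_species(d), list(c("A", "B", "C")))  # chained linkage
  d2 <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(cluster_species(d2), list("A", "B"))
  d3 <- matrix(c(0, .06, .06, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(cluster_species(d3), list(c("A", "B")))  # boundary inclusive
})
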