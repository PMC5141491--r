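test_that("MST keeps the strongest links (weight = 1 - PLI)", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.9
  w["A", "C"] <- w["C", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- 0.4
  tr <- build_mst(w)
  expect_setequal(edge_key(tr$edges), c("1 2", "1 3"))   # AB and AC
  expect_error(build_mst(matrix(c(0, NA, NA, 0), 2)), "NA")
  # equal weights: still a valid spanning tree, resolved by the tie rule
  ones <- matrix(0.5, 4, 4); diag(ones) <- 0
  expect_equal(nrow(build_mst(ones)$edges), 3)
  expect_identical(build_mst(ones)$edges, build_mst(ones)$edges)
})

test_that("Kruskal equals the exhaustive minimum and igraph on random instances", {
  set.seed(41)
  g6 <- as.matrix(expand.grid(rep(list(1:6), 4)))
  for (r in 1:25) {
    w <- random_pli_matrix(6)
    tr <- build_mst(w)
    total <- sum(1 - w[tr$edges])
    best <- min(apply(g6, 1L, function(s) sum(1 - w[prufer_tree(s)$edges])))
    expect_equal(total, best)
    g <- igraph::graph_from_adjacency_matrix(1 - w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(total, sum(igraph::E(igraph::mst(g))$weight))
  }
})

test_that("topology metrics match closed forms for stars and paths", {
  star <- function(n) spanning_tree(cbind(1, 2:n), n)
  path <- function(n) spanning_tree(cbind(1:(n - 1), 2:n), n)
  expect_equal(leaf_fraction(star(5)), 4 / 5)
  expect_equal(leaf_fraction(path(5)), 2 / 5)
  expect_equal(leaf_fraction(spanning_tree(rbind(c(1, 2)), 2)), 1)
  expect_equal(tree_diameter(path(9)), 1)
  expect_equal(tree_diameter(star(9)), 2 / 8)
  expect_equal(tree_diameter(star(9), normalized = FALSE), 2)
  expect_equal(degree_divergence(star(8)), 8 / 2)
  expect_equal(degree_divergence(path(4)), 5 / 3)
  k1000 <- degree_divergence(path(1000))
  expect_gt(k1000, 1.99); expect_lt(k1000, 2)
  expect_equal(tree_hierarchy(star(12)), 0.5)
  expect_equal(tree_hierarchy(path(5)), 0.375)
  expect_error(tree_hierarchy(spanning_tree(rbind(c(1, 2)), 2)), "fewer than 3")
})

test_that("tree diameter agrees with an all-pairs BFS oracle on random trees", {
  set.seed(42)
  for (r in 1:20) {
    tr <- prufer_tree(sample(8, 6, replace = TRUE))
    g <- igraph::graph_from_edgelist(tr$edges, directed = FALSE)
    expect_equal(tree_diameter(tr, normalized = FALSE),
                 max(igraph::distances(g)))
    expect_equal(tree_betweenness(tr, normalized = FALSE),
                 unname(igraph::betweenness(g)))
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(43)
  tr <- prufer_tree(c(3, 1, 4, 2, 5))
  perm <- sample(7)
  tr2 <- spanning_tree(matrix(perm[tr$edges], ncol = 2), 7)
  for (f in list(leaf_fraction, tree_diameter, degree_divergence, tree_hierarchy))
    expect_equal(f(tr), f(tr2))
})

test_that("every tree's leaf fraction lies between the path and the star", {
  set.seed(44)
  for (r in 1:50) {
    tr <- prufer_tree(sample(9, 7, replace = TRUE))
    lf <- leaf_fraction(tr)
    expect_gte(lf, 2 / 9)
    expect_lte(lf, 8 / 9)
  }
})

test_that("dissimilarity is an edge-overlap pseudometric", {
  star4 <- spanning_tree(cbind(1, 2:4), 4)
  path4 <- spanning_tree(cbind(1:3, 2:4), 4)
  expect_equal(mst_dissimilarity(star4, star4), 0)
  expect_equal(mst_dissimilarity(star4, path4), 2 / 3)  # only edge (1,2) shared
  expect_equal(mst_dissimilarity(path4, star4), 2 / 3)
  a <- spanning_tree(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)
  b <- spanning_tree(rbind(c(1, 3), c(1, 4), c(2, 4)), 4)
  expect_equal(mst_dissimilarity(a, b), 1)              # edge-disjoint
  expect_error(mst_dissimilarity(star4, spanning_tree(cbind(1, 2:5), 5)),
               "same node set")
  # triangle inequality over random labelled trees
  set.seed(45)
  for (r in 1:30) {
    trees <- lapply(1:3, function(i) prufer_tree(sample(6, 4, replace = TRUE)))
    d12 <- mst_dissimilarity(trees[[1]], trees[[2]])
    d23 <- mst_dissimilarity(trees[[2]], trees[[3]])
    d13 <- mst_dissimilarity(trees[[1]], trees[[3]])
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("the reference tree is the MST of the mean control matrix", {
  set.seed(46)
  m <- random_pli_matrix(6)
  expect_identical(reference_tree(list(m))$edges, build_mst(m)$edges)
  expect_identical(reference_tree(list(m, m, m))$edges, build_mst(m)$edges)
  mats <- replicate(3, random_pli_matrix(6), simplify = FALSE)
  ref <- reference_tree(mats)
  avg <- Reduce(`+`, mats) / 3
  expect_identical(ref$edges, build_mst(avg)$edges)
  # and that MST is the exhaustive minimum for the averaged matrix
  expect_equal(sum(1 - avg[ref$edges]), exhaustive_mst_weight(avg))
  expect_error(reference_tree(list(m, random_pli_matrix(5))), "dimensions")
})

test_that("subject summaries average per-epoch metrics", {
  set.seed(47)
  m <- random_pli_matrix(8)
  same <- subject_mst_summary(list(m, m, m, m))
  expect_equal(same$subject$leaf_fraction, same$epoch$leaf_fraction[1])
  mats <- replicate(4, random_pli_matrix(8), simplify = FALSE)
  ref <- reference_tree(mats[1:2])
  s <- subject_mst_summary(mats, ref)
  expect_equal(s$subject$leaf_fraction, mean(s$epoch$leaf_fraction))
  expect_equal(s$subject$dissimilarity, mean(s$epoch$dissimilarity))
  expect_equal(nrow(s$epoch), 4)
  # mean-matrix aggregation builds one tree from the averaged matrix
  s2 <- subject_mst_summary(mats, ref, aggregation = "mean_matrix")
  tr <- build_mst(Reduce(`+`, mats) / 4)
  expect_equal(s2$subject$leaf_fraction, leaf_fraction(tr))
})

test_that("Pruefer decoding reproduces degrees and enumerates distinct trees", {
  # degree of node = multiplicity in the sequence + 1
  s <- c(2, 2, 5)
  tr <- prufer_tree(s)
  deg <- tabulate(tr$edges, 5)
  expect_equal(deg, c(1, 3, 1, 1, 2)[order(1:5)])
  # all 5^3 sequences give 125 distinct labelled trees (Cayley)
  g5 <- as.matrix(expand.grid(rep(list(1:5), 3)))
  keys <- apply(g5, 1L, function(q) paste(edge_key(prufer_tree(q)$edges), collapse = "|"))
  expect_equal(length(unique(keys)), 125)
})
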