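#' Spanning tree over a fixed node set
#'
#' @param edges two-column integer matrix of node indices (1-based), one row
#'   per edge; stored with the smaller index first and rows ordered.
#' @param n_nodes number of nodes.
#' @param labels optional node labels.
#' @return An object of class `spanning_tree`.
#' @export
spanning_tree <- function(edges, n_nodes, labels = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) != n_nodes - 1L)
    stop("a spanning tree on ", n_nodes, " nodes must have ", n_nodes - 1L, " edges")
  if (any(edges < 1L) || any(edges > n_nodes)) stop("edge endpoint out of range")
  edges <- t(apply(edges, 1L, sort))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (anyDuplicated(edges)) stop("duplicate edges")
  # connectivity check via union-find
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
    if (a == b) stop("edges contain a cycle")
    parent[a] <- b
  }
  structure(list(edges = edges, n_nodes = as.integer(n_nodes), labels = labels),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

tree_degrees <- function(tree) tabulate(tree$edges, nbins = tree$n_nodes)

tree_adjacency_list <- function(tree) {
  adj <- vector("list", tree$n_nodes)
  for (r in seq_len(nrow(tree$edges))) {
    i <- tree$edges[r, 1L]; j <- tree$edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

bfs_dist <- function(adj, from, n) {
  dist <- rep.int(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist
}

#' Minimum spanning tree of a PLI connectivity matrix
#'
#' Link weights are `1 - PLI`, so the MST keeps the strongest connections.
#' Kruskal's algorithm with a deterministic tie rule: candidate edges are
#' ordered by (weight, smaller node index, larger node index), making trees
#' reproducible even when PLI values tie.
#'
#' @param matrix symmetric PLI matrix (entries in `[0,1]`, zero diagonal), or
#'   any symmetric similarity matrix on the same scale.
#' @return A [spanning_tree()].
#' @export
build_mst <- function(matrix) {
  n <- nrow(matrix)
  if (n < 2L) stop("MST needs at least 2 nodes")
  if (anyNA(matrix)) stop("connectivity matrix contains NA")
  labels <- rownames(matrix)
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- 1 - matrix[ut]
  ord <- order(w, ut[, 1L], ut[, 2L])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  picked <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (e in ord) {
    a <- find(ut[e, 1L]); b <- find(ut[e, 2L])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      picked[k, ] <- c(ut[e, 1L], ut[e, 2L])
      if (k == n - 1L) break
    }
  }
  spanning_tree(picked, n, labels = labels)
}

#' MST topology descriptors
#'
#' Four dimensionless summaries of tree shape, all invariant to node
#' relabelling:
#' * `leaf_fraction()` — number of degree-1 nodes over total nodes; high for
#'   a star (centralized), `2/N` for a path (decentralized).
#' * `tree_diameter()` — longest shortest path in links; `normalized = TRUE`
#'   (default) divides by `N - 1` so a path scores 1.
#' * `degree_divergence()` — kappa, \eqn{\langle k^2\rangle/\langle k\rangle}
#'   over node degrees; broadness of the degree distribution.
#' * `tree_hierarchy()` — \eqn{L / (2 M B_{max})} with `L` leaves, `M = N-1`
#'   edges and `B_max` the maximum betweenness centrality normalized by
#'   `(N-1)(N-2)/2`; balances integration against hub overload, exactly 0.5
#'   for a star and tending to 0 for long paths.
#'
#' @param tree a [spanning_tree()].
#' @param normalized divide the link-count diameter by `N - 1`?
#' @return scalar metric value, or for [mst_metrics()] a named list
#'   `leaf_fraction`, `diameter`, `kappa`, `hierarchy`.
#' @name mst_metrics
NULL

#' @rdname mst_metrics
#' @export
leaf_fraction <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  sum(tree_degrees(tree) == 1L) / tree$n_nodes
}

#' @rdname mst_metrics
#' @export
tree_diameter <- function(tree, normalized = TRUE) {
  stopifnot(inherits(tree, "spanning_tree"))
  adj <- tree_adjacency_list(tree)
  # double BFS: farthest node from an arbitrary start is a diameter endpoint
  d1 <- bfs_dist(adj, 1L, tree$n_nodes)
  u <- which.max(d1)
  d2 <- bfs_dist(adj, u, tree$n_nodes)
  diam <- max(d2)
  if (normalized) diam / (tree$n_nodes - 1L) else diam
}

#' @rdname mst_metrics
#' @export
degree_divergence <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  k <- tree_degrees(tree)
  mean(k^2) / mean(k)
}

#' Betweenness centrality of every node of a tree
#'
#' For trees the betweenness of node `v` is the number of node pairs whose
#' unique path passes through `v`: with components of sizes
#' \eqn{c_1..c_m} after removing `v`, that is \eqn{\sum_{a<b} c_a c_b}.
#' `normalized = TRUE` divides by `(N-1)(N-2)/2`, the pair count excluding `v`.
#'
#' @param tree a [spanning_tree()].
#' @param normalized divide by `(N-1)(N-2)/2`?
#' @return numeric vector of betweenness values, one per node.
#' @export
tree_betweenness <- function(tree, normalized = TRUE) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n_nodes
  adj <- tree_adjacency_list(tree)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    sizes <- integer(0)
    seen <- rep.int(FALSE, n)
    seen[v] <- TRUE
    for (s in adj[[v]]) if (!seen[s]) {
      size <- 0L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        x <- queue[1L]; queue <- queue[-1L]
        size <- size + 1L
        for (w in adj[[x]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      sizes <- c(sizes, size)
    }
    tot <- sum(sizes)
    btw[v] <- (tot^2 - sum(sizes^2)) / 2
  }
  if (normalized) btw / ((n - 1) * (n - 2) / 2) else btw
}

#' @rdname mst_metrics
#' @export
tree_hierarchy <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n_nodes
  if (n < 3L) stop("tree hierarchy is undefined for fewer than 3 nodes")
  L <- sum(tree_degrees(tree) == 1L)
  M <- n - 1L
  bmax <- max(tree_betweenness(tree, normalized = TRUE))
  L / (2 * M * bmax)
}

#' @rdname mst_metrics
#' @export
mst_metrics <- function(tree, normalized = TRUE) {
  list(leaf_fraction = leaf_fraction(tree),
       diameter = tree_diameter(tree, normalized = normalized),
       kappa = degree_divergence(tree),
       hierarchy = tree_hierarchy(tree))
}

#' Reference MST from the control group
#'
#' Element-wise mean of all control PLI matrices (pooling subjects and
#' epochs), then the MST of the mean matrix.
#'
#' @param control_matrices list of equal-dimension PLI matrices.
#' @return A [spanning_tree()].
#' @export
reference_tree <- function(control_matrices) {
  if (!length(control_matrices)) stop("need at least one control matrix")
  dims <- vapply(control_matrices, nrow, integer(1))
  if (any(dims != dims[1])) stop("control matrices must share dimensions")
  build_mst(Reduce(`+`, control_matrices) / length(control_matrices))
}

#' MST dissimilarity against a reference tree
#'
#' `1 - |shared edges| / (N - 1)`: 0 for identical trees, 1 for edge-disjoint
#' ones. Symmetric, and a pseudometric on trees over a fixed node set.
#'
#' @param tree,reference [spanning_tree()]s on the same node set.
#' @return dissimilarity in `[0, 1]`.
#' @export
mst_dissimilarity <- function(tree, reference) {
  stopifnot(inherits(tree, "spanning_tree"), inherits(reference, "spanning_tree"))
  if (tree$n_nodes != reference$n_nodes)
    stop("trees must be over the same node set")
  if (!is.null(tree$labels) && !is.null(reference$labels) &&
      !identical(tree$labels, reference$labels))
    stop("trees must share node labels")
  key <- function(e) paste(e[, 1L], e[, 2L])
  shared <- length(intersect(key(tree$edges), key(reference$edges)))
  1 - shared / (tree$n_nodes - 1L)
}

#' Per-epoch and subject-level MST summary
#'
#' Builds the MST of every epoch's PLI matrix, computes the four topology
#' metrics and (optionally) the dissimilarity to a reference tree, and
#' aggregates to the subject level. Default aggregation averages the
#' per-epoch metrics; `aggregation = "mean_matrix"` instead builds one tree
#' from the epoch-mean matrix.
#'
#' @param matrices list of per-epoch PLI matrices for one subject.
#' @param reference optional reference [spanning_tree()].
#' @param aggregation `"metric_mean"` (default) or `"mean_matrix"`.
#' @param normalized passed to [tree_diameter()].
#' @return list with `epoch` (tibble, one row per epoch) and `subject`
#'   (named list of subject-level values).
#' @export
subject_mst_summary <- function(matrices, reference = NULL,
                                aggregation = c("metric_mean", "mean_matrix"),
                                normalized = TRUE) {
  aggregation <- match.arg(aggregation)
  if (!length(matrices)) stop("need at least one epoch matrix")
  vals <- vapply(matrices, function(mat) {
    tr <- build_mst(mat)
    m <- mst_metrics(tr, normalized = normalized)
    c(m$leaf_fraction, m$diameter, m$kappa, m$hierarchy,
      if (is.null(reference)) NA_real_ else mst_dissimilarity(tr, reference))
  }, numeric(5))
  epoch_tbl <- tibble::tibble(epoch = seq_along(matrices),
                              leaf_fraction = vals[1, ], diameter = vals[2, ],
                              kappa = vals[3, ], hierarchy = vals[4, ],
                              dissimilarity = vals[5, ])
  subject <- if (aggregation == "metric_mean") {
    as.list(colMeans(epoch_tbl[, -1L]))
  } else {
    tr <- build_mst(Reduce(`+`, matrices) / length(matrices))
    m <- mst_metrics(tr, normalized = normalized)
    m$dissimilarity <- if (is.null(reference)) NA_real_ else mst_dissimilarity(tr, reference)
    m
  }
  list(epoch = epoch_tbl, subject = subject)
}

#' Labelled tree from a Pruefer sequence
#'
#' Decodes a Pruefer sequence of length `n - 2` over node indices `1..n` into
#' the unique labelled tree it encodes; iterating over all `n^(n-2)` sequences
#' enumerates every labelled tree on `n` nodes (Cayley's formula), which this
#' package uses as an exhaustive oracle for MST and metric properties.
#'
#' @param seq integer vector with values in `1..n`; its length determines
#'   `n = length(seq) + 2`.
#' @return A [spanning_tree()] on `n` nodes.
#' @export
prufer_tree <- function(seq) {
  n <- length(seq) + 2L
  if (n < 2L) stop("sequence too short")
  seq <- as.integer(seq)
  if (length(seq) && (any(seq < 1L) || any(seq > n))) stop("sequence values out of range")
  degree <- rep.int(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(seq)) {
    leaf <- which.max(degree == 1L)        # smallest remaining leaf
    s <- seq[k]
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- 0L                     # removed from the tree
    degree[s] <- degree[s] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)   # two nodes remain; join them
  spanning_tree(edges, n)
}
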