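# Shared fixtures and independent oracles, all built in code at test time.

# small count matrix with proper dimnames
make_counts <- function(mat, samples = NULL, otus = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- samples %||% sprintf("S%02d", seq_len(nrow(mat)))
  colnames(mat) <- otus %||% sprintf("OTU%02d", seq_len(ncol(mat)))
  storage.mode(mat) <- "double"
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Erdos-Renyi graph with named vertices, as an igraph object
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# brute-force maximum of density * size over all induced subgraphs with
# >= 3 vertices (used as an upper bound for MCODE scores)
brute_best_density_size <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  best <- 0
  for (sz in 3:n) {
    combos <- utils::combn(n, sz)
    for (ci in seq_len(ncol(combos))) {
      vs <- combos[, ci]
      e <- sum(A[vs, vs]) / 2
      best <- max(best, 2 * e / (sz * (sz - 1)) * sz)
    }
  }
  best
}

# independent unweighted-UniFrac oracle: explicit per-branch classification
# (branch = edge above each non-root node; leaf set below via clade
# extraction), shared/unique tally on the two presence vectors
unifrac_branch_oracle <- function(presence_a, presence_b, tree) {
  stopifnot(!is.null(names(presence_a)), !is.null(names(presence_b)))
  unique_len <- 0
  union_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    leaves <- if (child <= length(tree$tip.label)) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
    in_a <- any(presence_a[leaves] > 0)
    in_b <- any(presence_b[leaves] > 0)
    len <- tree$edge.length[e]
    if (in_a || in_b) union_len <- union_len + len
    if (xor(in_a, in_b)) unique_len <- unique_len + len
  }
  if (union_len == 0) 0 else unique_len / union_len
}

# star tree with unit branches, read from newick text
star_tree <- function(n) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(n)), collapse = ","), "):0;"))
}

# adjusted Rand index between two labelled partitions over shared names
ari <- function(a, b) {
  nm <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[nm], b[nm])
}
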