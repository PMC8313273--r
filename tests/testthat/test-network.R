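make_corr <- function(entries, n = 5) {
  ids <- sprintf("OTU%02d", seq_len(n))
  rho <- diag(n)
  dimnames(rho) <- list(ids, ids)
  for (e in entries) rho[e[[1]], e[[2]]] <- rho[e[[2]], e[[1]]] <- e[[3]]
  rho
}

test_that("network construction thresholds edges and keeps isolated nodes", {
  rho <- make_corr(list(list(1, 2, 0.7)))
  net <- build_network(rho, 0.65)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(sum(net$isolated), 3)
  expect_equal(igraph::vcount(net$graph), 5)   # isolated nodes retained
  expect_warning(build_network(make_corr(list(list(1, 2, 0.9))), 0.95),
                 "no edges")
  # threshold is strict: |rho| must exceed it
  at <- suppressWarnings(build_network(make_corr(list(list(1, 2, 0.65))), 0.65))
  expect_equal(igraph::ecount(at$graph), 0)
  # p-value gate drops the edge whose pseudo-p exceeds p_max
  pmat <- matrix(0.5, 5, 5)
  pmat[1, 2] <- pmat[2, 1] <- 0.001
  corr <- structure(list(rho = make_corr(list(list(1, 2, 0.7),
                                              list(3, 4, -0.8))),
                         p = pmat), class = "sparcc_corr")
  gated <- build_network(corr, 0.65, p_max = 0.01)
  expect_equal(igraph::ecount(gated$graph), 1)
})

test_that("topology statistics match closed forms", {
  # triangle: avg edges/node 2, clustering 1, density 1
  tri <- make_corr(list(list(1, 2, 0.8), list(1, 3, 0.8), list(2, 3, 0.8)),
                   n = 3)
  stats <- network_topology(build_network(tri, 0.65))
  expect_equal(stats$avg_edges_per_node, 2)
  expect_equal(stats$mean_clustering_coefficient, 1)
  expect_equal(stats$density, 1)
  # 3 entries above threshold, 1 negative -> pct_negative 33.33
  three <- make_corr(list(list(1, 2, 0.8), list(3, 4, -0.7), list(4, 5, 0.9)))
  s3 <- network_topology(build_network(three, 0.65))
  expect_equal(s3$n_edges, 3)
  expect_equal(s3$pct_negative, 100 / 3)
  # handshake lemma on a network built from a random correlation matrix
  set.seed(6)
  R <- cov2cor(crossprod(matrix(rnorm(8 * 12), 8, 12)))
  dimnames(R) <- list(sprintf("o%d", 1:12), sprintf("o%d", 1:12))
  net <- suppressWarnings(build_network(R, 0.65))
  st <- suppressWarnings(network_topology(net))
  expect_equal(sum(igraph::degree(net$graph)), 2 * st$n_edges)
  # denominator switch
  ten <- build_network(three, 0.65)
  expect_equal(network_topology(ten, per_node = "all")$avg_edges_per_node,
               2 * 3 / 5)
})

test_that("MCODE resolves cliques with pendants to the bare clique", {
  for (k in 3:8) {
    g <- igraph::make_full_graph(k)
    g <- igraph::add_vertices(g, 1)
    g <- igraph::add_edges(g, c(1, k + 1))
    igraph::V(g)$name <- sprintf("n%02d", seq_len(k + 1))
    mods <- mcode(g)
    expect_length(mods, 1)
    expect_setequal(mods[[1]]$members, sprintf("n%02d", seq_len(k)))
    expect_equal(mods[[1]]$score, k)
    expect_equal(mods[[1]]$density, 1)
  }
})

test_that("MCODE scores are consistent and bounded by brute force", {
  set.seed(12)
  for (rep in 1:40) {
    g <- random_named_graph(sample(5:10, 1), runif(1, 0.25, 0.7))
    mods <- mcode(g)
    if (!length(mods)) next
    top <- mods[[1]]
    sub <- igraph::induced_subgraph(g, top$members)
    sz <- length(top$members)
    recomputed <- 2 * igraph::ecount(sub) / (sz * (sz - 1)) * sz
    expect_equal(top$score, recomputed, tolerance = 1e-12)
    expect_lte(top$score, brute_best_density_size(g) + 1e-12)
    # sorted by descending score
    scores <- vapply(mods, `[[`, numeric(1), "score")
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("MCODE is deterministic and honours min_size/haircut", {
  set.seed(3)
  g <- random_named_graph(15, 0.3)
  expect_identical(mcode(g), mcode(g))
  # a path of 3 has no 2-core: no module survives haircut
  p3 <- igraph::make_graph(~ a - b, b - c)
  expect_length(mcode(p3), 0)
  # triangle with a pendant at a generous admission cutoff: haircut trims
  # the singly connected member, disabling it keeps all four
  tp <- igraph::make_graph(~ a - b, b - c, a - c, a - d)
  with_hc <- mcode(tp, node_score_cutoff = 0.6)
  expect_setequal(with_hc[[1]]$members, c("a", "b", "c"))
  no_hc <- mcode(tp, node_score_cutoff = 0.6, haircut = FALSE)
  expect_setequal(no_hc[[1]]$members, c("a", "b", "c", "d"))
})

test_that("PCIT masks the indirect edge of a Gaussian chain", {
  # X -> Y -> Z with rho_xz = rho_xy * rho_yz: the X-Z edge is indirect
  # (moderate chain strength; for very strong chains the published rule
  # keeps the indirect edge because it stays within the tolerance)
  r <- 0.5
  R <- matrix(c(1, r, r^2, r, 1, r, r^2, r, 1), 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  mask <- pcit_filter(R)
  expect_true(mask["X", "Y"])
  expect_true(mask["Y", "Z"])
  expect_false(mask["X", "Z"])
  expect_equal(mask, t(mask))
  # 2-OTU identity: nothing to test, all off-diagonal kept
  R2 <- diag(2); R2[1, 2] <- R2[2, 1] <- 0.4
  dimnames(R2) <- list(c("a", "b"), c("a", "b"))
  m2 <- pcit_filter(R2)
  expect_true(m2["a", "b"] && m2["b", "a"])
  expect_false(any(diag(m2)))
})

test_that("network and module tables export round-trippable TSV", {
  rho <- make_corr(list(list(1, 2, 0.8), list(2, 3, 0.7), list(1, 3, 0.75)))
  net <- build_network(rho, 0.65)
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_network_edges(net, ep)
  edges <- read.delim(ep)
  expect_equal(nrow(edges), 3)
  expect_named(edges, c("source", "target", "weight", "sign"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_modules(mcode(net), mp)
  mods <- read.delim(mp)
  expect_equal(mods$mcode_score, 3)
})
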