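#' Build a signed co-occurrence network from a correlation matrix
#'
#' Edge (i, j) exists iff `|rho_ij| > threshold` (default 0.65) and, when a
#' pseudo-p matrix is available and `p_max` given, `p_ij <= p_max`. Isolated
#' nodes stay in the node set, flagged, and are dropped only at export (the
#' usual rendering choice).
#'
#' @param corr `sparcc_corr` or square symmetric correlation matrix with OTU
#'   IDs as dimnames.
#' @param threshold edge magnitude threshold in (0, 1).
#' @param p_max optional pseudo-p ceiling; needs `corr$p`.
#' @param node_abundance optional named vector of mean relative abundances,
#'   stored as node metadata.
#' @param edge_mask optional logical matrix (e.g. from [pcit_filter()]);
#'   edges where it is FALSE are dropped.
#' @return object of class `cooccurrence_network`: `graph` (igraph, edge
#'   attributes `weight` (signed rho) and `sign`), `otu_ids`, `threshold`,
#'   `isolated` (logical per node).
#' @export
build_network <- function(corr, threshold = 0.65, p_max = NULL,
                          node_abundance = NULL, edge_mask = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  rho <- if (inherits(corr, "sparcc_corr")) corr$rho else corr
  pmat <- if (inherits(corr, "sparcc_corr")) corr$p else NULL
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop("corr must be (or contain) a square correlation matrix")
  ids <- rownames(rho)
  if (is.null(ids)) stop("correlation matrix must carry OTU IDs as dimnames")
  keep <- abs(rho) > threshold
  if (!is.null(p_max)) {
    if (is.null(pmat)) stop("p_max given but no p-values available")
    keep <- keep & pmat <= p_max
  }
  if (!is.null(edge_mask)) keep <- keep & edge_mask
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  if (nrow(ij) == 0L) warning("network has no edges at threshold ", threshold)
  edges <- data.frame(from = ids[ij[, 1L]], to = ids[ij[, 2L]],
                      weight = rho[ij], sign = ifelse(rho[ij] >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  vertices <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(node_abundance))
    vertices$mean_abundance <- unname(node_abundance[ids])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g, otu_ids = ids, threshold = threshold,
                 isolated = setNames(igraph::degree(g) == 0, ids)),
            class = "cooccurrence_network")
}

.as_igraph <- function(net) {
  if (inherits(net, "cooccurrence_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a cooccurrence_network or igraph object")
}

#' Topology statistics of a co-occurrence network
#'
#' Stability is read as the percentage of negative (competitive) edges;
#' complexity as the average number of edges per node, `2 E / V` with `V`
#' the non-isolated node count by default (matching the convention of
#' omitting unconnected nodes) or all nodes with `per_node = "all"`. The
#' clustering coefficient is the mean local coefficient over nodes of degree
#' >= 2; density is `2E / (V (V - 1))` over non-isolated nodes.
#'
#' @param net `cooccurrence_network`.
#' @param per_node denominator for `avg_edges_per_node`: `"non_isolated"`
#'   (default) or `"all"`.
#' @return data.frame (one row): n_nodes, n_nodes_connected, n_edges,
#'   pct_negative, avg_edges_per_node, mean_clustering_coefficient, density,
#'   connected_component_count.
#' @export
network_topology <- function(net, per_node = c("non_isolated", "all")) {
  per_node <- match.arg(per_node)
  g <- .as_igraph(net)
  E <- igraph::ecount(g)
  V <- igraph::vcount(g)
  deg <- igraph::degree(g)
  vconn <- sum(deg > 0)
  if (E == 0L) {
    warning("zero-edge network: statistics reported as 0")
    return(data.frame(n_nodes = V, n_nodes_connected = 0L, n_edges = 0L,
                      pct_negative = 0, avg_edges_per_node = 0,
                      mean_clustering_coefficient = 0, density = 0,
                      connected_component_count = igraph::components(g)$no))
  }
  signs <- igraph::edge_attr(g, "sign")
  if (is.null(signs)) signs <- rep(1L, E)
  denom <- if (per_node == "non_isolated") vconn else V
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  loc <- loc[deg >= 2]
  data.frame(
    n_nodes = V, n_nodes_connected = vconn, n_edges = E,
    pct_negative = 100 * sum(signs < 0) / E,
    avg_edges_per_node = 2 * E / denom,
    mean_clustering_coefficient = if (length(loc)) mean(loc) else 0,
    density = 2 * E / (vconn * (vconn - 1)),
    connected_component_count = igraph::components(g)$no)
}

#' MCODE module detection
#'
#' Molecular Complex Detection on the unsigned graph (edge signs are kept as
#' metadata only). Stage 1 weights each vertex by `k * density(k-core)`
#' where the k-core is the highest core of the induced subgraph on the
#' vertex's closed neighbourhood. Stage 2 grows a complex from the
#' highest-weighted unseen seed, admitting neighbours whose weight is
#' `>= seed weight * (1 - node_score_cutoff)`. Stage 3 optionally fluffs
#' (adds high-density neighbours) and haircuts (keeps the 2-core, removing
#' singly connected members). Modules smaller than `min_size` are dropped;
#' each is scored `density * size` and the list is sorted by descending
#' score. Ties in vertex weight are broken by OTU ID order, making the
#' output deterministic.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param k_core reserved for MCODE's k-core filter of complexes (default 2,
#'   applied via haircut).
#' @param node_score_cutoff admission slack relative to the seed weight
#'   (default 0.2).
#' @param haircut remove singly connected complex members (default TRUE).
#' @param fluff expand complexes with neighbours whose closed-neighbourhood
#'   density exceeds `fluff_density` (default FALSE).
#' @param fluff_density density cutoff used when `fluff = TRUE`.
#' @param min_size minimum complex size (default 3).
#' @return list of modules sorted by descending `score`; each has `members`,
#'   `seed`, `n_edges`, `density` (loop-free `2E / (V (V - 1))`) and `score`
#'   (`density * size`).
#' @references Bader & Hogue (2003) An automated method for finding
#'   molecular complexes in large protein interaction networks.
#' @export
mcode <- function(net, k_core = 2, node_score_cutoff = 0.2, haircut = TRUE,
                  fluff = FALSE, fluff_density = 0.5, min_size = 3) {
  g <- .as_igraph(net)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  V <- igraph::vcount(g)
  if (V == 0L) return(list())
  names_v <- igraph::V(g)$name
  if (is.null(names_v)) names_v <- as.character(seq_len(V))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)

  w <- vapply(seq_len(V), function(v) {
    nb <- c(v, adj[[v]])
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0L) return(0)
    ksub <- igraph::induced_subgraph(sub, which(core >= k))
    k * igraph::edge_density(ksub)
  }, numeric(1L))

  order_v <- order(-w, names_v)
  visited <- logical(V)
  modules <- list()
  for (seed in order_v) {
    if (visited[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (!visited[v] && w[v] >= thresh) {
            visited[v] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    if (fluff) {
      cand <- setdiff(unique(unlist(adj[members])), members)
      for (v in cand) {
        nb <- c(v, adj[[v]])
        dens <- igraph::edge_density(igraph::induced_subgraph(g, nb))
        if (is.finite(dens) && dens > fluff_density)
          members <- c(members, v)
      }
    }
    if (haircut) {
      # keep the k-core of the complex (k_core = 2 removes singly
      # connected members, iteratively by the definition of coreness)
      sub <- igraph::induced_subgraph(g, members)
      members <- members[igraph::coreness(sub) >= k_core]
    }
    if (length(members) < min_size) next
    sub <- igraph::induced_subgraph(g, sort(members))
    sz <- length(members)
    dens <- 2 * igraph::ecount(sub) / (sz * (sz - 1))
    modules[[length(modules) + 1L]] <- list(
      members = sort(names_v[members]), seed = names_v[seed],
      n_edges = igraph::ecount(sub), density = dens, score = dens * sz)
  }
  if (!length(modules)) return(list())
  ord <- order(-vapply(modules, `[[`, numeric(1L), "score"),
               -vapply(modules, function(mo) length(mo$members), integer(1L)),
               vapply(modules, function(mo) mo$members[1L], character(1L)))
  modules[ord]
}

#' PCIT edge filter
#'
#' Partial Correlation with Information Theory (Reverter & Chan 2008): for
#' every triad (i, j, k) the three first-order partial correlations are
#' computed and the information-theoretic tolerance is the mean of the three
#' partial/direct ratios; edge (i, j) survives iff there is NO third node k
#' for which both `|r_ij| < |eps * r_ik|` and `|r_ij| < |eps * r_jk|` hold.
#' Triads containing a singular correlation (`|r| = 1`) are skipped.
#' Complexity is O(m^3); intended for the moderate OTU counts left after
#' network filtering.
#'
#' @param corr `sparcc_corr` or square correlation matrix.
#' @return symmetric logical matrix; TRUE = edge kept. Diagonal FALSE. A
#'   2-OTU matrix returns all TRUE off-diagonal (no triads to test).
#' @export
pcit_filter <- function(corr) {
  R <- if (inherits(corr, "sparcc_corr")) corr$rho else corr
  m <- nrow(R)
  if (m < 2L) stop("need at least 2 OTUs")
  keep <- matrix(TRUE, m, m, dimnames = dimnames(R))
  diag(keep) <- FALSE
  if (m < 3L) return(keep)
  skipped <- 0L
  for (i in seq_len(m - 2L)) for (j in seq.int(i + 1L, m - 1L)) {
    for (k in seq.int(j + 1L, m)) {
      rij <- R[i, j]; rik <- R[i, k]; rjk <- R[j, k]
      if (any(abs(c(rij, rik, rjk)) >= 1 - 1e-12)) { skipped <- skipped + 1L; next }
      pij <- (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
      pik <- (rik - rij * rjk) / sqrt((1 - rij^2) * (1 - rjk^2))
      pjk <- (rjk - rij * rik) / sqrt((1 - rij^2) * (1 - rik^2))
      eps <- mean(c(pij / rij, pik / rik, pjk / rjk))
      if (!is.finite(eps)) { skipped <- skipped + 1L; next }
      if (abs(rij) < abs(eps * rik) && abs(rij) < abs(eps * rjk))
        keep[i, j] <- keep[j, i] <- FALSE
      if (abs(rik) < abs(eps * rij) && abs(rik) < abs(eps * rjk))
        keep[i, k] <- keep[k, i] <- FALSE
      if (abs(rjk) < abs(eps * rij) && abs(rjk) < abs(eps * rik))
        keep[j, k] <- keep[k, j] <- FALSE
    }
  }
  attr(keep, "skipped_triads") <- skipped
  keep
}

#' Export a network as an edge-list TSV (and node table)
#'
#' Writes `source, target, weight, sign`; unconnected nodes are omitted from
#' the edge list, following the usual rendering convention.
#'
#' @param net `cooccurrence_network`.
#' @param path edge-list output path.
#' @export
write_network_edges <- function(net, path) {
  g <- .as_igraph(net)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export MCODE modules as a TSV table
#' @param modules list from [mcode()].
#' @param path output file path.
#' @export
write_modules <- function(modules, path) {
  df <- if (length(modules)) {
    data.frame(
      module = seq_along(modules),
      mcode_score = vapply(modules, `[[`, numeric(1L), "score"),
      size = vapply(modules, function(mo) length(mo$members), integer(1L)),
      density = vapply(modules, `[[`, numeric(1L), "density"),
      members = vapply(modules, function(mo)
        paste(mo$members, collapse = ","), character(1L)))
  } else {
    data.frame(module = integer(0), mcode_score = numeric(0),
               size = integer(0), density = numeric(0),
               members = character(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
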