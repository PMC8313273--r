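#' Alpha diversity: Chao1, Shannon and Faith's PD
#'
#' Chao1 uses the bias-corrected estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (F1 = singletons, F2 = doubletons),
#' which is defined even when no doubletons are observed; the classic form
#' `S_obs + F1^2 / (2 F2)` is available with `chao1_bias_corrected = FALSE`.
#' Shannon is reported in natural-log units by default (`-sum p_i ln p_i`
#' over nonzero `p_i`). Faith's PD is the total branch length of the minimal
#' subtree spanning a sample's observed leaves and the root
#' (via [picante::pd()]).
#'
#' @param counts samples x OTUs integer matrix (Chao1 needs raw counts).
#' @param tree rooted `phylo`, required only when PD is wanted.
#' @param chao1_bias_corrected use the bias-corrected Chao1 (default TRUE).
#' @param shannon_base logarithm base for Shannon (default `exp(1)`).
#' @return data.frame: sample_id, observed, chao1, shannon, pd (NA without a
#'   tree).
#' @export
alpha_diversity <- function(counts, tree = NULL, chao1_bias_corrected = TRUE,
                            shannon_base = exp(1)) {
  validate_otu_table(counts)
  chao1 <- apply(counts, 1L, function(x) {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    if (chao1_bias_corrected) {
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else if (f2 > 0) {
      s + f1^2 / (2 * f2)
    } else {
      # classic estimator undefined at F2 = 0; fall back to bias-corrected
      s + f1 * (f1 - 1) / 2
    }
  })
  shannon <- vegan::diversity(counts, index = "shannon", base = shannon_base)
  pd <- rep(NA_real_, nrow(counts))
  if (!is.null(tree)) {
    missing <- setdiff(colnames(counts), tree$tip.label)
    if (length(missing))
      stop("OTU(s) missing from tree: ", paste(missing, collapse = ", "))
    pd <- picante::pd(counts, tree, include.root = TRUE)$PD
  }
  data.frame(sample_id = rownames(counts), observed = rowSums(counts > 0),
             chao1 = chao1, shannon = as.numeric(shannon), pd = pd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic beta diversity: for two samples,
#' `d = (branch length on the root-to-taxon paths of exactly one sample) /
#' (branch length on the paths of either sample)`.
#'
#' @param counts samples x OTUs matrix; presence = count > 0. Every OTU
#'   must be a leaf of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @return `dist` over samples, values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(counts, tree) {
  validate_otu_table(counts, integer_counts = FALSE)
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from tree: ", paste(missing, collapse = ", "))
  empty <- rowSums(counts > 0) == 0
  if (any(empty))
    stop("sample(s) with zero observed OTUs: ",
         paste(rownames(counts)[empty], collapse = ", "))
  n <- nrow(counts)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # samples x nodes indicator: node lies on a root-to-observed-taxon path
  ind <- matrix(FALSE, n, nnode)
  present <- counts > 0
  tip_col <- match(tree$tip.label, colnames(counts))
  obs <- !is.na(tip_col)
  ind[, which(obs)] <- present[, tip_col[obs], drop = FALSE]
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge)))
    ind[, post$edge[e, 1L]] <- ind[, post$edge[e, 1L]] | ind[, post$edge[e, 2L]]
  # branch e subtends node edge[e, 2]; weight = its length
  len <- tree$edge.length
  B <- ind[, tree$edge[, 2L], drop = FALSE]   # samples x branches
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- B[i, ]; b <- B[j, ]
    union_len <- sum(len[a | b])
    d[i, j] <- d[j, i] <-
      if (union_len == 0) 0 else sum(len[xor(a, b)]) / union_len
  }
  as.dist(d)
}

#' Bray-Curtis dissimilarities
#'
#' `d(A, B) = sum |a_i - b_i| / sum (a_i + b_i)`, computed on relative
#' abundances by default (so uneven totals do not masquerade as turnover) or
#' on raw counts with `on = "counts"`.
#'
#' @param counts samples x OTUs matrix.
#' @param on `"relative"` (default) or `"counts"`.
#' @return `dist` over samples, values in `[0, 1]`.
#' @export
bray_curtis <- function(counts, on = c("relative", "counts")) {
  on <- match.arg(on)
  validate_otu_table(counts, integer_counts = FALSE)
  if (any(rowSums(counts) == 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  x <- if (on == "relative") relative_abundance(counts) else counts
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical scaling: eigendecomposition of the Gower-centred `-D^2/2`
#' matrix. Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported but excluded
#' from the `proportion_explained` denominator. For reproducibility each
#' axis is oriented so its first nonzero loading is positive.
#'
#' @param d `dist` or square symmetric distance matrix.
#' @param n_axes number of axes to return (default 2).
#' @return list of class `pcoa_ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (per returned
#'   axis, over the positive eigenvalues).
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  n <- nrow(D)
  # Gower double centring: A - row means - column means + grand mean
  G <- -0.5 * D^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1L], 0) * 1e-12 & values > 0)
  if (n_axes > length(pos)) {
    warning("n_axes = ", n_axes, " exceeds the number of positive axes (",
            length(pos), "); truncated")
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(values[axes]), n_axes)
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1L], k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(D), sprintf("PCo%d", seq_len(n_axes)))
  structure(list(coordinates = coords, eigenvalues = values,
                 proportion_explained = values[axes] / sum(values[pos])),
            class = "pcoa_ordination")
}

#' Multi-factor PERMANOVA with R-squared effect sizes
#'
#' Sequential (Type I) partitioning of the Gower-centred total sum of
#' squares of a distance matrix over the factors, in the given order, via
#' [vegan::adonis2()]; per-factor `R2 = SS_factor / SS_total`, pseudo-F, and
#' a permutation p-value `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under
#' free permutation of sample labels. `by = "margin"` gives the marginal
#' (one-factor-at-a-time adjusted) alternative.
#'
#' @param d `dist` or square distance matrix over samples.
#' @param metadata data.frame with a `sample_id` column matching the labels
#'   of `d`.
#' @param factors character vector of metadata columns, fitted in order.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param by `"terms"` (sequential, default) or `"margin"`.
#' @return data.frame: term, df, sum_sq, R2, F, p (Residual and Total rows
#'   carry NA for F and p).
#' @export
permanova <- function(d, metadata, factors, n_perm = 999, seed = NULL,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  if (n_perm < 99) stop("n_perm must be >= 99")
  D <- as.matrix(d)
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry sample IDs")
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  missing_factors <- setdiff(factors, names(meta))
  if (length(missing_factors))
    stop("unknown factor(s): ", paste(missing_factors, collapse = ", "))
  fdat <- as.data.frame(lapply(meta[factors], factor),
                        stringsAsFactors = TRUE)
  if (anyNA(fdat) || any(vapply(meta[factors], function(x)
    any(is.na(x) | x == ""), logical(1L))))
    stop("factor(s) with missing values among the analysed samples")
  single <- names(fdat)[vapply(fdat, nlevels, 1L) < 2L]
  if (length(single))
    stop("factor(s) with a single level: ", paste(single, collapse = ", "))
  mm <- stats::model.matrix(~ ., data = fdat)
  expected_rank <- 1L + sum(vapply(fdat, nlevels, 1L) - 1L)
  if (qr(mm)$rank < expected_rank)
    stop("confounded (aliased) factors among: ",
         paste(factors, collapse = ", "))
  form <- stats::as.formula(paste(
    "as.dist(D) ~", paste(factors, collapse = " + ")))
  fit <- .with_seed(seed,
    vegan::adonis2(form, data = fdat, permutations = n_perm, by = by))
  data.frame(term = rownames(fit), df = fit$Df, sum_sq = fit$SumOfSqs,
             R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test of a per-sample quantity across groups
#'
#' Tie-corrected H and its chi-square p-value. The degenerate all-equal
#' input (tie correction denominator zero) is reported as `H = 0, p = 1`.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length; >= 2 nonempty groups.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis_by_group <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(tabulate(groups, nlevels(groups)) == 0L))
    stop("empty group(s): ",
         paste(levels(groups)[tabulate(groups, nlevels(groups)) == 0L],
               collapse = ", "))
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
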