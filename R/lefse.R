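#' LEfSe-style linear discriminant effect sizes
#'
#' Two-stage biomarker screen. Stage 1: per-feature Kruskal-Wallis test
#' across the classes on per-sample abundances rescaled to a total of 1e6
#' (the LEfSe convention); features with `p >= alpha` are marked
#' non-significant and skipped. Stage 2: over `n_boot` bootstrap iterations
#' a fraction `boot_fraction` of samples per class is subsampled and a
#' ridge-regularised Fisher linear discriminant is fitted on the surviving
#' features (class-conditional means, pooled within-class covariance plus a
#' small ridge). The per-feature effect size of an iteration is the
#' arithmetic mean of (a) the absolute between-class difference of the
#' feature's contribution to the projected class means on the unit
#' discriminant axis and (b) the absolute raw between-class mean difference;
#' with more than two classes the maximum over class pairs is used. The
#' reported `lda_score` is `log10` of the iteration mean, floored at 1
#' (so scores are >= 0). A feature is significant iff `kw_p < alpha` and
#' `lda_score > lda_threshold`. Numeric parity with the original LEfSe tool
#' is not promised; semantics follow its published source.
#'
#' @param features samples x features abundance matrix.
#' @param classes factor/character per sample, >= 2 levels, each with >= 3
#'   samples.
#' @param alpha Kruskal-Wallis screen level (default 0.05).
#' @param lda_threshold log10 effect-size threshold (default 2.0; 1.0 is
#'   conventional for predicted-pathway tables).
#' @param n_boot bootstrap iterations (default 30; < 10 warns).
#' @param boot_fraction per-class subsample fraction (default 2/3).
#' @param seed integer seed.
#' @param ridge relative ridge added to the pooled covariance diagonal.
#' @return data.frame of class `effect_size_table`: feature, kw_p,
#'   lda_score, enriched_class, significant.
#' @export
lda_effect_size <- function(features, classes, alpha = 0.05,
                            lda_threshold = 2.0, n_boot = 30,
                            boot_fraction = 2 / 3, seed = NULL,
                            ridge = 1e-6) {
  validate_otu_table(features, integer_counts = FALSE)
  classes <- factor(classes)
  if (length(classes) != nrow(features))
    stop("classes must have one label per sample")
  if (nlevels(classes) < 2L) stop("need at least two classes")
  if (any(table(classes) < 3L))
    stop("every class needs >= 3 samples, found: ",
         paste(sprintf("%s=%d", levels(classes), table(classes)),
               collapse = ", "))
  if (n_boot < 10) warning("n_boot < 10 gives unstable effect sizes")

  totals <- rowSums(features)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(features)[totals <= 0], collapse = ", "))
  X <- features / totals * 1e6

  # a feature identical across all samples carries no class signal: p = 1
  # by convention, judged on the input values (before per-sample rescaling,
  # which re-introduces depth variation)
  const <- apply(features, 2L, function(v) length(unique(v)) == 1L) |
    apply(X, 2L, function(v) length(unique(v)) == 1L)
  kw_p <- vapply(seq_len(ncol(X)), function(j) {
    if (const[j]) 1 else kruskal.test(X[, j], classes)$p.value
  }, numeric(1L))
  names(kw_p) <- colnames(X)
  class_means <- apply(X, 2L, function(v) tapply(v, classes, mean))
  enriched <- levels(classes)[apply(class_means, 2L, which.max)]

  surviving <- which(kw_p < alpha)
  lda_score <- rep(0, ncol(X))
  if (length(surviving)) {
    S <- X[, surviving, drop = FALSE]
    eff <- .with_seed(seed, {
      acc <- matrix(0, n_boot, ncol(S))
      idx_by_class <- split(seq_along(classes), classes)
      for (b in seq_len(n_boot)) {
        take <- unlist(lapply(idx_by_class, function(ix)
          sample(ix, max(2L, ceiling(boot_fraction * length(ix))))))
        acc[b, ] <- .lda_iteration(S[take, , drop = FALSE], classes[take],
                                   ridge)
      }
      colMeans(acc)
    })
    lda_score[surviving] <- log10(pmax(eff, 1))
  }

  structure(data.frame(
    feature = colnames(X), kw_p = kw_p, lda_score = lda_score,
    enriched_class = enriched,
    significant = kw_p < alpha & lda_score > lda_threshold,
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("effect_size_table", "data.frame"))
}

# One bootstrap iteration: ridge-regularised Fisher discriminant on the
# surviving features; per-feature effect = mean(|feature's share of the
# projected class-mean gap|, |raw class-mean gap|), maximised over class
# pairs for multi-class designs.
.lda_iteration <- function(S, cl, ridge) {
  cl <- droplevels(cl)
  p <- ncol(S)
  mu <- do.call(rbind, lapply(levels(cl), function(g)
    colMeans(S[cl == g, , drop = FALSE])))
  centred <- S - mu[as.integer(cl), , drop = FALSE]
  W <- crossprod(centred) / max(1L, nrow(S) - nlevels(cl))
  lam <- ridge * mean(diag(W)) + 1e-10
  Wr <- W + diag(lam, p)
  pairs <- utils::combn(nlevels(cl), 2L)
  best <- rep(0, p)
  for (q in seq_len(ncol(pairs))) {
    d <- mu[pairs[1L, q], ] - mu[pairs[2L, q], ]
    w <- solve(Wr, d)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-30) next
    w <- w / nw
    eff <- (abs(w * d) + abs(d)) / 2
    best <- pmax(best, eff)
  }
  best
}

#' Spearman correlations between pathway and feature tables
#'
#' Tie-corrected Spearman rho per (pathway, feature) pair with the
#' t-approximation p-value. Pairs involving a constant vector are reported
#' with NA.
#'
#' @param pathways samples x pathways matrix.
#' @param features samples x features matrix over the same samples.
#' @param feature_subset optional character vector restricting the features.
#' @param adjust `"none"` (default) or `"BH"` for a `p_adj` column.
#' @return data.frame: pathway, feature, rho, p (and `p_adj` if requested).
#' @export
spearman_correlation <- function(pathways, features, feature_subset = NULL,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(rownames(pathways), rownames(features)))
    stop("pathway and feature tables must cover the same samples in the ",
         "same order")
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(features))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    features <- features[, feature_subset, drop = FALSE]
  }
  grid <- expand.grid(feature = colnames(features),
                      pathway = colnames(pathways),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- pathways[, grid$pathway[i]]
    y <- features[, grid$feature[i]]
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
      return(data.frame(pathway = grid$pathway[i], feature = grid$feature[i],
                        rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    data.frame(pathway = grid$pathway[i], feature = grid$feature[i],
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
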