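#' SparCC compositional correlations
#'
#' Estimates "basis" (absolute-abundance) correlations between OTUs from
#' compositional counts. Per resample: fractions are drawn from a per-sample
#' Dirichlet(counts + 1); the variation matrix
#' `T_ij = Var_samples[ln(x_i / x_j)]` is computed; basis variances
#' `omega` are solved from the sparsity-implied linear system
#' `sum_j T_ij = (m - 2) omega_i + sum_j omega_j`; correlations follow as
#' `rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i omega_j))`.
#' The strongest pair with `|rho|` above `exclusion_threshold` is then
#' iteratively removed from the system (one pair per round, up to
#' `max_exclusion_rounds`) and `omega` re-solved, weakening the influence of
#' genuinely correlated pairs on the sparsity assumption. The reported
#' estimate is the median over resamples. Raw estimates outside `[-1, 1]`
#' are clipped and counted.
#'
#' @param counts samples x OTUs non-negative count matrix; >= 4 OTUs.
#' @param n_fraction_resamples Dirichlet resamples to median over
#'   (default 20, the reference implementation's default).
#' @param exclusion_threshold `|rho|` above which a pair is excluded from
#'   the basis-variance system (default 0.1).
#' @param max_exclusion_rounds exclusion iterations per resample; default
#'   `floor(m / 3)`.
#' @param seed integer seed; the estimate is deterministic given it.
#' @return object of class `sparcc_corr`: `otu_ids`, `rho` (symmetric, unit
#'   diagonal), `n_clipped`, `excluded_pairs` (mean exclusions per resample),
#'   `p` (NULL until [sparcc_pvalues()]).
#' @references Friedman & Alm (2012) Inferring correlation networks from
#'   genomic survey data.
#' @export
sparcc_correlations <- function(counts, n_fraction_resamples = 20,
                                exclusion_threshold = 0.1,
                                max_exclusion_rounds = NULL, seed = NULL) {
  validate_otu_table(counts, integer_counts = FALSE)
  m <- ncol(counts)
  if (m < 4L)
    stop("SparCC needs at least 4 OTUs; the basis-variance system is ",
         "underdetermined below that")
  if (is.null(max_exclusion_rounds)) max_exclusion_rounds <- m %/% 3L
  n <- nrow(counts)
  # degenerate-input guard on the observed compositions (before Dirichlet
  # resampling, whose sampling noise would mask a zero variation matrix)
  obs <- log((counts + 1) / rowSums(counts + 1))
  Vo <- cov(obs)
  To <- outer(diag(Vo), diag(Vo), "+") - 2 * Vo
  diag(To) <- 0
  if (max(To) < 1e-12)
    stop("degenerate input: all samples share one composition (zero ",
         "log-ratio variance)")
  if (any(!is.finite(To)))
    stop("non-finite log-ratio variance; filter all-zero OTUs first")
  .with_seed(seed, {
    rhos <- array(NA_real_, c(m, m, n_fraction_resamples))
    clipped <- 0L
    excl <- 0L
    for (r in seq_len(n_fraction_resamples)) {
      g <- matrix(rgamma(n * m, shape = counts + 1, rate = 1), n, m)
      frac <- g / rowSums(g)
      fit <- .sparcc_from_fractions(log(frac), exclusion_threshold,
                                    max_exclusion_rounds)
      rhos[, , r] <- fit$rho
      clipped <- clipped + fit$n_clipped
      excl <- excl + fit$n_excluded
    }
    rho <- apply(rhos, c(1L, 2L), median)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    dimnames(rho) <- list(colnames(counts), colnames(counts))
    structure(list(otu_ids = colnames(counts), rho = rho,
                   n_clipped = clipped,
                   mean_excluded_pairs = excl / n_fraction_resamples,
                   p = NULL),
              class = "sparcc_corr")
  })
}

# Single SparCC pass on a matrix of log fractions (samples x OTUs).
.sparcc_from_fractions <- function(logfrac, exclusion_threshold,
                                   max_exclusion_rounds) {
  m <- ncol(logfrac)
  V <- cov(logfrac)
  v <- diag(V)
  Tm <- outer(v, v, "+") - 2 * V       # variation matrix
  diag(Tm) <- 0
  if (max(Tm) < 1e-12)
    stop("degenerate input: all log-ratio variances are ~0 (identical ",
         "compositions); filter or inspect the table first")
  if (any(!is.finite(Tm)))
    stop("non-finite log-ratio variance; filter all-zero OTUs first")
  M <- matrix(1, m, m)
  diag(M) <- m - 1
  Twork <- Tm
  excluded <- matrix(FALSE, m, m)
  est <- .sparcc_solve(Twork, M, Tm)
  n_excluded <- 0L
  for (round in seq_len(max_exclusion_rounds)) {
    cand <- abs(est$rho)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    mx <- max(cand)
    if (!is.finite(mx) || mx <= exclusion_threshold) break
    hit <- which(cand == mx, arr.ind = TRUE)
    # deterministic tie-break: smallest row, then column, index
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    Twork[i, j] <- Twork[j, i] <- 0
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    n_excluded <- n_excluded + 1L
    est <- .sparcc_solve(Twork, M, Tm)
  }
  list(rho = est$rho, n_clipped = est$n_clipped, n_excluded = n_excluded)
}

# Solve basis variances from the (possibly exclusion-reduced) system and
# convert to correlations; clip to [-1, 1].
.sparcc_solve <- function(Twork, M, Tm) {
  omega <- drop(solve(M, rowSums(Twork)))
  floor_val <- max(min(Tm[Tm > 0]) * 1e-6, 1e-12)
  omega[omega <= 0] <- floor_val
  denom <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - Tm) / denom
  n_clipped <- sum(abs(rho) > 1)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  list(rho = rho, n_clipped = n_clipped)
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' For each bootstrap the columns of the count table are independently
#' permuted across samples (destroying all between-OTU association while
#' preserving marginals) and the SparCC estimate is recomputed. Two-sided
#' pseudo-p per pair: `(1 + #{|rho_boot| >= |rho_obs|}) / (1 + n_bootstrap)`.
#' Diagonal p is 1 by convention.
#'
#' @param counts the count matrix the observed estimate came from.
#' @param observed `sparcc_corr` from [sparcc_correlations()].
#' @param n_bootstrap >= 99 (resolution for alpha = 0.05).
#' @param seed integer seed.
#' @param n_fraction_resamples,exclusion_threshold,max_exclusion_rounds
#'   passed through to the per-bootstrap re-estimation; use the values of
#'   the observed run.
#' @return the `sparcc_corr` with `p` filled (symmetric matrix).
#' @export
sparcc_pvalues <- function(counts, observed, n_bootstrap = 99, seed = NULL,
                           n_fraction_resamples = 20,
                           exclusion_threshold = 0.1,
                           max_exclusion_rounds = NULL) {
  if (!inherits(observed, "sparcc_corr")) stop("observed must be a sparcc_corr")
  if (n_bootstrap < 99)
    stop("n_bootstrap must be >= 99 to resolve p-values at alpha = 0.05")
  validate_otu_table(counts, integer_counts = FALSE)
  obs <- abs(observed$rho)
  m <- ncol(counts)
  .with_seed(seed, {
    hits <- matrix(0L, m, m)
    for (b in seq_len(n_bootstrap)) {
      perm <- apply(counts, 2L, sample)
      rownames(perm) <- rownames(counts)
      boot <- sparcc_correlations(
        perm, n_fraction_resamples = n_fraction_resamples,
        exclusion_threshold = exclusion_threshold,
        max_exclusion_rounds = max_exclusion_rounds, seed = NULL)
      hits <- hits + (abs(boot$rho) >= obs)
    }
    p <- (1 + hits) / (1 + n_bootstrap)
    p <- (p + t(p)) / 2
    diag(p) <- 1
    dimnames(p) <- dimnames(observed$rho)
    observed$p <- p
    observed$n_bootstrap <- n_bootstrap
    observed
  })
}

#' Write a symmetric OTU matrix (correlations or p-values) as TSV
#' @param mat square matrix with OTU IDs as dimnames.
#' @param path output file path.
#' @export
write_otu_matrix <- function(mat, path) {
  df <- data.frame(otu_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
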