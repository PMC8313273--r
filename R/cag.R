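#' Build co-abundance groups (CAGs) by Ward clustering on correlation distance
#'
#' OTUs are first retained if they participate in at least one pair with
#' correlation above `corr_keep_threshold` (read as an OTU-retention rule:
#' Ward clustering needs a full distance matrix over the retained set).
#' Correlations are converted to a correlation distance `d = 1 - rho`
#' (negative correlations give d > 1, a valid dissimilarity) and
#' agglomerated with Ward linkage ([stats::hclust()], `ward.D2` by default).
#' The tree is cut into `n_cags` clusters; `n_cags = "auto"` scans downward
#' from `max_cags` and returns the largest count for which every multi-member
#' CAG passes permutational validation at p < 0.005.
#'
#' @param counts samples x OTUs count matrix (used for the per-sample CAG
#'   abundance table and, in auto mode, validation).
#' @param corr `sparcc_corr` or square correlation matrix over the OTUs.
#' @param corr_keep_threshold pair threshold for OTU retention (default 0.5).
#' @param n_cags integer number of CAGs, or `"auto"`.
#' @param linkage `"ward.D2"` (default) or `"ward.D"`.
#' @param sub_threshold_to_unit alternative reading of the retention rule:
#'   set `d = 1` for all sub-threshold pairs before clustering.
#' @param max_cags upper bound scanned in auto mode (default 40).
#' @param n_perm,seed,alpha validation settings used in auto mode (passed to
#'   [validate_cags()]); `alpha` defaults to 0.005.
#' @return object of class `cag_set`: `assignment` (named integer, OTU ->
#'   CAG), `members` (list per CAG), `n_cags`, `abundance` (samples x CAGs:
#'   summed member relative abundances), `p` (per-CAG validation p, NA until
#'   validated), `acceptable`, `hclust`.
#' @export
build_cags <- function(counts, corr, corr_keep_threshold = 0.5,
                       n_cags = "auto", linkage = c("ward.D2", "ward.D"),
                       sub_threshold_to_unit = FALSE, max_cags = 40,
                       n_perm = 999, seed = NULL, alpha = 0.005) {
  linkage <- match.arg(linkage)
  validate_otu_table(counts, integer_counts = FALSE)
  rho <- if (inherits(corr, "sparcc_corr")) corr$rho else corr
  if (is.null(rownames(rho))) stop("correlation matrix needs OTU IDs")
  if (!all(colnames(counts) %in% rownames(rho)))
    stop("correlation matrix does not cover all OTUs in the table")
  rho <- rho[colnames(counts), colnames(counts)]
  off <- rho
  diag(off) <- 0
  retained <- colnames(counts)[apply(off > corr_keep_threshold, 1L, any)]
  if (!length(retained))
    stop("no OTU participates in a pair with correlation > ",
         corr_keep_threshold)
  dmat <- 1 - rho[retained, retained]
  if (sub_threshold_to_unit) {
    sub <- rho[retained, retained] <= corr_keep_threshold
    dmat[sub] <- 1
  }
  diag(dmat) <- 0
  hc <- hclust(as.dist(dmat), method = linkage)

  cut_to_set <- function(k) {
    assignment <- cutree(hc, k = k)
    rel <- relative_abundance(counts)[, retained, drop = FALSE]
    members <- split(names(assignment), assignment)
    names(members) <- sprintf("CAG%d", as.integer(names(members)))
    ab <- vapply(members, function(ms)
      rowSums(rel[, ms, drop = FALSE]), numeric(nrow(rel)))
    if (nrow(rel) == 1L) ab <- matrix(ab, 1L, dimnames = list(rownames(rel),
                                                              names(members)))
    structure(list(assignment = assignment, members = members,
                   n_cags = k, abundance = ab,
                   p = setNames(rep(NA_real_, k), names(members)),
                   acceptable = setNames(rep(NA, k), names(members)),
                   retained = retained, hclust = hc),
              class = "cag_set")
  }

  if (identical(n_cags, "auto")) {
    for (k in seq.int(min(max_cags, length(retained) - 1L), 2L)) {
      cags <- cut_to_set(k)
      cags <- validate_cags(cags, counts, n_perm = n_perm, seed = seed,
                            alpha = alpha)
      ok <- cags$acceptable[!is.na(cags$acceptable)]
      if (length(ok) && all(ok)) return(cags)
    }
    stop("auto mode found no CAG count (2..", max_cags,
         ") with all CAGs acceptable at p < ", alpha)
  }
  n_cags <- as.integer(n_cags)
  if (n_cags > length(retained))
    stop("n_cags (", n_cags, ") exceeds the number of retained OTUs (",
         length(retained), ")")
  cut_to_set(n_cags)
}

#' Construct a CAG set from an explicit assignment
#'
#' Builds the `cag_set` container (member lists, per-sample abundance table)
#' from a given OTU -> group assignment, without any clustering. Useful for
#' validating externally defined groupings and for calibration studies with
#' random partitions.
#'
#' @param assignment named integer/character vector: OTU ID -> CAG label.
#' @param counts samples x OTUs count matrix covering the assigned OTUs.
#' @return a `cag_set` (validation p-values unset).
#' @export
as_cag_set <- function(assignment, counts) {
  validate_otu_table(counts, integer_counts = FALSE)
  if (is.null(names(assignment))) stop("assignment must be named by OTU ID")
  missing <- setdiff(names(assignment), colnames(counts))
  if (length(missing))
    stop("assigned OTU(s) absent from table: ",
         paste(missing, collapse = ", "))
  codes <- as.integer(factor(assignment))
  names(codes) <- names(assignment)
  retained <- names(assignment)
  rel <- relative_abundance(counts)[, retained, drop = FALSE]
  members <- split(names(codes), codes)
  names(members) <- sprintf("CAG%d", as.integer(names(members)))
  ab <- vapply(members, function(ms)
    rowSums(rel[, ms, drop = FALSE]), numeric(nrow(rel)))
  if (nrow(rel) == 1L)
    ab <- matrix(ab, 1L, dimnames = list(rownames(rel), names(members)))
  k <- length(members)
  structure(list(assignment = codes, members = members, n_cags = k,
                 abundance = ab,
                 p = setNames(rep(NA_real_, k), names(members)),
                 acceptable = setNames(rep(NA, k), names(members)),
                 retained = retained, hclust = NULL),
            class = "cag_set")
}

#' Validate CAGs by permutational MANOVA on OTU profiles
#'
#' For each CAG with at least two members, the retained OTUs are treated as
#' observations, their abundance profiles across samples as the multivariate
#' response; Bray-Curtis dissimilarities among these profiles are tested for
#' separation of this CAG versus all other retained OTUs with PERMANOVA
#' under `n_perm` label permutations. Profiles are normalised per OTU (each
#' profile sums to 1) by default so the dissimilarity reflects the *shape*
#' of co-variation rather than abundance-level offsets — the property a
#' co-abundance group claims; `profile_normalise = FALSE` uses the raw
#' relative-abundance profiles. A CAG is acceptable when p < `alpha`
#' (default 0.005). Single-member CAGs are skipped with a warning.
#'
#' @param cags `cag_set` from [build_cags()].
#' @param counts the count matrix the CAGs were built from.
#' @param n_perm permutations, >= 199 (default 999; p < 0.005 needs > 199).
#' @param seed integer seed.
#' @param alpha acceptance threshold on p (default 0.005).
#' @param profile_normalise scale each OTU profile to sum 1 before
#'   Bray-Curtis (default TRUE).
#' @return the `cag_set` with `p` and `acceptable` filled.
#' @export
validate_cags <- function(cags, counts, n_perm = 999, seed = NULL,
                          alpha = 0.005, profile_normalise = TRUE) {
  if (!inherits(cags, "cag_set")) stop("cags must be a cag_set")
  if (n_perm < 199)
    stop("n_perm must be >= 199 to resolve p < 0.005")
  rel <- relative_abundance(counts)[, cags$retained, drop = FALSE]
  profiles <- t(rel)                       # OTUs as observations
  if (profile_normalise) {
    tot <- rowSums(profiles)
    if (any(tot == 0))
      stop("OTU(s) with empty profile: ",
           paste(rownames(profiles)[tot == 0], collapse = ", "))
    profiles <- profiles / tot
  }
  d <- vegan::vegdist(profiles, method = "bray")
  sizes <- vapply(cags$members, length, integer(1L))
  if (any(sizes < 2L))
    warning("single-member CAG(s) skipped in validation: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  seeds <- derive_seed(if (is.null(seed)) 0L else seed,
                       seq_along(cags$members))
  for (ci in seq_along(cags$members)) {
    nm <- names(cags$members)[ci]
    if (sizes[ci] < 2L) next
    membership <- factor(ifelse(
      rownames(profiles) %in% cags$members[[ci]], "in", "out"))
    if (nlevels(membership) < 2L) { # CAG == whole retained set
      cags$p[nm] <- NA_real_
      next
    }
    fdat <- data.frame(membership = membership)
    fit <- .with_seed(if (is.null(seed)) NULL else seeds[ci],
      vegan::adonis2(d ~ membership, data = fdat, permutations = n_perm))
    cags$p[nm] <- fit$`Pr(>F)`[1L]
    cags$acceptable[nm] <- cags$p[nm] < alpha
  }
  cags
}

#' Compare per-sample CAG abundances between two groups
#'
#' Two-sided Wilcoxon rank-sum test of each CAG's per-sample abundance
#' between the two levels of `group_factor`; direction is the level with the
#' larger median. No multiplicity correction by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param cags `cag_set` with its `abundance` table.
#' @param metadata data.frame with `sample_id` and the group column.
#' @param group_factor metadata column name with exactly two levels, each
#'   with >= 3 samples.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: cag, W, p, direction, median per level (and `p_adj`
#'   when requested).
#' @export
compare_cag_groups <- function(cags, metadata, group_factor = "group",
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!inherits(cags, "cag_set")) stop("cags must be a cag_set")
  if (!group_factor %in% names(metadata))
    stop("metadata has no column '", group_factor, "'")
  ab <- cags$abundance
  meta <- metadata[match(rownames(ab), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(rownames(ab), metadata$sample_id), collapse = ", "))
  grp <- factor(meta[[group_factor]])
  if (nlevels(grp) != 2L)
    stop("'", group_factor, "' must have exactly two levels, found ",
         nlevels(grp))
  if (any(table(grp) < 3L))
    stop("each group level needs >= 3 samples")
  lv <- levels(grp)
  res <- lapply(colnames(ab), function(cg) {
    x <- ab[grp == lv[1L], cg]
    y <- ab[grp == lv[2L], cg]
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    m1 <- median(x); m2 <- median(y)
    data.frame(cag = cg, W = unname(wt$statistic), p = wt$p.value,
               direction = if (m1 == m2) NA_character_ else
                 lv[which.max(c(m1, m2))],
               median_1 = m1, median_2 = m2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "median_1"] <- paste0("median_", lv[1L])
  names(out)[names(out) == "median_2"] <- paste0("median_", lv[2L])
  if (adjust == "BH") out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Write a CAG assignment table as TSV
#' @param cags `cag_set`.
#' @param path output file path.
#' @export
write_cag_assignment <- function(cags, path) {
  cag_names <- sprintf("CAG%d", cags$assignment)
  df <- data.frame(otu_id = names(cags$assignment), cag = cag_names,
                   p_validation = unname(cags$p[cag_names]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
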