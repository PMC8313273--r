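#' Validate an OTU count table
#'
#' An OTU table is a numeric matrix with samples as rows and OTUs as
#' columns; both dimensions must be named, IDs must be unique and counts
#' non-negative.
#'
#' @param counts matrix to validate.
#' @param integer_counts require whole numbers (TRUE for count tables,
#'   FALSE for relative-abundance tables).
#' @return the validated matrix, invisibly coerced to numeric.
#' @export
validate_otu_table <- function(counts, integer_counts = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("OTU table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must have sample IDs as rownames and OTU IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("OTU table contains missing or negative values")
  if (integer_counts && any(abs(counts - round(counts)) > 1e-8))
    stop("OTU table contains non-integer counts")
  invisible(counts)
}

#' Read an OTU count table from TSV
#'
#' Expected dialect: tab-separated, header row holds OTU IDs, first column
#' holds sample IDs. `transposed = TRUE` accepts the OTUs-as-rows
#' orientation and returns the standard samples x OTUs matrix.
#'
#' @param path file path.
#' @param transposed logical; input has OTUs as rows, samples as columns.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, transposed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("parse error in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("value error in %s: non-numeric cell at row '%s', column '%s'",
                 path, ids[bad[1L]], colnames(cells)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("value error in %s: negative count at row '%s', column '%s'",
                 path, ids[bad[1L]], colnames(cells)[bad[2L]]))
  }
  rownames(num) <- ids
  if (transposed) num <- t(num)
  storage.mode(num) <- "double"
  validate_otu_table(num)
  num
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: header = OTU IDs, first column
#' `sample_id`.
#'
#' @param counts samples x OTUs matrix.
#' @param path output file path.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy samples to an even depth
#'
#' Subsamples each sample's reads without replacement
#' (hypergeometric, via [vegan::rrarefy()]) so every retained row sums to
#' exactly `depth`. Samples with fewer than `depth` reads are dropped with
#' a warning rather than an error, the standard community practice.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; rarefaction with the same seed is bit-identical.
#' @return rarefied count matrix; dropped samples reported via warning and
#'   the `"dropped_samples"` attribute.
#' @export
rarefy_table <- function(counts, depth, seed = NULL) {
  validate_otu_table(counts)
  if (length(depth) != 1L || !is.finite(depth) || depth < 1)
    stop("depth must be a single integer >= 1")
  depth <- as.integer(round(depth))
  totals <- rowSums(counts)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth ", depth)
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[drop], collapse = ", "))
  kept <- counts[!drop, , drop = FALSE]
  # vegan >= 2.7 warns heuristically when a table has no singletons; that
  # is expected for simulated or pre-filtered tables, so muffle it
  out <- .with_seed(seed, withCallingHandlers(
    vegan::rrarefy(kept, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "double"
  attr(out, "dropped_samples") <- rownames(counts)[drop]
  out
}

#' Filter OTUs on mean relative abundance and prevalence
#'
#' Keeps OTU j iff its abundance summary (mean, or max with
#' `abund_stat = "max"`) of per-sample relative abundance is
#' `>= min_mean_rel_abund` AND the fraction of samples with a nonzero count
#' is `>= min_prevalence`. Prevalence is computed on raw counts > 0. The
#' sample set is unchanged. Two regimes are used in practice: 0.0001/0.10
#' before diversity analyses and 0.0005/0.20 before network and CAG
#' construction, each applied independently to the rarefied table.
#'
#' @param counts samples x OTUs count matrix.
#' @param min_mean_rel_abund fraction in `[0, 1]`.
#' @param min_prevalence fraction of samples in `[0, 1]`.
#' @param abund_stat summary of relative abundance compared against
#'   `min_mean_rel_abund`: `"mean"` (default) or `"max"`.
#' @return filtered count matrix.
#' @export
filter_otus <- function(counts, min_mean_rel_abund, min_prevalence,
                        abund_stat = c("mean", "max")) {
  validate_otu_table(counts, integer_counts = FALSE)
  abund_stat <- match.arg(abund_stat)
  if (min_mean_rel_abund < 0 || min_mean_rel_abund > 1 ||
      min_prevalence < 0 || min_prevalence > 1)
    stop("thresholds must lie in [0, 1]")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  rel <- counts / totals
  ab <- if (abund_stat == "mean") colMeans(rel) else apply(rel, 2L, max)
  prev <- colMeans(counts > 0)
  keep <- ab >= min_mean_rel_abund & prev >= min_prevalence
  if (!any(keep))
    stop("all OTUs removed by filter (min_mean_rel_abund = ",
         min_mean_rel_abund, ", min_prevalence = ", min_prevalence, ")")
  out <- counts[, keep, drop = FALSE]
  if (any(rowSums(out) == 0))
    warning("sample(s) left with no counts after OTU filtering: ",
            paste(rownames(out)[rowSums(out) == 0], collapse = ", "))
  out
}

#' Convert counts to relative abundances
#'
#' @param counts samples x OTUs matrix; every row total must be positive.
#' @return matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  validate_otu_table(counts, integer_counts = FALSE)
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals <= 0], collapse = ", "))
  counts / totals
}

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Read a taxonomy map
#'
#' Two-column TSV (`otu_id`, semicolon-delimited lineage). Greengenes-style
#' `k__`/`p__`/... prefixes are accepted and stripped; missing ranks stay
#' empty strings.
#'
#' @param path file path.
#' @return data.frame with columns `otu_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("taxonomy file must have two columns (otu_id, lineage)")
  parts <- strsplit(df[[2L]], ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kpcofgs]__", "", p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7L)))
  colnames(mat) <- TAXONOMIC_RANKS
  data.frame(otu_id = df[[1L]], mat, stringsAsFactors = FALSE)
}

#' Write a taxonomy map as two-column TSV
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path output file path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lineage <- apply(as.matrix(taxonomy[, TAXONOMIC_RANKS]), 1L, paste,
                   collapse = ";")
  write.table(data.frame(otu_id = taxonomy$otu_id, lineage = lineage),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV keyed by `sample_id`; recognised analysis columns are `stage`
#' (E1-E4), `group` (NA/NO), `batch`, `farm`, `genetics`, `animal_id`, all
#' optional. Note the group label "NA" (normal heat cycle) is read as the
#' literal string, not a missing value.
#'
#' @param path file path.
#' @return data.frame with a `sample_id` column.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", na.strings = NULL)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in metadata")
  df
}

#' Write sample metadata
#' @param metadata data.frame with a `sample_id` column.
#' @param path output file path.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' PD/UniFrac computations need: a single rooted tree with branch lengths.
#'
#' @param path newick file; leaf labels are OTU IDs.
#' @return an [ape] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, found several")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Columns of the output are distinct lineages truncated at `rank`
#' (semicolon-joined); the value is the sum of member-OTU abundances, so
#' per-sample totals are conserved. OTUs whose lineage is empty at `rank`
#' are pooled into an `unclassified_<parent>` column named after their
#' deepest annotated rank.
#'
#' @param table samples x OTUs abundance (or count) matrix.
#' @param taxonomy data.frame as from [read_taxonomy()].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return samples x lineages matrix.
#' @export
aggregate_taxonomy <- function(table, taxonomy, rank) {
  validate_otu_table(table, integer_counts = FALSE)
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  k <- match(rank, TAXONOMIC_RANKS)
  tax <- taxonomy[match(colnames(table), taxonomy$otu_id), , drop = FALSE]
  unknown <- is.na(tax$otu_id)
  if (any(unknown)) {
    warning(sum(unknown), " OTU(s) absent from taxonomy pooled as unclassified")
    tax[unknown, TAXONOMIC_RANKS] <- ""
  }
  lin <- as.matrix(tax[, TAXONOMIC_RANKS[seq_len(k)], drop = FALSE])
  lin[is.na(lin)] <- ""
  labels <- vapply(seq_len(nrow(lin)), function(i) {
    v <- lin[i, ]
    if (nzchar(v[k])) {
      paste(v[nzchar(v)], collapse = ";")
    } else {
      parent <- v[nzchar(v)]
      parent <- if (length(parent)) parent[length(parent)] else "root"
      paste0("unclassified_", parent)
    }
  }, character(1L))
  groups <- factor(labels, levels = sort(unique(labels)))
  ind <- stats::model.matrix(~ groups - 1)
  colnames(ind) <- levels(groups)
  out <- table %*% ind
  rownames(out) <- rownames(table)
  out
}

# TSV writers shared across modules -----------------------------------------

#' Write a square distance matrix as TSV
#' @param d `dist` object or square matrix.
#' @param path output file path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
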