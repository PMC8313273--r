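# End-to-end orchestration of the two study designs: the heat-cycle
# analysis (per-stage networks + diversity) and the puberty-failure
# analysis (CAGs + biomarker screen). Both write plain TSV artifacts plus a
# JSON manifest with full provenance (package version, seeds, config hash).

# FNV-1a over the deparsed config list: a stable, dependency-free content
# hash for the manifest.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.write_manifest <- function(out_dir, analysis, config, seed, outputs,
                            notes = character(0)) {
  manifest <- list(
    tool = "otunet",
    version = as.character(utils::packageVersion("otunet")),
    analysis = analysis,
    master_seed = seed,
    config_hash = .config_hash(config),
    config = config,
    outputs = outputs,
    notes = notes)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.write_df <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.log_stage <- function(verbose, ...) {
  if (verbose) message("[otunet] ", ...)
}

# factors from the canonical printed order that exist in the metadata with
# >= 2 levels among the analysed samples
.usable_factors <- function(metadata, wanted) {
  ok <- vapply(wanted, function(f)
    f %in% names(metadata) &&
      !any(is.na(metadata[[f]]) | metadata[[f]] == "") &&
      length(unique(metadata[[f]])) >= 2L, logical(1L))
  wanted[ok]
}

#' Run the heat-cycle analysis end to end
#'
#' Pipeline: optional rarefaction; diversity-regime OTU filter; alpha
#' diversity with per-stage Kruskal-Wallis; unweighted UniFrac +
#' Bray-Curtis + PCoA; multi-factor PERMANOVA; then per stage a
#' network-regime filter, SparCC, the thresholded signed network, topology
#' statistics and MCODE modules; a cross-stage Jaccard module-overlap
#' matrix; and a stage biomarker screen. All artifacts are written under
#' `out_dir` and listed in `manifest.json`.
#'
#' @param counts samples x OTUs count matrix.
#' @param metadata data.frame with `sample_id` and a `stage` column (>= 2
#'   stages present).
#' @param tree rooted `phylo` over the OTUs (for PD and UniFrac).
#' @param out_dir output directory, created if needed.
#' @param depth optional rarefaction depth; NULL skips rarefaction.
#' @param diversity_filter `c(min_mean_rel_abund, min_prevalence)` before
#'   diversity analyses (default 0.0001, 0.10).
#' @param network_filter filter before per-stage networks (default 0.0005,
#'   0.20, applied within each stage's sample subset).
#' @param network_threshold SparCC magnitude threshold for edges (default
#'   0.65).
#' @param sparcc_resamples Dirichlet resamples for SparCC.
#' @param permanova_factors factors fitted sequentially (default batch,
#'   stage, farm, genetics; silently reduced to those usable).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param lda_threshold,lefse_alpha stage biomarker screen settings.
#' @param seed master seed; per-stage seeds are derived from it so stages
#'   can be rerun in isolation.
#' @param verbose log one line per stage.
#' @return (invisibly) the manifest as a list.
#' @export
run_cycle_analysis <- function(counts, metadata, tree, out_dir,
                               depth = NULL,
                               diversity_filter = c(1e-4, 0.10),
                               network_filter = c(5e-4, 0.20),
                               network_threshold = 0.65,
                               sparcc_resamples = 20,
                               permanova_factors = c("batch", "stage",
                                                     "farm", "genetics"),
                               n_perm = 999, lda_threshold = 2.0,
                               lefse_alpha = 0.05, seed = 1,
                               verbose = FALSE) {
  validate_otu_table(counts)
  if (!"stage" %in% names(metadata)) stop("metadata has no 'stage' column")
  meta <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  no_stage <- is.na(meta$stage) | meta$stage == "" | is.na(meta$sample_id)
  if (any(no_stage))
    stop("sample(s) without a stage label: ",
         paste(rownames(counts)[no_stage], collapse = ", "))
  stages <- sort(unique(meta$stage))
  if (length(stages) < 2L)
    stop("cycle analysis needs >= 2 stages, found: ",
         paste(stages, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(depth = depth, diversity_filter = diversity_filter,
                 network_filter = network_filter,
                 network_threshold = network_threshold,
                 sparcc_resamples = sparcc_resamples,
                 permanova_factors = permanova_factors, n_perm = n_perm,
                 lda_threshold = lda_threshold, lefse_alpha = lefse_alpha,
                 seed = seed)
  outputs <- character(0)
  notes <- character(0)

  if (!is.null(depth)) {
    counts <- rarefy_table(counts, depth, seed = derive_seed(seed, 1L))
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
    .log_stage(verbose, "rarefied to ", depth, ": ", nrow(counts),
               " samples retained")
  }

  div <- filter_otus(counts, diversity_filter[1L], diversity_filter[2L])
  .log_stage(verbose, "diversity filter: ", ncol(div), "/", ncol(counts),
             " OTUs kept")

  alpha <- alpha_diversity(div, tree)
  kw <- do.call(rbind, lapply(c("chao1", "shannon", "pd"), function(ix) {
    r <- kruskal_wallis_by_group(alpha[[ix]], meta$stage)
    data.frame(index = ix, H = r$H, p = r$p)
  }))
  outputs <- c(outputs, .write_df(alpha, file.path(out_dir, "alpha_diversity.tsv")),
               .write_df(kw, file.path(out_dir, "alpha_kruskal_wallis.tsv")))

  uf <- unweighted_unifrac(div, tree)
  bc <- bray_curtis(div)
  outputs <- c(outputs,
               write_distance_matrix(uf, file.path(out_dir, "unifrac.tsv")),
               write_distance_matrix(bc, file.path(out_dir, "bray_curtis.tsv")))
  ord <- pcoa_ordination(uf, n_axes = min(4L, nrow(as.matrix(uf)) - 1L))
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE)
  eig <- data.frame(axis = seq_along(ord$eigenvalues),
                    eigenvalue = ord$eigenvalues)
  outputs <- c(outputs, .write_df(coords, file.path(out_dir, "pcoa_coordinates.tsv")),
               .write_df(eig, file.path(out_dir, "pcoa_eigenvalues.tsv")))

  factors <- .usable_factors(meta, permanova_factors)
  if (length(factors)) {
    pmv <- permanova(uf, meta, factors, n_perm = n_perm,
                     seed = derive_seed(seed, 2L))
    outputs <- c(outputs, .write_df(pmv, file.path(out_dir, "permanova.tsv")))
  } else {
    notes <- c(notes, "permanova skipped: no usable factors")
  }

  topo_rows <- list()
  all_modules <- list()
  for (si in seq_along(stages)) {
    s <- stages[si]
    sub <- counts[meta$stage == s, , drop = FALSE]
    subf <- filter_otus(sub, network_filter[1L], network_filter[2L])
    .log_stage(verbose, "stage ", s, ": ", nrow(subf), " samples, ",
               ncol(subf), " OTUs after network filter")
    corr <- sparcc_correlations(subf, n_fraction_resamples = sparcc_resamples,
                                seed = derive_seed(seed, 10L + si))
    net <- suppressWarnings(build_network(
      corr, threshold = network_threshold,
      node_abundance = colMeans(relative_abundance(subf))))
    topo <- network_topology(net)
    topo_rows[[s]] <- cbind(stage = s, topo)
    mods <- mcode(net)
    all_modules[[s]] <- mods
    outputs <- c(outputs,
                 write_network_edges(net, file.path(
                   out_dir, sprintf("network_edges_%s.tsv", s))),
                 write_modules(mods, file.path(
                   out_dir, sprintf("network_modules_%s.tsv", s))))
  }
  outputs <- c(outputs, .write_df(do.call(rbind, topo_rows),
                                  file.path(out_dir, "network_topology.tsv")))

  overlap <- .module_jaccard(all_modules)
  outputs <- c(outputs, .write_df(overlap,
                                  file.path(out_dir, "module_overlap.tsv")))

  biomarkers <- lda_effect_size(relative_abundance(div), meta$stage,
                                alpha = lefse_alpha,
                                lda_threshold = lda_threshold,
                                seed = derive_seed(seed, 20L))
  outputs <- c(outputs, .write_df(biomarkers,
                                  file.path(out_dir, "stage_biomarkers.tsv")))

  manifest_path <- .write_manifest(out_dir, "cycle", config, seed,
                                   basename(outputs), notes)
  .log_stage(verbose, "wrote ", length(outputs), " artifacts + manifest")
  invisible(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
}

# Jaccard overlap between module member sets across stages; module identity
# across stages is never asserted, only reported.
.module_jaccard <- function(all_modules) {
  labels <- character(0)
  sets <- list()
  for (s in names(all_modules)) {
    mods <- all_modules[[s]]
    for (k in seq_along(mods)) {
      labels <- c(labels, sprintf("%s_module%d", s, k))
      sets[[length(sets) + 1L]] <- mods[[k]]$members
    }
  }
  if (length(sets) < 2L)
    return(data.frame(module_a = character(0), module_b = character(0),
                      jaccard = numeric(0)))
  pairs <- utils::combn(length(sets), 2L)
  data.frame(
    module_a = labels[pairs[1L, ]], module_b = labels[pairs[2L, ]],
    jaccard = vapply(seq_len(ncol(pairs)), function(q) {
      a <- sets[[pairs[1L, q]]]; b <- sets[[pairs[2L, q]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1L)), stringsAsFactors = FALSE)
}

#' Run the puberty-failure (two-group) analysis end to end
#'
#' Pipeline: optional rarefaction; network-regime OTU filter; SparCC;
#' co-abundance groups with permutational validation and a two-group
#' Wilcoxon comparison; biomarker screens at the OTU and (given a taxonomy)
#' genus and family levels; and, when a pathway table is supplied, Spearman
#' correlations between pathways and the significant OTUs (all filtered OTUs
#' when none is significant). Artifacts are written under `out_dir` and
#' listed in `manifest.json`.
#'
#' @param counts samples x OTUs count matrix.
#' @param metadata data.frame with `sample_id` and a two-level group column.
#' @param taxonomy optional taxonomy data.frame for genus/family screens.
#' @param pathways optional samples x pathways table.
#' @param out_dir output directory.
#' @param group_factor metadata column (default `"group"`).
#' @param depth optional rarefaction depth.
#' @param network_filter OTU filter before SparCC (default 0.0005, 0.20).
#' @param corr_keep_threshold CAG retention threshold (default 0.5).
#' @param n_cags CAG count or `"auto"` (default).
#' @param max_cags auto-mode upper bound.
#' @param n_perm validation permutations (default 999).
#' @param sparcc_resamples Dirichlet resamples for SparCC.
#' @param lda_threshold,lefse_alpha biomarker screen settings.
#' @param seed master seed.
#' @param verbose log one line per stage.
#' @return (invisibly) the manifest as a list.
#' @export
run_puberty_analysis <- function(counts, metadata, taxonomy = NULL,
                                 pathways = NULL, out_dir,
                                 group_factor = "group", depth = NULL,
                                 network_filter = c(5e-4, 0.20),
                                 corr_keep_threshold = 0.5, n_cags = "auto",
                                 max_cags = 40, n_perm = 999,
                                 sparcc_resamples = 20, lda_threshold = 2.0,
                                 lefse_alpha = 0.05, seed = 1,
                                 verbose = FALSE) {
  validate_otu_table(counts)
  if (!group_factor %in% names(metadata))
    stop("metadata has no '", group_factor, "' column")
  meta <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (length(unique(meta[[group_factor]])) < 2L)
    stop("'", group_factor, "' must have two levels among the samples")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(group_factor = group_factor, depth = depth,
                 network_filter = network_filter,
                 corr_keep_threshold = corr_keep_threshold, n_cags = n_cags,
                 max_cags = max_cags, n_perm = n_perm,
                 sparcc_resamples = sparcc_resamples,
                 lda_threshold = lda_threshold, lefse_alpha = lefse_alpha,
                 seed = seed)
  outputs <- character(0)
  notes <- character(0)

  if (!is.null(depth)) {
    counts <- rarefy_table(counts, depth, seed = derive_seed(seed, 1L))
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  }

  filt <- filter_otus(counts, network_filter[1L], network_filter[2L])
  .log_stage(verbose, "network filter: ", ncol(filt), "/", ncol(counts),
             " OTUs kept")

  corr <- sparcc_correlations(filt, n_fraction_resamples = sparcc_resamples,
                              seed = derive_seed(seed, 2L))
  outputs <- c(outputs, write_otu_matrix(
    corr$rho, file.path(out_dir, "sparcc_correlations.tsv")))

  cags <- build_cags(filt, corr, corr_keep_threshold = corr_keep_threshold,
                     n_cags = n_cags, max_cags = max_cags, n_perm = n_perm,
                     seed = derive_seed(seed, 3L))
  if (!identical(n_cags, "auto"))
    cags <- validate_cags(cags, filt, n_perm = n_perm,
                          seed = derive_seed(seed, 3L))
  .log_stage(verbose, "built ", cags$n_cags, " CAGs over ",
             length(cags$retained), " retained OTUs")
  outputs <- c(outputs,
               write_cag_assignment(cags, file.path(out_dir, "cag_assignment.tsv")),
               .write_df(data.frame(sample_id = rownames(cags$abundance),
                                    cags$abundance, check.names = FALSE),
                         file.path(out_dir, "cag_abundance.tsv")))

  cmp <- compare_cag_groups(cags, meta, group_factor)
  outputs <- c(outputs, .write_df(cmp, file.path(out_dir, "cag_group_comparison.tsv")))

  rel <- relative_abundance(filt)
  screens <- list(otu = rel)
  if (!is.null(taxonomy)) {
    screens$genus <- aggregate_taxonomy(rel, taxonomy, "genus")
    screens$family <- aggregate_taxonomy(rel, taxonomy, "family")
  } else {
    notes <- c(notes, "genus/family screens skipped: no taxonomy supplied")
  }
  sig_otus <- character(0)
  for (lvl in names(screens)) {
    est <- lda_effect_size(screens[[lvl]], meta[[group_factor]],
                           alpha = lefse_alpha,
                           lda_threshold = lda_threshold,
                           seed = derive_seed(seed, 4L))
    if (lvl == "otu") sig_otus <- est$feature[est$significant]
    outputs <- c(outputs, .write_df(
      est, file.path(out_dir, sprintf("biomarkers_%s.tsv", lvl))))
  }

  if (!is.null(pathways)) {
    feats <- if (length(sig_otus)) sig_otus else colnames(rel)
    if (!length(sig_otus))
      notes <- c(notes,
                 "no significant OTU biomarkers; pathways correlated against all filtered OTUs")
    pw <- pathways[rownames(rel), , drop = FALSE]
    spear <- spearman_correlation(pw, rel, feature_subset = feats)
    outputs <- c(outputs, .write_df(
      spear, file.path(out_dir, "pathway_correlations.tsv")))
  } else {
    notes <- c(notes, "pathway correlation skipped: no pathway table supplied")
  }

  manifest_path <- .write_manifest(out_dir, "puberty", config, seed,
                                   basename(outputs), notes)
  .log_stage(verbose, "wrote ", length(outputs), " artifacts + manifest")
  invisible(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
}

#' Load a flat pipeline configuration from YAML
#'
#' Convenience for driving [run_cycle_analysis()] /
#' [run_puberty_analysis()] from a flat-key YAML file; values are passed as
#' arguments by name. Requires the `yaml` package.
#'
#' @param path YAML file with flat keys matching the run function arguments.
#' @return named list of arguments.
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of argument names")
  cfg
}
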