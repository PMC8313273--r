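#' Configuration for the synthetic OTU dataset generator
#'
#' The generator emulates the structure of a gilt gut-microbiome study: a
#' balanced design of four ordered oestrus stages (E1 dioestrus, E2
#' pro-oestrus, E3 oestrus, E4 metoestrus) crossed with two gilt groups
#' (`NA` = normal heat cycle, `NO` = failure to enter oestrus), compositional
#' counts at an even sequencing depth, planted blocks of co-varying OTUs,
#' stage-periodic taxa and group-differential taxa.
#'
#' Defaults mirror the emulated study design: 22 samples per stage, depth
#' 34,949 reads (the rarefaction depth), mild Dirichlet-multinomial
#' overdispersion (concentration `1/overdispersion` = 10,000).
#'
#' @param n_samples_per_cell samples per stage x group cell.
#' @param n_otus number of OTUs.
#' @param depth reads per sample; every simulated sample sums to exactly this.
#' @param n_blocks,block_size number and size of planted co-abundance blocks.
#' @param block_correlation within-block latent (basis) correlation in (0,1).
#' @param n_stage_otus taxa with a one-period sinusoidal stage effect.
#' @param stage_amplitude amplitude of the stage sinusoid on the natural-log
#'   scale.
#' @param n_group_otus taxa differentially abundant between NA and NO gilts.
#' @param group_log2fc absolute log2 fold change of group taxa in NO samples.
#' @param base_logmean_sd SD of baseline log-mean abundances across OTUs.
#' @param otu_log_sd SD of per-sample log-abundance noise around the baseline.
#' @param overdispersion Dirichlet-multinomial scale; Dirichlet concentration
#'   is `1/overdispersion`, 0 gives a plain multinomial.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_samples_per_cell = 22, n_otus = 150, depth = 34949,
                       n_blocks = 2, block_size = 5, block_correlation = 0.8,
                       n_stage_otus = 10, stage_amplitude = 1,
                       n_group_otus = 10, group_log2fc = 1,
                       base_logmean_sd = 1.5, otu_log_sd = 1,
                       overdispersion = 1e-4, seed = 1) {
  cfg <- list(n_samples_per_cell = as.integer(n_samples_per_cell),
              n_otus = as.integer(n_otus), depth = as.integer(depth),
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size),
              block_correlation = block_correlation,
              n_stage_otus = as.integer(n_stage_otus),
              stage_amplitude = stage_amplitude,
              n_group_otus = as.integer(n_group_otus),
              group_log2fc = group_log2fc,
              base_logmean_sd = base_logmean_sd, otu_log_sd = otu_log_sd,
              overdispersion = overdispersion, seed = as.integer(seed))
  with(cfg, {
    if (n_samples_per_cell < 1 || n_otus < 1 || depth < 1)
      stop("sample count, OTU count and depth must all be positive")
    if (n_blocks < 0 || block_size < 0 || n_stage_otus < 0 || n_group_otus < 0)
      stop("structure counts must be non-negative")
    if (n_blocks > 0 && (block_correlation <= 0 || block_correlation >= 1))
      stop("block_correlation must lie in (0, 1)")
    if (n_blocks * block_size + n_stage_otus + n_group_otus > n_otus)
      stop("planted structure exceeds n_otus: ",
           n_blocks * block_size + n_stage_otus + n_group_otus, " > ", n_otus)
    if (overdispersion < 0) stop("overdispersion must be >= 0")
    if (base_logmean_sd < 0 || otu_log_sd < 0) stop("SDs must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

STAGES <- c("E1", "E2", "E3", "E4")
GROUPS <- c("NA", "NO")

#' Simulate an OTU dataset with planted structure
#'
#' Counts are drawn in three stages: (1) a latent log-abundance vector per
#' sample = baseline log-mean + block factor (equi-correlated Gaussian per
#' block) + stage effect (one-period sinusoid over the four ordered stages
#' with a per-OTU phase) + group effect (+/- `group_log2fc * log 2` added in
#' NO samples); (2) softmax to a composition; (3) a Dirichlet-multinomial
#' draw of exactly `depth` reads. The tree is a random coalescent over the
#' OTUs and the taxonomy is carved from its nested clades, so genera and
#' families are monophyletic.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (samples x OTUs, rows sum to `depth`),
#'   `metadata` (sample_id, stage, group, batch, farm, genetics, animal_id),
#'   `tree` (`phylo`), `taxonomy` (data.frame) and `truth` (ground-truth
#'   record: `block_membership`, `stage_otus` with phases, `group_otus` with
#'   signs, `true_correlations` latent basis correlation matrix).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  m <- config$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(m))

  .with_seed(config$seed, {
    # design: stage x group balanced cells
    cells <- expand.grid(stage = STAGES, group = GROUPS,
                         rep = seq_len(config$n_samples_per_cell),
                         stringsAsFactors = FALSE)
    n <- nrow(cells)
    # the same animal is sampled at all four stages (repeated measures);
    # farm and genetic line are animal-level, sampling batch is sample-level
    animal_id <- sprintf("A%s%03d", ifelse(cells$group == "NA", "N", "O"),
                         cells$rep)
    animals <- unique(animal_id)
    farm_of <- setNames(sample(c("F1", "F2"), length(animals), replace = TRUE),
                        animals)
    gen_of <- setNames(sample(c("G1", "G2"), length(animals), replace = TRUE),
                       animals)
    metadata <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      stage = cells$stage,
      group = cells$group,
      animal_id = animal_id,
      batch = sample(c("B1", "B2", "B3"), n, replace = TRUE),
      farm = farm_of[animal_id],
      genetics = gen_of[animal_id],
      stringsAsFactors = FALSE)
    rownames(metadata) <- NULL

    # role assignment: blocks first, then stage OTUs, then group OTUs
    idx <- seq_len(m)
    block_membership <- rep(NA_integer_, m)
    pos <- 0L
    for (b in seq_len(config$n_blocks)) {
      block_membership[pos + seq_len(config$block_size)] <- b
      pos <- pos + config$block_size
    }
    stage_idx <- pos + seq_len(config$n_stage_otus)
    pos <- pos + config$n_stage_otus
    group_idx <- pos + seq_len(config$n_group_otus)

    base_mu <- rnorm(m, 0, config$base_logmean_sd)
    # planted-structure taxa receive baselines from the centre of the
    # abundance distribution: recovery tests must measure the estimators,
    # not read-depth detection limits on accidentally rare taxa
    n_planted <- config$n_blocks * config$block_size +
      config$n_stage_otus + config$n_group_otus
    if (n_planted > 0L && n_planted < m) {
      central <- order(abs(base_mu - median(base_mu)))[seq_len(n_planted)]
      planted_pos <- seq_len(n_planted)
      swap <- setdiff(central, planted_pos)
      free <- setdiff(planted_pos, central)
      if (length(swap)) {
        tmp <- base_mu[free]
        base_mu[free] <- base_mu[swap]
        base_mu[swap] <- tmp
      }
    }
    phases <- runif(max(config$n_stage_otus, 1L), 0, 2 * pi)[
      seq_len(config$n_stage_otus)]
    signs <- if (config$n_group_otus > 0)
      sample(c(-1, 1), config$n_group_otus, replace = TRUE) else numeric(0)

    sig <- config$otu_log_sd
    r <- config$block_correlation
    eps <- matrix(rnorm(n * m, 0, sig), n, m)
    for (b in seq_len(config$n_blocks)) {
      members <- which(block_membership == b)
      u <- rnorm(n, 0, sig)               # shared block factor
      eps[, members] <- sqrt(r) * u +
        sqrt(1 - r) * matrix(rnorm(n * length(members), 0, sig),
                             n, length(members))
    }
    y <- sweep(eps, 2L, base_mu, "+")
    if (config$n_stage_otus > 0) {
      s <- match(metadata$stage, STAGES)
      for (j in seq_along(stage_idx)) {
        y[, stage_idx[j]] <- y[, stage_idx[j]] +
          config$stage_amplitude * sin(2 * pi * (s - 1) / 4 + phases[j])
      }
    }
    if (config$n_group_otus > 0) {
      no <- metadata$group == "NO"
      for (j in seq_along(group_idx)) {
        y[no, group_idx[j]] <- y[no, group_idx[j]] +
          signs[j] * config$group_log2fc * log(2)
      }
    }

    comp <- exp(y - apply(y, 1L, max))
    comp <- comp / rowSums(comp)
    counts <- matrix(0, n, m, dimnames = list(metadata$sample_id, otu_ids))
    conc <- if (config$overdispersion > 0) 1 / config$overdispersion else Inf
    for (i in seq_len(n)) {
      p <- if (is.finite(conc)) {
        g <- rgamma(m, shape = comp[i, ] * conc, rate = 1)
        if (sum(g) == 0) comp[i, ] else g / sum(g)
      } else comp[i, ]
      counts[i, ] <- rmultinom(1L, config$depth, p)
    }

    tree <- ape::rcoal(m, tip.label = otu_ids)
    taxonomy <- .taxonomy_from_tree(tree)

    true_cor <- diag(m)
    for (b in seq_len(config$n_blocks)) {
      members <- which(block_membership == b)
      true_cor[members, members] <- r
      diag(true_cor)[members] <- 1
    }
    dimnames(true_cor) <- list(otu_ids, otu_ids)

    truth <- list(
      block_membership = setNames(block_membership, otu_ids),
      stage_otus = setNames(phases, otu_ids[stage_idx]),
      group_otus = setNames(signs, otu_ids[group_idx]),
      true_correlations = true_cor)

    list(counts = counts, metadata = metadata, tree = tree,
         taxonomy = taxonomy, truth = truth, config = config)
  })
}

# Carve a 7-rank taxonomy out of the nested clades of an ultrametric tree:
# cutting the same dendrogram at increasing k gives nested, monophyletic
# groups at every rank.
.taxonomy_from_tree <- function(tree) {
  m <- length(tree$tip.label)
  hc <- ape::as.hclust.phylo(tree)
  ks <- c(phylum = max(2L, round(m / 60)), class = max(3L, round(m / 40)),
          order = max(4L, round(m / 25)), family = max(5L, round(m / 12)),
          genus = max(8L, round(m / 5)))
  ks <- pmin(cummax(ks), m)
  cuts <- lapply(ks, function(k) cutree(hc, k = k))
  data.frame(
    otu_id = tree$tip.label,
    kingdom = "Bacteria",
    phylum = sprintf("Phy%02d", cuts$phylum[tree$tip.label]),
    class = sprintf("Cls%02d", cuts$class[tree$tip.label]),
    order = sprintf("Ord%02d", cuts$order[tree$tip.label]),
    family = sprintf("Fam%03d", cuts$family[tree$tip.label]),
    genus = sprintf("Gen%03d", cuts$genus[tree$tip.label]),
    species = paste0("sp_", tree$tip.label),
    stringsAsFactors = FALSE)
}

#' Simulate a pathway-abundance table linked to chosen OTUs
#'
#' Stand-in for a predicted functional profile: each pathway is a weighted
#' sum of the relative abundances of its linked OTUs plus Gaussian noise,
#' clipped at zero.
#'
#' @param counts samples x OTUs count matrix.
#' @param linked_otus character vector of OTU IDs (one pathway), or a named
#'   list of such vectors (one pathway per element).
#' @param weights numeric vector aligned with `linked_otus` (or list of
#'   vectors); signed.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed integer seed.
#' @return samples x pathways non-negative matrix.
#' @export
simulate_pathway_table <- function(counts, linked_otus, weights,
                                   noise_sd = 0, seed = NULL) {
  validate_otu_table(counts)
  if (!is.list(linked_otus)) {
    linked_otus <- list(pathway1 = linked_otus)
    weights <- list(weights)
  }
  if (is.null(names(linked_otus)))
    names(linked_otus) <- sprintf("pathway%d", seq_along(linked_otus))
  rel <- relative_abundance(counts)
  .with_seed(seed, {
    cols <- lapply(seq_along(linked_otus), function(i) {
      otus <- linked_otus[[i]]
      w <- weights[[i]]
      missing <- setdiff(otus, colnames(rel))
      if (length(missing))
        stop("unknown OTU(s) in linked set: ", paste(missing, collapse = ", "))
      if (length(w) != length(otus))
        stop("weights and linked_otus lengths differ for pathway ", i)
      v <- as.vector(rel[, otus, drop = FALSE] %*% w) +
        rnorm(nrow(rel), 0, noise_sd)
      pmax(v, 0)
    })
    out <- do.call(cbind, cols)
    dimnames(out) <- list(rownames(rel), names(linked_otus))
    out
  })
}
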