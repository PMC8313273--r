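test_that("simulated datasets are deterministic and sum to depth", {
  cfg <- sim_config(n_samples_per_cell = 4, n_otus = 40, depth = 3000,
                    seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_true(all(rowSums(a$counts) == 3000))
  expect_equal(nrow(a$counts), 4 * 4 * 2)     # stages x groups x reps
  expect_setequal(unique(a$metadata$stage), c("E1", "E2", "E3", "E4"))
  expect_setequal(unique(a$metadata$group), c("NA", "NO"))
  # taxonomy covers every OTU with monophyletic nested ranks
  expect_setequal(a$taxonomy$otu_id, colnames(a$counts))
  fam_of_genus <- tapply(a$taxonomy$family, a$taxonomy$genus,
                         function(x) length(unique(x)))
  expect_true(all(fam_of_genus == 1))          # genera nest inside families
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_otus = 10, n_blocks = 3, block_size = 4,
                          n_stage_otus = 0, n_group_otus = 0),
               "planted structure exceeds")
  expect_error(sim_config(block_correlation = 1.2), "block_correlation")
  expect_error(sim_config(depth = 0), "positive")
})

test_that("within-block correlations exceed between-block correlations", {
  cfg <- sim_config(n_samples_per_cell = 60, n_otus = 40, depth = 20000,
                    n_blocks = 2, block_size = 5, block_correlation = 0.9,
                    n_stage_otus = 0, n_group_otus = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  logrel <- log(relative_abundance(sim$counts) + 1e-6)
  cc <- cor(logrel)
  bm <- sim$truth$block_membership
  b1 <- names(bm)[!is.na(bm) & bm == 1]
  b2 <- names(bm)[!is.na(bm) & bm == 2]
  within <- c(cc[b1, b1][upper.tri(diag(5))], cc[b2, b2][upper.tri(diag(5))])
  between <- as.vector(cc[b1, b2])
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.5)
})

test_that("a zero group effect gives nominal Wilcoxon type-I error", {
  cfg <- sim_config(n_samples_per_cell = 20, n_otus = 150, depth = 10000,
                    n_blocks = 0, block_size = 0, n_stage_otus = 0,
                    n_group_otus = 10, group_log2fc = 0, seed = 33)
  sim <- simulate_dataset(cfg)
  rel <- relative_abundance(sim$counts)
  grp <- sim$metadata$group
  pvals <- apply(rel, 2L, function(v)
    suppressWarnings(wilcox.test(v[grp == "NA"], v[grp == "NO"])$p.value))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("planted stage taxa carry larger Kruskal-Wallis statistics", {
  cfg <- sim_config(n_samples_per_cell = 50, n_otus = 60, depth = 10000,
                    n_blocks = 0, block_size = 0, n_stage_otus = 10,
                    stage_amplitude = 1.5, n_group_otus = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  rel <- relative_abundance(sim$counts)
  H <- apply(rel, 2L, function(v)
    kruskal_wallis_by_group(v, sim$metadata$stage)$H)
  planted <- names(sim$truth$stage_otus)
  expect_gt(mean(H[planted]), mean(H[setdiff(colnames(rel), planted)]))
})

test_that("pathway simulation links, calibrates and repeats", {
  cfg <- sim_config(n_samples_per_cell = 15, n_otus = 30, depth = 8000,
                    n_blocks = 0, block_size = 0, n_stage_otus = 0,
                    n_group_otus = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  # single positive weight, no noise: Spearman rho = 1 (monotone transform)
  pw <- simulate_pathway_table(sim$counts, "OTU0001", 2.5, noise_sd = 0,
                               seed = 1)
  expect_equal(cor(pw[, 1], relative_abundance(sim$counts)[, "OTU0001"],
                   method = "spearman"), 1)
  # all-zero weights + noise: null correlation with every OTU stays modest
  pw0 <- simulate_pathway_table(sim$counts, colnames(sim$counts)[1:3],
                                c(0, 0, 0), noise_sd = 1, seed = 2)
  rel <- relative_abundance(sim$counts)
  rhos <- apply(rel, 2L, function(v) cor(pw0[, 1], v, method = "spearman"))
  # 120 samples: null |rho| should stay below ~4/sqrt(n)
  expect_lt(max(abs(rhos)), 4 / sqrt(nrow(rel)))
  expect_identical(pw0, simulate_pathway_table(sim$counts,
                                               colnames(sim$counts)[1:3],
                                               c(0, 0, 0), noise_sd = 1,
                                               seed = 2))
  expect_error(simulate_pathway_table(sim$counts, "nope", 1), "unknown OTU")
})
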