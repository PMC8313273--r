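test_that("Chao1 matches hand-computed corrected and classic forms", {
  # 10 observed OTUs, 4 singletons, 2 doubletons:
  # corrected 10 + 4*3/(2*3) = 12; classic 10 + 16/4 = 14
  x <- c(1, 1, 1, 1, 2, 2, 5, 7, 9, 11)
  tb <- make_counts(matrix(x, 1))
  expect_equal(alpha_diversity(tb)$chao1, 12)
  expect_equal(alpha_diversity(tb, chao1_bias_corrected = FALSE)$chao1, 14)
  # chao1 never falls below observed richness
  set.seed(8)
  rnd <- make_counts(matrix(rpois(5 * 30, 1.5), 5, 30))
  rnd[rowSums(rnd) == 0, 1] <- 1
  a <- alpha_diversity(rnd)
  expect_true(all(a$chao1 >= a$observed))
})

test_that("Shannon and PD closed forms", {
  tb <- make_counts(matrix(rep(5, 8), 1), otus = sprintf("t%d", 1:8))
  expect_equal(alpha_diversity(tb)$shannon, log(8))
  # star tree, unit branches, 5 of 9 leaves observed -> PD = 5
  tr <- star_tree(9)
  tb2 <- make_counts(matrix(c(rep(1, 5), rep(0, 4)), 1),
                     otus = sprintf("t%d", 1:9))
  expect_equal(alpha_diversity(tb2, tr)$pd, 5)
  expect_error(alpha_diversity(make_counts(matrix(1, 1, 1), otus = "zz"), tr),
               "missing from tree")
})

test_that("unweighted UniFrac closed forms and oracle agreement", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tb <- make_counts(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1)),
                    otus = c("a", "b", "c", "d"))
  d <- as.matrix(unweighted_unifrac(tb, tr))
  expect_equal(d["S01", "S02"], 0)          # identical profiles
  expect_equal(d["S01", "S03"], 1)          # disjoint root clades
  expect_error(unweighted_unifrac(make_counts(rbind(c(1, 0), c(0, 0)),
                                              otus = c("a", "b")), tr),
               "zero observed")

  # random 6-leaf trees, random presence patterns vs branch oracle,
  # plus agreement with picante's implementation
  set.seed(5)
  for (rep in 1:5) {
    tr6 <- ape::rtree(6)
    tr6$tip.label <- letters[1:6]
    pres <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6,
                   dimnames = list(sprintf("S%d", 1:4), letters[1:6]))
    pres[rowSums(pres) == 0, 1] <- 1
    ours <- as.matrix(unweighted_unifrac(pres, tr6))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(ours[i, j],
                   unifrac_branch_oracle(pres[i, ], pres[j, ], tr6))
    }
    pic <- as.matrix(picante::unifrac(pres, tr6))
    expect_equal(ours, pic[rownames(ours), colnames(ours)],
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis hand computation and bounds", {
  tb <- make_counts(rbind(c(2, 2), c(2, 0)))
  expect_equal(as.numeric(bray_curtis(tb, on = "counts")), 2 / 6)
  tb2 <- make_counts(rbind(c(3, 0), c(0, 7)))
  expect_equal(as.numeric(bray_curtis(tb2)), 1)          # disjoint supports
  tb3 <- make_counts(rbind(c(1, 2), c(2, 4)))
  expect_equal(as.numeric(bray_curtis(tb3)), 0)          # identical profiles
  set.seed(1)
  rnd <- make_counts(matrix(rpois(6 * 10, 5) + 1, 6, 10))
  d <- as.matrix(bray_curtis(rnd))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points 0, 1, 2
  d <- dist(matrix(c(0, 1, 2), 3))
  attr(d, "Labels") <- c("p1", "p2", "p3")
  ord <- suppressWarnings(pcoa_ordination(d, 2))
  # first axis reproduces the line up to sign
  ax <- unname(ord$coordinates[, 1]) - ord$coordinates[1, 1]
  expect_equal(abs(ax), c(0, 1, 2), tolerance = 1e-9)
  # general Euclidean input: distances reproduced exactly
  set.seed(2)
  X <- matrix(rnorm(7 * 3), 7, 3, dimnames = list(sprintf("s%d", 1:7), NULL))
  d2 <- dist(X)
  ord2 <- pcoa_ordination(d2, 3)
  expect_equal(as.matrix(dist(ord2$coordinates)), as.matrix(d2),
               tolerance = 1e-9, ignore_attr = TRUE)
  # equilateral triangle: two equal positive eigenvalues
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                       dimnames = list(letters[1:3], letters[1:3])))
  ord3 <- pcoa_ordination(d3, 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  # sign convention: first nonzero loading positive
  expect_true(all(apply(ord2$coordinates, 2L, function(v)
    v[which(abs(v) > 1e-12)[1L]] > 0)))
})

test_that("PERMANOVA partitions, detects and errors on bad factors", {
  # single factor: R2_factor + R2_residual = 1 exactly
  set.seed(3)
  X <- matrix(rnorm(20 * 4), 20, 4)
  ids <- sprintf("s%d", 1:20)
  rownames(X) <- ids
  meta <- data.frame(sample_id = ids, g = rep(c("a", "b"), 10),
                     stringsAsFactors = FALSE)
  d <- dist(X)
  res <- permanova(d, meta, "g", n_perm = 99, seed = 1)
  expect_equal(sum(res$R2[res$term %in% c("g", "Residual")]), 1,
               tolerance = 1e-12)
  # two well-separated clusters: R2 near 1, best possible p
  X2 <- rbind(matrix(rnorm(10 * 2, 0, 0.01), 10, 2),
              matrix(rnorm(10 * 2, 50, 0.01), 10, 2))
  rownames(X2) <- ids
  meta$g <- rep(c("a", "b"), each = 10)   # first cluster = a, second = b
  # metadata rows shuffled on purpose: matching is by sample_id
  res2 <- permanova(dist(X2), meta[sample(nrow(meta)), ], "g",
                    n_perm = 199, seed = 1)
  expect_gt(res2$R2[1], 0.99)
  expect_equal(res2$p[1], 1 / 200)
  # single-level and aliased factors are rejected
  meta$one <- "x"
  expect_error(permanova(d, meta, "one"), "single level")
  meta$g2 <- meta$g
  expect_error(permanova(d, meta, c("g", "g2")), "aliased")
})

test_that("Kruskal-Wallis wrapper matches the rank formula and conventions", {
  # two groups with fully separated ranks, n = 5 + 5
  v <- c(1:5, 11:15)
  g <- rep(c("a", "b"), each = 5)
  res <- kruskal_wallis_by_group(v, g)
  H_hand <- 12 / (10 * 11) * (5 * (3 - 5.5)^2 + 5 * (8 - 5.5)^2)
  expect_equal(res$H, H_hand)
  # label-order invariance
  perm <- sample(10)
  expect_equal(kruskal_wallis_by_group(v[perm], g[perm])$H, res$H)
  # all-identical values: H = 0, p = 1 by convention
  expect_equal(kruskal_wallis_by_group(rep(2, 6), rep(c("a", "b"), 3)),
               list(H = 0, df = 1L, p = 1))
  expect_error(kruskal_wallis_by_group(1:3, c("a", "a", "a")), "two groups")
})
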