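test_that("OTU table TSV round-trips and malformed input is rejected", {
  tb <- make_counts(matrix(c(4, 1, 0, 0, 2, 5), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tb, path)
  back <- read_otu_table(path)
  expect_identical(back, tb)

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1\t2", "s2\t3"), ragged)
  expect_error(read_otu_table(ragged), "line 3")

  badcell <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1\tx"), badcell)
  expect_error(read_otu_table(badcell), "non-numeric cell.*'s1'.*'B'")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1\t-2"), neg)
  expect_error(read_otu_table(neg), "negative")

  # transposed orientation flag
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(otu_id = colnames(tb), t(tb), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_otu_table(tpath, transposed = TRUE), tb)
})

test_that("rarefaction hits the exact depth, is seeded, drops short samples", {
  tb <- make_counts(rbind(c(10, 10), c(5, 0), c(40, 25)))
  expect_warning(r <- rarefy_table(tb, 20, seed = 1), "dropping 1 sample")
  expect_true(all(rowSums(r) == 20))
  # depth equal to the total leaves counts unchanged
  expect_equal(unname(r["S01", ]), c(10, 10))
  expect_identical(attr(r, "dropped_samples"), "S02")
  # single nonzero OTU keeps everything in it
  tb2 <- make_counts(matrix(c(5, 0), 1, 2))
  expect_equal(unname(rarefy_table(tb2, 3, seed = 1)[1L, ]), c(3, 0))
  # determinism
  r2 <- suppressWarnings(rarefy_table(tb, 20, seed = 1))
  expect_identical(r, r2)
  expect_error(rarefy_table(tb, 0), "depth")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # 50+50 reads subsampled to 10: first-OTU count ~ Hypergeometric(100,50,10)
  tb <- make_counts(matrix(c(50, 50), 1, 2))
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(s)
    rarefy_table(tb, 10, seed = s)[1L, 1L], numeric(1L))
  mu <- 10 * 50 / 100
  vr <- 10 * 0.5 * 0.5 * (100 - 10) / (100 - 1)
  se <- sqrt(vr / n_rep)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("filter_otus evaluates both predicates and is idempotent", {
  set.seed(42)
  tb <- make_counts(matrix(rpois(10 * 8, 20), 10, 8))
  tb[, 2] <- 0                              # all-zero OTU
  tb[4:10, 3] <- 0                          # prevalence 3/10
  a_thr <- 0.0005; p_thr <- 0.2
  rel <- tb / rowSums(tb)
  keep_oracle <- colMeans(rel) >= a_thr & colMeans(tb > 0) >= p_thr
  f <- filter_otus(tb, a_thr, p_thr)
  expect_identical(colnames(f), colnames(tb)[keep_oracle])
  expect_false("OTU02" %in% colnames(f))    # zero OTU removed
  expect_identical(filter_otus(f, a_thr, p_thr), f)  # idempotent
  expect_identical(filter_otus(tb, 0, 0), tb)        # no-op thresholds
  expect_error(filter_otus(tb, 1, 1), "all OTUs removed")
  # prevalence alone removes an abundant but rare-prevalence OTU
  tb2 <- make_counts(matrix(1, 10, 2))
  tb2[2:10, 1] <- 0
  tb2[1, 1] <- 1000
  expect_identical(colnames(filter_otus(tb2, 0.0005, 0.2)), "OTU02")
})

test_that("relative abundance normalises rows and rejects empty samples", {
  tb <- make_counts(rbind(c(1, 3, 0), c(5, 0, 0)))
  rel <- relative_abundance(tb)
  expect_equal(unname(rel[1L, ]), c(0.25, 0.75, 0))
  expect_equal(unname(rel[2L, ]), c(1, 0, 0))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  bad <- make_counts(rbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(bad), "S02")
})

test_that("taxonomic aggregation is additive, conservative and hierarchical", {
  tb <- make_counts(rbind(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.3, 0.2, 0.1)))
  tax <- data.frame(
    otu_id = colnames(tb),
    kingdom = "Bacteria", phylum = c("P1", "P1", "P2", "P2"),
    class = "C", order = "O", family = c("F1", "F1", "F2", "F2"),
    genus = c("G1", "G1", "G2", ""), species = c("s1", "s2", "s3", ""),
    stringsAsFactors = FALSE)
  gen <- aggregate_taxonomy(tb, tax, "genus")
  g1 <- grep("G1$", colnames(gen))
  expect_equal(unname(gen[1L, g1]), 0.3)
  # missing genus pooled into unclassified bucket named by the parent
  expect_true(any(grepl("^unclassified_F2$", colnames(gen))))
  expect_equal(unname(rowSums(gen)), unname(rowSums(tb)))  # conservation

  # species-level aggregation then pooling to genus == direct genus
  sp <- aggregate_taxonomy(tb, tax, "species")
  pooled <- sapply(colnames(gen), function(gcol) {
    member <- if (startsWith(gcol, "unclassified")) {
      grepl("^unclassified", colnames(sp))
    } else {
      startsWith(colnames(sp), paste0(gcol, ";"))
    }
    rowSums(sp[, member, drop = FALSE])
  })
  expect_equal(unname(pooled), unname(gen))
  expect_error(aggregate_taxonomy(tb, tax, "clade"), "unknown rank")
})

test_that("taxonomy reader strips greengenes prefixes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tlineage",
               "OTU1\tk__Bacteria;p__Firmicutes;c__Clostridia",
               "OTU2\tk__Bacteria"), path)
  tax <- read_taxonomy(path)
  expect_equal(tax$phylum, c("Firmicutes", ""))
  expect_equal(tax$class, c("Clostridia", ""))
  expect_equal(tax$species, c("", ""))
})

test_that("tree reader enforces rooted trees with branch lengths", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):0.5,(c:1,d:1):0.5);", p)
  tr <- read_tree(p)
  expect_true(ape::is.rooted(tr))
  writeLines("((a,b),(c,d));", p)
  expect_error(read_tree(p), "branch lengths")
})
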