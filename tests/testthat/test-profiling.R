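# Relative-abundance normalization, rank aggregation, richness and
# shared/exclusive taxon sets.

test_that("column normalization follows the relative-abundance formula", {
  m <- matrix(c(2, 2, 4), ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
  out <- normalize_relative(abundance_table(m))
  expect_equal(unname(out$values[, 1]), c(0.25, 0.25, 0.5))
  expect_true(out$normalized)

  one <- matrix(5, dimnames = list("g1", "s1"))
  expect_equal(unname(normalize_relative(abundance_table(one))$values[1, 1]), 1)

  z <- matrix(c(1, 1, 0, 0), ncol = 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_warning(outz <- normalize_relative(abundance_table(z)), "all-zero")
  expect_equal(unname(outz$values[, "s2"]), c(0, 0))

  # idempotence
  tab <- random_gene_table(tiny_metadata(3L), n_genes = 20L, seed = 2)
  expect_equal(normalize_relative(tab)$values, tab$values, tolerance = 1e-12)
})

test_that("gene-length correction divides by length before normalizing", {
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  out <- normalize_relative(abundance_table(m), gene_lengths = c(g1 = 100, g2 = 300))
  expect_equal(unname(out$values[, 1]), c(0.75, 0.25))
  expect_error(normalize_relative(abundance_table(m), gene_lengths = c(g1 = 0, g2 = 1)),
               "positive")
})

test_that("negative or malformed tables are rejected", {
  m <- matrix(c(-1, 1), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_error(abundance_table(m), "non-negative")
  expect_error(abundance_table(matrix(0.5, dimnames = list("a", "s")), normalized = TRUE),
               "sum to 1")
})

test_that("taxonomic aggregation is additive and conserves per-sample mass", {
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    phylum = c("P1", "P1", "unclassified"),
                    genus = c("GA", "GA", "unclassified"),
                    species = c("s1", "s2", "unclassified"),
                    kos = c("K1;K2", "K1", ""), stringsAsFactors = FALSE)
  m <- matrix(c(0.3, 0.2, 0.5), ncol = 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  tab <- abundance_table(m, normalized = TRUE)
  g <- aggregate_rank(tab, ann, "genus")
  expect_equal(g$values["GA", "s1"], 0.5)
  expect_equal(g$values["unclassified", "s1"], 0.5)
  expect_equal(colSums(g$values), colSums(m), tolerance = 1e-12)

  # KO multi-mapping duplicates mass: K1 gets g1+g2, K2 gets g1 alone
  ko <- aggregate_rank(tab, ann, "KO")
  expect_equal(ko$values["K1", "s1"], 0.5)
  expect_equal(ko$values["K2", "s1"], 0.3)
  expect_false(ko$normalized)

  # all genes unclassified at species level -> one row with all the mass
  ann2 <- ann; ann2$species <- "unclassified"
  sp <- aggregate_rank(tab, ann2, "species")
  expect_equal(rownames(sp$values), "unclassified")
  expect_equal(unname(sp$values[1, 1]), 1)
})

test_that("aggregation conserves mass on random simulated tables", {
  sim <- simulate_cohort_study(community = small_community(), seed = 13)
  for (rk in c("phylum", "genus", "species")) {
    agg <- aggregate_rank(sim$table, sim$annotation, rk)
    expect_lt(max(abs(colSums(agg$values) - colSums(sim$table$values))), 1e-12)
  }
})

test_that("unknown gene ids in aggregation are reported", {
  tab <- random_gene_table(tiny_metadata(2L), n_genes = 5L, seed = 1)
  ann <- data.frame(gene = features(tab)[-1], phylum = "P", genus = "G",
                    species = "S", kos = "", stringsAsFactors = FALSE)
  expect_error(aggregate_rank(tab, ann, "genus"), "gene001")
})

test_that("richness counts strictly positive entries and ignores scaling", {
  m <- matrix(c(0, 0.1, 0.9, 0, 0, 0), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  tab <- abundance_table(m)
  expect_equal(unname(gene_richness(tab)), c(2L, 0L))
  scaled <- abundance_table(m * 7)
  expect_equal(gene_richness(scaled), gene_richness(tab))
  expect_error(gene_richness(tab, samples = "nope"), "unknown sample")

  # binomial expectation at occupancy 0.5 over 1000 genes
  set.seed(8)
  occ <- matrix(rbinom(1000, 1, 0.5) * rexp(1000), ncol = 1,
                dimnames = list(sprintf("g%04d", 1:1000), "s1"))
  r <- unname(gene_richness(abundance_table(occ)))
  expect_lt(abs(r - 500), 3 * sqrt(1000 * 0.25))
})

test_that("shared/exclusive taxa form a partition of present taxa", {
  md <- tiny_metadata(2L)
  m <- matrix(0, nrow = 3, ncol = 4, dimnames = list(c("A", "B", "C"), md$sample_id))
  m[c("A", "B"), ] <- 1                       # both sites
  m["C", md$site == "feces"] <- 1             # feces only
  se <- shared_exclusive_taxa(abundance_table(m), md)
  expect_equal(se$shared, c("A", "B"))
  expect_equal(se$exclusive_feces, "C")
  expect_equal(se$exclusive_mucosa, character(0))

  m2 <- matrix(runif(12) + 0.1, nrow = 3, dimnames = dimnames(m))
  se2 <- shared_exclusive_taxa(abundance_table(m2), md)
  expect_equal(se2$shared, c("A", "B", "C"))

  # the three sets partition all present taxa on a random sparse table
  tab <- random_gene_table(tiny_metadata(5L), n_genes = 40L, seed = 3, sparsity = 0.6)
  se3 <- shared_exclusive_taxa(tab, tiny_metadata(5L))
  all_present <- features(tab)[rowSums(tab$values) > 0]
  expect_setequal(c(se3$shared, se3$exclusive_mucosa, se3$exclusive_feces), all_present)
  expect_length(intersect(se3$shared, se3$exclusive_mucosa), 0)
  expect_length(intersect(se3$exclusive_mucosa, se3$exclusive_feces), 0)
})

test_that("planted mucosa-exclusive genera are recovered exactly", {
  sim <- simulate_cohort_study(community = small_community(), seed = 21)
  g <- aggregate_rank(sim$table, sim$annotation, "genus")
  se <- shared_exclusive_taxa(g, sim$metadata)
  expect_identical(se$exclusive_mucosa, sim$ground_truth$mucosa_exclusive_genera)
})

test_that("top taxa ranking sorts by site mean with lexicographic ties", {
  md <- tiny_metadata(2L)
  m <- matrix(0, nrow = 3, ncol = 4, dimnames = list(c("A", "B", "C"), md$sample_id))
  m["A", md$site == "mucosa"] <- 0.5
  m["B", md$site == "mucosa"] <- 0.3
  m["C", md$site == "mucosa"] <- 0.2
  expect_equal(top_n_taxa(abundance_table(m), md, "mucosa", 2), c("A", "B"))

  tied <- abundance_table(matrix(1, 3, 4, dimnames = dimnames(m)))
  expect_equal(top_n_taxa(tied, md, "mucosa", 3), c("A", "B", "C"))
  expect_message(all3 <- top_n_taxa(tied, md, "mucosa", 10), "returning all")
  expect_length(all3, 3)

  # oracle equivalence on a random table
  tab <- random_gene_table(tiny_metadata(6L), n_genes = 25L, seed = 5)
  md6 <- tiny_metadata(6L)
  means <- rowMeans(tab$values[, md6$site == "feces"])
  oracle <- names(sort(means, decreasing = TRUE))  # no ties w.p. 1
  expect_equal(top_n_taxa(tab, md6, "feces", 25), oracle)
})
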