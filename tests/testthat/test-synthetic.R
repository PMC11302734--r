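# Synthetic paired-cohort generator: cohort structure, annotation
# consistency, and the generative model's stated behavior.

test_that("cohort generation respects pairing, gender counts and determinism", {
  md <- generate_cohort(cohort_config(n_subjects = 20L, gender_ratio = 0.6), seed = 5)
  expect_equal(nrow(md), 40L)
  expect_equal(unname(table(md$subject_id)), rep(2L, 20L), ignore_attr = TRUE)
  expect_true(all(table(md$subject_id, md$site) == 1L))
  expect_equal(sum(md$gender == "male") / 2L, 12)
  expect_true(all(md$age >= 44 & md$age <= 68))
  expect_true(all(md$bmi >= 19.7 & md$bmi <= 27))
  expect_equal(unname(table(md$polyp_group) / 2L), c(3, 12, 5), ignore_attr = TRUE)

  md2 <- generate_cohort(cohort_config(n_subjects = 2L, gender_ratio = 0.5,
                                       polyp_group_sizes = c(1L, 1L, 0L)), seed = 1)
  expect_equal(nrow(md2), 4L)
  expect_true(all(table(md2$subject_id) == 2L))

  expect_identical(generate_cohort(cohort_config(), seed = 42),
                   generate_cohort(cohort_config(), seed = 42))
  expect_false(identical(generate_cohort(cohort_config(), seed = 1),
                         generate_cohort(cohort_config(), seed = 2)))
})

test_that("invalid cohort configurations are rejected naming the field", {
  expect_error(cohort_config(n_subjects = 1L), "n_subjects")
  expect_error(cohort_config(age_range = c(60, 50)), "age_range")
  expect_error(cohort_config(gender_ratio = 1.5), "gender_ratio")
  expect_error(cohort_config(polyp_group_sizes = c(3L, 12L, 6L)), "polyp_group_sizes")
})

test_that("annotation maps are internally consistent and deterministic", {
  cfg <- community_config(n_genes = 100L, n_phyla = 3L, n_genera = 10L,
                          n_species = 20L, n_kos = 20L, n_pathways = 5L,
                          mucosa_exclusive_genera = 1L, feces_exclusive_genera = 2L)
  ann <- generate_annotation(cfg, seed = 3)
  a <- ann$annotation
  expect_equal(nrow(a), 100L)
  expect_false(anyDuplicated(a$gene) > 0)

  cl <- a[a$species != "unclassified", ]
  expect_true(all(!duplicated(unique(cl[, c("species", "genus")])$species)))
  expect_true(all(!duplicated(unique(cl[, c("genus", "phylum")])$genus)))

  # every pathway holds at least one KO, and pathway KOs are real KO ids
  expect_setequal(unique(ann$pathways$pathway), sprintf("map%05d", 1:5))
  expect_true(all(ann$pathways$ko %in% sprintf("K%05d", 1:20)))
  ko_universe <- setdiff(unique(unlist(strsplit(a$kos, ";"))), "")
  expect_true(all(ko_universe %in% sprintf("K%05d", 1:20)))
  # per-gene KO lists carry no duplicates
  expect_true(all(vapply(strsplit(a$kos, ";"), anyDuplicated, integer(1)) == 0L))

  expect_identical(ann, generate_annotation(cfg, seed = 3))

  cfg1 <- community_config(n_genes = 50L, n_phyla = 2L, n_genera = 5L,
                           n_species = 10L, n_kos = 8L, n_pathways = 1L,
                           mucosa_exclusive_genera = 0L, feces_exclusive_genera = 0L)
  ann1 <- generate_annotation(cfg1, seed = 1)
  expect_equal(unique(ann1$pathways$pathway), "map00001")
  expect_setequal(ann1$pathways$ko, sprintf("K%05d", 1:8))
})

test_that("invalid community configurations are rejected naming the field", {
  expect_error(community_config(n_species = 10L, n_genera = 20L), "n_species")
  expect_error(community_config(mucosa_occupancy = 0), "mucosa_occupancy")
  expect_error(community_config(mucosa_occupancy = 0.95, feces_occupancy = 0.9),
               "mucosa_occupancy")
  expect_error(community_config(site_effects = data.frame(feature = "G001", level = "genus",
                                                          log2fc = Inf, site = "mucosa")),
               "log2fc")
})

test_that("null generator plants nothing, normalizes columns and orders richness", {
  sim <- simulate_cohort_study(community = small_community(), seed = 9)
  expect_equal(nrow(sim$ground_truth$differential_features), 0L)
  expect_true(all(abs(colSums(sim$table$values) - 1) < 1e-9))
  mucosa <- sim$metadata$sample_id[sim$metadata$site == "mucosa"]
  feces <- sim$metadata$sample_id[sim$metadata$site == "feces"]
  expect_gt(mean(gene_richness(sim$table, feces)), mean(gene_richness(sim$table, mucosa)))
  expect_identical(sim$table$values,
                   simulate_cohort_study(community = small_community(), seed = 9)$table$values)
})

test_that("per-sample richness matches the binomial occupancy expectation", {
  cfg <- community_config(n_genes = 10000L, mucosa_occupancy = 0.01, feces_occupancy = 0.9,
                          mucosa_exclusive_genera = 0L, feces_exclusive_genera = 0L)
  sim <- simulate_cohort_study(community = cfg, seed = 2)
  mucosa <- sim$metadata$sample_id[sim$metadata$site == "mucosa"]
  feces <- sim$metadata$sample_id[sim$metadata$site == "feces"]
  rm_ <- mean(gene_richness(sim$table, mucosa))
  rf <- mean(gene_richness(sim$table, feces))
  expect_lt(abs(rm_ - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  expect_lt(abs(rf - 9000), 3 * sqrt(10000 * 0.9 * 0.1))
})

test_that("planted genus enrichment is realized in cohort mean abundances", {
  eff <- site_effects("G001", log2fc = 2, site = "mucosa")
  cfg <- small_community(site_effects = eff)
  gap <- vapply(1:50, function(s) {
    sim <- simulate_cohort_study(community = cfg, seed = s)
    g <- aggregate_rank(sim$table, sim$annotation, "genus")
    site <- sim$metadata$site[match(sample_ids(g), sim$metadata$sample_id)]
    mean(g$values["G001", site == "mucosa"]) - mean(g$values["G001", site == "feces"])
  }, numeric(1))
  expect_gt(mean(gap), 0)
  expect_gt(mean(gap > 0), 0.9)
})

test_that("phenotype effects multiply the enriched group's samples", {
  eff <- phenotype_effects("G002", log2fc = 3, variable = "gender", group = "male")
  cfg <- small_community(phenotype_effects = eff)
  sim <- simulate_cohort_study(community = cfg, seed = 4)
  expect_equal(sim$ground_truth$differential_features$type, "phenotype")
  expect_equal(sim$ground_truth$differential_features$enriched, "male")
  g <- aggregate_rank(sim$table, sim$annotation, "genus")
  md <- sim$metadata[match(sample_ids(g), sim$metadata$sample_id), ]
  mucosa_male <- md$site == "mucosa" & md$gender == "male"
  mucosa_female <- md$site == "mucosa" & md$gender == "female"
  expect_gt(mean(g$values["G002", mucosa_male]), mean(g$values["G002", mucosa_female]))
})

test_that("effects referencing unknown features are rejected", {
  cfg <- small_community(site_effects = site_effects("G999", log2fc = 1, site = "mucosa"))
  md <- generate_cohort(cohort_config(), seed = 1)
  expect_error(generate_paired_abundances(md, cfg, seed = 1), "G999")
})
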