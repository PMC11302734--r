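#' Community configuration for the paired-sample simulator
#'
#' Describes the synthetic gene catalog and the generative model for paired
#' mucosa/feces abundance profiles. Genes carry a per-subject log-normal
#' baseline shared by the subject's two samples plus independent per-sample
#' log-normal noise; planted site or phenotype
#' effects act as multiplicative fold-changes on the genes of the named
#' feature; an independent Bernoulli presence mask per gene x sample (with a
#' site-specific occupancy) creates the mucosa/feces richness asymmetry; and
#' each sample is finally renormalized to relative abundances.
#'
#' The defaults define a desk-scale community: 4000 genes over 8 phyla,
#' 80 genera and 160 species, 500 KOs in 40 pathways; mucosa occupancy 0.06
#' versus feces 0.90 (a roughly 15-fold per-sample gene-richness gap); 3
#' genera exclusive to the mucosa and 36 exclusive to feces, leaving about
#' half of the genera shared between sites.
#'
#' @param n_genes,n_phyla,n_genera,n_species,n_kos,n_pathways catalog sizes;
#'   `n_phyla <= n_genera <= n_species <= n_genes` and
#'   `n_pathways <= n_kos` are required.
#' @param base_log_mean,base_log_sd mean and SD of the per-subject natural-log
#'   gene baseline (shared by the subject's two samples).
#' @param sample_log_sd SD of the additional per-sample natural-log noise on
#'   every gene (independent across the two samples of a subject). This
#'   models within-subject sampling/measurement variability; without it the
#'   paired samples would differ only through the presence mask and all
#'   features would inherit a single common compositional drift per subject,
#'   which no real paired design exhibits.
#' @param mucosa_occupancy,feces_occupancy per-gene presence probability in a
#'   mucosa / feces sample, in `(0, 1]` with
#'   `mucosa_occupancy <= feces_occupancy`. Equal occupancies give a
#'   site-exchangeable null generator used for type-I calibration; a strict
#'   gap reproduces the feces-over-mucosa richness ordering.
#' @param mucosa_exclusive_genera,feces_exclusive_genera number of genera
#'   whose genes are masked out entirely from the other site.
#' @param unclassified_fraction fraction of genes left taxonomically
#'   unclassified at all ranks.
#' @param site_effects optional data.frame from [site_effects()]: planted
#'   site-differential features.
#' @param phenotype_effects optional data.frame from [phenotype_effects()]:
#'   planted phenotype-differential features.
#' @return a validated `community_config` list.
#' @export
community_config <- function(n_genes = 4000L,
                             n_phyla = 8L,
                             n_genera = 80L,
                             n_species = 160L,
                             n_kos = 500L,
                             n_pathways = 40L,
                             base_log_mean = 0,
                             base_log_sd = 1,
                             sample_log_sd = 0.5,
                             mucosa_occupancy = 0.06,
                             feces_occupancy = 0.9,
                             mucosa_exclusive_genera = 3L,
                             feces_exclusive_genera = 36L,
                             unclassified_fraction = 0.05,
                             site_effects = NULL,
                             phenotype_effects = NULL) {
  for (f in c("n_genes", "n_phyla", "n_genera", "n_species", "n_kos", "n_pathways")) {
    if (!is_count(get(f))) stop_config(f, "must be a positive integer")
  }
  if (n_genera < n_phyla) stop_config("n_genera", "must be >= n_phyla")
  if (n_species < n_genera) stop_config("n_species", "must be >= n_genera")
  if (n_genes < n_species) stop_config("n_genes", "must be >= n_species")
  if (n_kos < n_pathways) stop_config("n_pathways", "must be <= n_kos")
  if (!is.numeric(base_log_sd) || base_log_sd <= 0) stop_config("base_log_sd", "must be > 0")
  if (!is.numeric(sample_log_sd) || sample_log_sd < 0) stop_config("sample_log_sd", "must be >= 0")
  for (f in c("mucosa_occupancy", "feces_occupancy")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      stop_config(f, "must be in (0, 1]")
    }
  }
  if (mucosa_occupancy > feces_occupancy) {
    stop_config("mucosa_occupancy", "must be <= feces_occupancy (feces is the richer site)")
  }
  if (!is_count(mucosa_exclusive_genera, 0L) || !is_count(feces_exclusive_genera, 0L)) {
    stop_config("mucosa_exclusive_genera", "and feces_exclusive_genera must be non-negative integers")
  }
  if (mucosa_exclusive_genera + feces_exclusive_genera >= n_genera) {
    stop_config("feces_exclusive_genera", "exclusive genera must leave at least one shared genus")
  }
  if (!is.numeric(unclassified_fraction) || unclassified_fraction < 0 || unclassified_fraction >= 1) {
    stop_config("unclassified_fraction", "must be in [0, 1)")
  }
  if (!is.null(site_effects)) site_effects <- validate_effects(site_effects, kind = "site")
  if (!is.null(phenotype_effects)) phenotype_effects <- validate_effects(phenotype_effects, kind = "phenotype")
  structure(list(n_genes = as.integer(n_genes), n_phyla = as.integer(n_phyla),
                 n_genera = as.integer(n_genera), n_species = as.integer(n_species),
                 n_kos = as.integer(n_kos), n_pathways = as.integer(n_pathways),
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 sample_log_sd = sample_log_sd,
                 mucosa_occupancy = mucosa_occupancy, feces_occupancy = feces_occupancy,
                 mucosa_exclusive_genera = as.integer(mucosa_exclusive_genera),
                 feces_exclusive_genera = as.integer(feces_exclusive_genera),
                 unclassified_fraction = unclassified_fraction,
                 site_effects = site_effects, phenotype_effects = phenotype_effects),
            class = "community_config")
}

#' Planted site-differential effects
#'
#' @param feature feature ids (genes, taxa or KOs depending on `level`).
#' @param log2fc log2 fold-change of the enrichment (e.g. 2 for 4-fold).
#' @param site site in which the feature is enriched.
#' @param level feature level at which the id is interpreted; effects are
#'   applied to all genes annotated to the feature, so aggregation to higher
#'   ranks is itself exercised.
#' @return data.frame with columns `feature`, `level`, `log2fc`, `site`.
#' @export
site_effects <- function(feature, log2fc = 2, site = "mucosa",
                         level = c("genus", "gene", "species", "phylum", "KO")) {
  level <- match.arg(level)
  validate_effects(data.frame(feature = as.character(feature), level = level,
                              log2fc = log2fc, site = site,
                              stringsAsFactors = FALSE), kind = "site")
}

#' Planted phenotype-differential effects
#'
#' @inheritParams site_effects
#' @param variable phenotype variable (`"age"`, `"gender"`, `"bmi"`,
#'   `"polyp_risk"`).
#' @param group label of the enriched group under the default grouping
#'   scheme for that variable (see [grouping_scheme()]), e.g. `"HIGH"`,
#'   `"male"`, `"UP"`, `"Group 3"`.
#' @return data.frame with columns `feature`, `level`, `log2fc`, `variable`,
#'   `group`.
#' @export
phenotype_effects <- function(feature, log2fc = 2, variable = "gender",
                              group = "male",
                              level = c("genus", "gene", "species", "phylum", "KO")) {
  level <- match.arg(level)
  validate_effects(data.frame(feature = as.character(feature), level = level,
                              log2fc = log2fc, variable = variable, group = group,
                              stringsAsFactors = FALSE), kind = "phenotype")
}

validate_effects <- function(df, kind = c("site", "phenotype")) {
  kind <- match.arg(kind)
  need <- if (kind == "site") c("feature", "level", "log2fc", "site") else
    c("feature", "level", "log2fc", "variable", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_config(paste0(kind, "_effects"),
                sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(df$log2fc))) stop_config(paste0(kind, "_effects"), "log2fc must be finite")
  if (!all(df$level %in% c("gene", "phylum", "genus", "species", "KO"))) {
    stop_config(paste0(kind, "_effects"), "level must be gene/phylum/genus/species/KO")
  }
  if (kind == "site" && !all(df$site %in% c("mucosa", "feces"))) {
    stop_config("site_effects", "site must be 'mucosa' or 'feces'")
  }
  if (kind == "phenotype" && !all(df$variable %in% c("age", "gender", "bmi", "polyp_risk"))) {
    stop_config("phenotype_effects", "variable must be age/gender/bmi/polyp_risk")
  }
  df
}

#' Generate a synthetic gene annotation and pathway map
#'
#' Builds a consistent taxonomy (every gene maps to one species, species
#' nest within genera and genera within phyla), a gene-to-KO map in which a
#' gene carries 0-2 KOs, and a pathway map assigning every KO to one or two
#' pathways (every pathway holds at least one KO). A configured fraction of
#' genes is left `"unclassified"` at all taxonomic ranks.
#'
#' @param config a [community_config()].
#' @param seed integer global seed (annotation uses its own derived stream).
#' @return list with `annotation` (data.frame `gene`, `phylum`, `genus`,
#'   `species`, `kos` — semicolon-separated KO ids, possibly empty) and
#'   `pathways` (data.frame `pathway`, `ko`).
#' @export
generate_annotation <- function(config = community_config(), seed = 1L) {
  if (!inherits(config, "community_config")) config <- do.call(community_config, config)
  with_seed(stream_seed(seed, 2L), {
    phyla <- sprintf("P%02d", seq_len(config$n_phyla))
    genera <- sprintf("G%03d", seq_len(config$n_genera))
    species <- sprintf("SP%04d", seq_len(config$n_species))
    kos <- sprintf("K%05d", seq_len(config$n_kos))
    paths <- sprintf("map%05d", seq_len(config$n_pathways))

    # surjective nesting: the first block pins one child per parent
    genus_phylum <- stats::setNames(
      c(phyla, sample(phyla, config$n_genera - config$n_phyla, replace = TRUE)), genera)
    species_genus <- stats::setNames(
      c(genera, sample(genera, config$n_species - config$n_genera, replace = TRUE)), species)
    gene_species <- c(species,
                      sample(species, config$n_genes - config$n_species, replace = TRUE))
    gene_species <- sample(gene_species)  # decouple gene index from species index

    gene <- sprintf("gene%05d", seq_len(config$n_genes))
    sp <- gene_species
    gn <- unname(species_genus[sp])
    ph <- unname(genus_phylum[gn])

    n_uncl <- round(config$unclassified_fraction * config$n_genes)
    if (n_uncl > 0) {
      uncl <- sample.int(config$n_genes, n_uncl)
      sp[uncl] <- "unclassified"
      gn[uncl] <- "unclassified"
      ph[uncl] <- "unclassified"
    }

    n_ko_per_gene <- sample(0:2, config$n_genes, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    total_slots <- sum(n_ko_per_gene)
    pool <- if (total_slots >= config$n_kos) {
      sample(c(kos, sample(kos, total_slots - config$n_kos, replace = TRUE)))
    } else {
      sample(kos, total_slots, replace = FALSE)
    }
    ko_str <- character(config$n_genes)
    idx <- cumsum(n_ko_per_gene)
    start <- c(1L, head(idx, -1L) + 1L)
    for (i in which(n_ko_per_gene > 0L)) {
      ko_str[i] <- paste(unique(pool[start[i]:idx[i]]), collapse = ";")
    }

    ko_pathway <- stats::setNames(
      c(paths, sample(paths, config$n_kos - config$n_pathways, replace = TRUE)), kos)
    pathway_df <- data.frame(pathway = unname(ko_pathway), ko = kos, stringsAsFactors = FALSE)
    if (config$n_pathways >= 2L) {
      second <- sample(c(TRUE, FALSE), config$n_kos, replace = TRUE, prob = c(0.2, 0.8))
      if (any(second)) {
        extra <- vapply(which(second), function(i) {
          sample(setdiff(paths, ko_pathway[i]), 1L)
        }, character(1))
        pathway_df <- rbind(pathway_df,
                            data.frame(pathway = extra, ko = kos[second],
                                       stringsAsFactors = FALSE))
      }
    }
    pathway_df <- pathway_df[order(pathway_df$pathway, pathway_df$ko), ]
    rownames(pathway_df) <- NULL

    list(annotation = data.frame(gene = gene, phylum = ph, genus = gn, species = sp,
                                 kos = ko_str, stringsAsFactors = FALSE),
         pathways = pathway_df)
  })
}

# Genes annotated to a feature id at a given level.
resolve_feature_genes <- function(feature, level, annotation) {
  if (level == "gene") {
    if (!feature %in% annotation$gene) {
      stop_validation("planted effect refers to unknown gene '%s'", feature)
    }
    return(feature)
  }
  if (level == "KO") {
    hits <- vapply(strsplit(annotation$kos, ";", fixed = TRUE),
                   function(k) feature %in% k, logical(1))
  } else {
    hits <- annotation[[level]] == feature
  }
  if (!any(hits)) {
    stop_validation("planted effect refers to %s '%s' with no annotated genes", level, feature)
  }
  annotation$gene[hits]
}

#' Generate paired mucosa/feces gene abundances with known ground truth
#'
#' Implements the generative model described in [community_config()]:
#' per-subject log-normal gene baselines shared across the subject's two
#' samples, multiplicative planted effects, site-specific Bernoulli presence
#' masks (zeroed in the opposite site for exclusive genera) and per-sample
#' renormalization to relative abundances.
#'
#' @param metadata fully paired sample metadata, e.g. from [generate_cohort()].
#' @param config a [community_config()].
#' @param annotation optional annotation list from [generate_annotation()];
#'   generated from `config` and `seed` when omitted.
#' @param seed integer global seed.
#' @return list with `table` (gene-level normalized [abundance_table()]),
#'   `ground_truth` (planted differential features, exclusive genera and the
#'   null feature set) and `annotation`/`pathways` as used.
#' @export
generate_paired_abundances <- function(metadata, config = community_config(),
                                       annotation = NULL, seed = 1L) {
  if (!inherits(config, "community_config")) config <- do.call(community_config, config)
  validate_metadata(metadata, require_paired = TRUE)
  if (is.null(annotation)) annotation <- generate_annotation(config, seed)
  ann <- annotation$annotation
  if (nrow(ann) != config$n_genes) {
    stop_validation("annotation covers %d genes but config declares %d", nrow(ann), config$n_genes)
  }
  genes <- ann$gene
  subjects <- unique(metadata$subject_id)
  n_genes <- length(genes)
  n_samples <- nrow(metadata)

  effect_features <- character(0)
  if (!is.null(config$site_effects)) {
    effect_features <- c(effect_features,
                         config$site_effects$feature[config$site_effects$level == "genus"])
  }
  if (!is.null(config$phenotype_effects)) {
    effect_features <- c(effect_features,
                         config$phenotype_effects$feature[config$phenotype_effects$level == "genus"])
  }

  classified_genera <- setdiff(unique(ann$genus), "unclassified")
  candidates <- setdiff(classified_genera, effect_features)
  n_excl <- config$mucosa_exclusive_genera + config$feces_exclusive_genera
  if (length(candidates) < n_excl) {
    stop_config("mucosa_exclusive_genera",
                "not enough effect-free classified genera to plant exclusives")
  }
  excl <- with_seed(stream_seed(seed, 3L), sample(candidates, n_excl))
  mucosa_exclusive <- sort(head(excl, config$mucosa_exclusive_genera))
  feces_exclusive <- sort(tail(excl, config$feces_exclusive_genera))

  # occupancy per gene x site; exclusive genera are zeroed in the other site
  occ_mucosa <- rep(config$mucosa_occupancy, n_genes)
  occ_feces <- rep(config$feces_occupancy, n_genes)
  occ_mucosa[ann$genus %in% feces_exclusive] <- 0
  occ_feces[ann$genus %in% mucosa_exclusive] <- 0

  subj_idx <- match(metadata$subject_id, subjects)
  baseline <- with_seed(stream_seed(seed, 4L), {
    matrix(stats::rnorm(n_genes * length(subjects), config$base_log_mean, config$base_log_sd),
           nrow = n_genes)
  })
  values <- exp(baseline)[, subj_idx, drop = FALSE]
  if (config$sample_log_sd > 0) {
    noise <- with_seed(stream_seed(seed, 6L), {
      matrix(stats::rnorm(n_genes * n_samples, 0, config$sample_log_sd), nrow = n_genes)
    })
    values <- values * exp(noise)
  }

  gt_rows <- list()
  if (!is.null(config$site_effects)) {
    for (i in seq_len(nrow(config$site_effects))) {
      e <- config$site_effects[i, ]
      gset <- resolve_feature_genes(e$feature, e$level, ann)
      cols <- which(metadata$site == e$site)
      values[match(gset, genes), cols] <- values[match(gset, genes), cols] * 2^e$log2fc
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        feature = e$feature, level = e$level, log2fc = e$log2fc, type = "site",
        enriched = e$site, variable = NA_character_, n_genes = length(gset),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$phenotype_effects)) {
    for (i in seq_len(nrow(config$phenotype_effects))) {
      e <- config$phenotype_effects[i, ]
      gset <- resolve_feature_genes(e$feature, e$level, ann)
      grp <- suppressWarnings(assign_groups(metadata, grouping_scheme(e$variable)))
      cols <- which(!is.na(grp$group) & grp$group == e$group)
      if (!length(cols)) {
        stop_config("phenotype_effects",
                    sprintf("group '%s' of variable '%s' matches no samples", e$group, e$variable))
      }
      values[match(gset, genes), cols] <- values[match(gset, genes), cols] * 2^e$log2fc
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        feature = e$feature, level = e$level, log2fc = e$log2fc, type = "phenotype",
        enriched = e$group, variable = e$variable, n_genes = length(gset),
        stringsAsFactors = FALSE)
    }
  }
  differential <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(feature = character(0), level = character(0), log2fc = numeric(0),
               type = character(0), enriched = character(0), variable = character(0),
               n_genes = integer(0), stringsAsFactors = FALSE)

  occ <- ifelse(rep(metadata$site, each = n_genes) == "mucosa", occ_mucosa, occ_feces)
  mask <- with_seed(stream_seed(seed, 5L), {
    matrix(stats::rbinom(n_genes * n_samples, 1L, occ), nrow = n_genes)
  })
  values <- values * mask

  cs <- colSums(values)
  nz <- cs > 0
  values[, nz] <- sweep(values[, nz, drop = FALSE], 2, cs[nz], "/")
  dimnames(values) <- list(genes, metadata$sample_id)
  table <- abundance_table(values, level = "gene", normalized = TRUE)

  affected_genes <- unique(c(
    unlist(lapply(seq_len(nrow(differential)), function(i) {
      resolve_feature_genes(differential$feature[i], differential$level[i], ann)
    })),
    ann$gene[ann$genus %in% c(mucosa_exclusive, feces_exclusive)]))
  ground_truth <- list(
    differential_features = differential,
    mucosa_exclusive_genera = mucosa_exclusive,
    feces_exclusive_genera = feces_exclusive,
    null_features = setdiff(genes, affected_genes))

  list(table = table, ground_truth = ground_truth,
       annotation = annotation$annotation, pathways = annotation$pathways)
}

#' Simulate a full paired cohort study
#'
#' Convenience wrapper chaining [generate_cohort()], [generate_annotation()]
#' and [generate_paired_abundances()] under a single global seed.
#'
#' @param cohort a [cohort_config()].
#' @param community a [community_config()].
#' @param seed integer global seed for all streams.
#' @return list with `metadata`, `table`, `ground_truth`, `annotation`,
#'   `pathways`.
#' @examples
#' sim <- simulate_cohort_study(seed = 7)
#' sim$table
#' @export
simulate_cohort_study <- function(cohort = cohort_config(),
                                  community = community_config(),
                                  seed = 1L) {
  metadata <- generate_cohort(cohort, seed)
  ann <- generate_annotation(community, seed)
  res <- generate_paired_abundances(metadata, community, annotation = ann, seed = seed)
  c(list(metadata = metadata), res)
}
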