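# Umbrella pipeline: profile -> diversity -> differential -> enrichment ->
# phenotype screens, from TSV inputs to a checksummed output manifest.

#' Pipeline configuration
#'
#' Collects input paths and analysis settings for [run_pipeline()]. All
#' referenced files must exist at construction time.
#'
#' @param abundance,metadata,annotation,pathways input TSV paths (gene-level
#'   abundance table, sample metadata, gene annotation, pathway map).
#' @param outdir output directory.
#' @param ranks feature levels to profile and screen.
#' @param method paired test for the site contrast (`"wilcoxon"` or
#'   `"paired_t"`).
#' @param alpha significance level in `(0, 1)`.
#' @param ordination_rank rank at which Bray-Curtis/PCoA are computed.
#' @param pcoa_axes number of ordination axes.
#' @param reporter_draws background draws for reporter enrichment.
#' @param phenotypes phenotype variables to screen within `phenotype_site`
#'   (any of `"age"`, `"gender"`, `"bmi"`, `"polyp_risk"`).
#' @param phenotype_site site for the phenotype screens.
#' @param seed integer global seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, metadata, annotation, pathways,
                            outdir = "metapair_out",
                            ranks = c("phylum", "genus", "species", "KO"),
                            method = c("wilcoxon", "paired_t"),
                            alpha = 0.05,
                            ordination_rank = "genus",
                            pcoa_axes = 2L,
                            reporter_draws = 1000L,
                            phenotypes = c("age", "gender", "bmi", "polyp_risk"),
                            phenotype_site = "mucosa",
                            seed = 1L) {
  method <- match.arg(method)
  for (f in c("abundance", "metadata", "annotation", "pathways")) {
    p <- get(f)
    if (!is.character(p) || length(p) != 1L) stop_config(f, "must be a single file path")
    if (!file.exists(p)) stop_config(f, sprintf("refers to a missing file: %s", p))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop_config("alpha", "must be in (0, 1)")
  if (!all(ranks %in% c("phylum", "genus", "species", "KO"))) {
    stop_config("ranks", "must be among phylum/genus/species/KO")
  }
  if (!ordination_rank %in% c(ranks, "gene")) {
    stop_config("ordination_rank", "must be 'gene' or one of the profiled ranks")
  }
  if (!all(phenotypes %in% c("age", "gender", "bmi", "polyp_risk"))) {
    stop_config("phenotypes", "must be among age/gender/bmi/polyp_risk")
  }
  if (!is_count(seed, 0L)) stop_config("seed", "must be a non-negative integer")
  structure(list(abundance = abundance, metadata = metadata,
                 annotation = annotation, pathways = pathways, outdir = outdir,
                 ranks = ranks, method = method, alpha = alpha,
                 ordination_rank = ordination_rank, pcoa_axes = as.integer(pcoa_axes),
                 reporter_draws = as.integer(reporter_draws),
                 phenotypes = phenotypes, phenotype_site = phenotype_site,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the fields of [pipeline_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("abundance", "metadata", "annotation", "pathways")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      cand <- file.path(base, cfg[[f]])
      if (file.exists(cand)) cfg[[f]] <- cand
    }
  }
  do.call(pipeline_config, cfg)
}

#' Run the full paired-comparison pipeline
#'
#' Executes, in order: relative-abundance profiling and rank aggregation;
#' Bray-Curtis + PCoA ordination; the paired site differential screen at
#' each rank; reporter-score pathway enrichment of the KO screen; and
#' phenotype-stratified screens (with their own pathway enrichment for
#' two-group schemes). Every output TSV is listed in a JSON manifest with
#' md5 checksums, written last — a failed stage aborts with the stage named
#' and leaves no manifest.
#'
#' @param config a [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stop_validation("'config' must be a pipeline_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  notes <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(writer, value, filename) {
    path <- file.path(config$outdir, filename)
    writer(value, path)
    outputs <<- c(outputs, path)
    path
  }

  inputs <- stage("read", {
    maps <- read_maps(config$annotation, config$pathways)
    list(table = read_abundance_tsv(config$abundance, level = "gene"),
         metadata = read_metadata_tsv(config$metadata, require_paired = TRUE),
         annotation = maps$annotation, pathways = maps$pathways)
  })

  tables <- stage("profile", {
    gene_rel <- if (inputs$table$normalized) inputs$table else
      normalize_relative(inputs$table)
    tabs <- list(gene = gene_rel)
    for (rk in config$ranks) {
      tabs[[rk]] <- aggregate_rank(gene_rel, inputs$annotation, rank = rk)
      emit(write_abundance_tsv, tabs[[rk]], sprintf("abundance_%s.tsv", rk))
    }
    richness <- data.frame(sample_id = sample_ids(gene_rel),
                           gene_richness = unname(gene_richness(gene_rel)))
    emit(write_differential_tsv, richness, "gene_richness.tsv")
    tabs
  })

  stage("diversity", {
    tab <- tables[[config$ordination_rank]]
    d <- bray_curtis(tab)
    dd <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    emit(write_differential_tsv, dd, sprintf("braycurtis_%s.tsv", config$ordination_rank))
    ord <- pcoa(d, n_axes = min(config$pcoa_axes, nrow(d) - 1L))
    coords <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                         check.names = FALSE)
    emit(write_differential_tsv, coords, "pcoa_coordinates.tsv")
    eig <- data.frame(axis = seq_along(ord$eigenvalues), eigenvalue = ord$eigenvalues)
    emit(write_differential_tsv, eig, "pcoa_eigenvalues.tsv")
  })

  diffs <- stage("diff", {
    res <- list()
    for (rk in config$ranks) {
      res[[rk]] <- suppressMessages(
        differential_screen(tables[[rk]], inputs$metadata,
                            method = config$method, alpha = config$alpha))
      emit(write_differential_tsv, res[[rk]], sprintf("differential_site_%s.tsv", rk))
    }
    res
  })

  if ("KO" %in% config$ranks) {
    stage("enrich", {
      enr <- suppressMessages(
        reporter_enrich(diffs$KO, inputs$pathways,
                        n_draws = config$reporter_draws, seed = config$seed))
      emit(write_differential_tsv, enr, "reporter_site.tsv")
    })
  }

  stage("pheno", {
    taxon_ranks <- setdiff(config$ranks, "KO")
    for (ph in config$phenotypes) {
      if (ph == "polyp_risk") {
        for (rk in taxon_ranks) {
          res <- withCallingHandlers(
            polyp_risk_contrast(tables[[rk]], inputs$metadata,
                                site = config$phenotype_site, alpha = config$alpha),
            warning = function(w) {
              notes <<- unique(c(notes, conditionMessage(w)))
              invokeRestart("muffleWarning")
            })
          emit(write_differential_tsv, res, sprintf("differential_polyp_risk_%s.tsv", rk))
        }
        next
      }
      scheme <- grouping_scheme(ph)
      for (rk in config$ranks) {
        res <- withCallingHandlers(
          suppressMessages(subgroup_screen(tables[[rk]], inputs$metadata, scheme,
                                           site = config$phenotype_site,
                                           alpha = config$alpha)),
          warning = function(w) {
            notes <<- unique(c(notes, conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        emit(write_differential_tsv, res, sprintf("differential_%s_%s.tsv", ph, rk))
        if (rk == "KO") {
          enr <- suppressMessages(
            reporter_enrich(res, inputs$pathways,
                            n_draws = config$reporter_draws, seed = config$seed))
          emit(write_differential_tsv, enr, sprintf("reporter_%s.tsv", ph))
        }
      }
    }
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    alpha = config$alpha,
    method = config$method,
    notes = notes,
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
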