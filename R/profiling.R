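#' Normalize an abundance table to per-sample relative abundances
#'
#' Each sample column is divided by its total, optionally after dividing
#' each feature by its length in bp (reads-per-base style length
#' correction). All-zero columns are left all-zero and reported with a
#' warning.
#'
#' @param x an [abundance_table()] (or bare matrix) of non-negative counts
#'   or abundances.
#' @param gene_lengths optional numeric vector of strictly positive feature
#'   lengths (bp), named by feature id or in table row order.
#' @return a normalized [abundance_table()] at the same level.
#' @examples
#' m <- matrix(c(2, 2, 4), ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
#' normalize_relative(abundance_table(m))$values
#' @export
normalize_relative <- function(x, gene_lengths = NULL) {
  x <- as_abundance_table(x)
  v <- x$values
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      if (!all(features(x) %in% names(gene_lengths))) {
        stop_validation("gene_lengths does not cover all features")
      }
      gene_lengths <- gene_lengths[features(x)]
    } else if (length(gene_lengths) != nrow(v)) {
      stop_validation("gene_lengths must match the number of features")
    }
    if (any(!is.finite(gene_lengths) | gene_lengths <= 0)) {
      stop_validation("gene_lengths must be strictly positive (zero-length feature(s): %s)",
                      paste(features(x)[gene_lengths <= 0], collapse = ", "))
    }
    v <- v / gene_lengths
  }
  cs <- colSums(v)
  if (any(cs == 0)) {
    warning(sprintf("all-zero sample column(s) left unnormalized: %s",
                    paste(colnames(v)[cs == 0], collapse = ", ")), call. = FALSE)
  }
  nz <- cs > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, cs[nz], "/")
  abundance_table(v, level = x$level, normalized = TRUE)
}

#' Aggregate a gene-level table to a taxonomic rank or to KOs
#'
#' Taxonomic aggregation sums gene abundances within each taxon and emits
#' `"unclassified"` as its own row, so per-sample totals are conserved
#' exactly. KO aggregation is many-to-many: a gene annotated with several
#' KOs contributes its full abundance to each of them, so KO columns need
#' not sum to 1 and the result is never flagged normalized.
#'
#' @param x a gene-level [abundance_table()].
#' @param annotation annotation data.frame as produced by
#'   [generate_annotation()] (`gene`, `phylum`, `genus`, `species`, `kos`).
#' @param rank one of `"phylum"`, `"genus"`, `"species"`, `"KO"`.
#' @return an [abundance_table()] at the requested level.
#' @export
aggregate_rank <- function(x, annotation, rank = c("phylum", "genus", "species", "KO")) {
  rank <- match.arg(rank)
  x <- as_abundance_table(x)
  if (x$level != "gene") stop_validation("aggregate_rank expects a gene-level table, got '%s'", x$level)
  unknown <- setdiff(features(x), annotation$gene)
  if (length(unknown)) {
    stop_validation("gene id(s) missing from annotation: %s",
                    paste(utils::head(unknown, 10L), collapse = ", "))
  }
  idx <- match(features(x), annotation$gene)
  if (rank == "KO") {
    ko_lists <- strsplit(annotation$kos[idx], ";", fixed = TRUE)
    n_per <- lengths(ko_lists)
    keep <- n_per > 0L & vapply(ko_lists, function(k) any(nzchar(k)), logical(1))
    gene_rows <- rep.int(which(keep), n_per[keep])
    ko_ids <- unlist(ko_lists[keep], use.names = FALSE)
    if (!length(ko_ids)) stop_validation("no gene in the table carries a KO annotation")
    out <- rowsum(x$values[gene_rows, , drop = FALSE], group = ko_ids)
    return(abundance_table(out, level = "KO", normalized = FALSE))
  }
  grp <- annotation[[rank]][idx]
  out <- rowsum(x$values, group = grp)
  abundance_table(out, level = rank, normalized = x$normalized)
}

#' Per-sample gene richness
#'
#' Number of features with abundance strictly above `min_abundance`
#' (default 0) in each requested sample — the study's alpha-diversity proxy.
#' Richness is invariant under per-sample rescaling, so it can be computed
#' on counts or relative abundances alike.
#'
#' @param x an [abundance_table()].
#' @param samples sample ids (default: all samples).
#' @param min_abundance presence floor; a feature counts as present when its
#'   value exceeds this threshold.
#' @return named integer vector of richness per sample.
#' @export
gene_richness <- function(x, samples = NULL, min_abundance = 0) {
  x <- as_abundance_table(x, level = "gene")
  samples <- samples %||% sample_ids(x)
  unknown <- setdiff(samples, sample_ids(x))
  if (length(unknown)) {
    stop_validation("unknown sample id(s): %s", paste(unknown, collapse = ", "))
  }
  colSums(x$values[, samples, drop = FALSE] > min_abundance)
}

#' Taxa shared between sites and exclusive to each site
#'
#' A taxon is present in a site when its abundance exceeds `min_abundance`
#' in at least one sample of that site. The returned shared / exclusive sets
#' partition all taxa present anywhere.
#'
#' @param x an [abundance_table()] at any level.
#' @param metadata sample metadata covering the table's samples.
#' @param min_abundance presence floor (default 0, i.e. strictly positive).
#' @return list with sorted character vectors `shared`, `exclusive_mucosa`,
#'   `exclusive_feces`.
#' @export
shared_exclusive_taxa <- function(x, metadata, min_abundance = 0) {
  x <- as_abundance_table(x)
  validate_metadata(metadata)
  idx <- match(sample_ids(x), metadata$sample_id)
  if (anyNA(idx)) {
    stop_validation("metadata does not cover sample(s): %s",
                    paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  }
  site <- metadata$site[idx]
  present_m <- rowSums(x$values[, site == "mucosa", drop = FALSE] > min_abundance) > 0
  present_f <- rowSums(x$values[, site == "feces", drop = FALSE] > min_abundance) > 0
  ids <- features(x)
  list(shared = sort(ids[present_m & present_f]),
       exclusive_mucosa = sort(ids[present_m & !present_f]),
       exclusive_feces = sort(ids[present_f & !present_m]))
}

#' Most abundant taxa in a site
#'
#' Taxa ranked by mean relative abundance over the site's samples,
#' descending; ties are broken lexicographically by feature id so the output
#' is deterministic.
#'
#' @param x an [abundance_table()].
#' @param metadata sample metadata covering the table's samples.
#' @param site `"mucosa"` or `"feces"`.
#' @param n number of taxa to return; when `n` exceeds the number of taxa
#'   all taxa are returned with a message.
#' @return character vector of taxon ids, most abundant first.
#' @export
top_n_taxa <- function(x, metadata, site = c("mucosa", "feces"), n = 10L) {
  site <- match.arg(site)
  if (!is_count(n)) stop_validation("'n' must be a positive integer")
  x <- as_abundance_table(x)
  validate_metadata(metadata)
  idx <- match(sample_ids(x), metadata$sample_id)
  if (anyNA(idx)) {
    stop_validation("metadata does not cover sample(s): %s",
                    paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  }
  cols <- which(metadata$site[idx] == site)
  if (!length(cols)) stop_validation("no %s samples in the table", site)
  means <- rowMeans(x$values[, cols, drop = FALSE])
  ord <- order(-means, features(x))
  if (n > length(means)) {
    message(sprintf("requested top %d taxa but only %d available; returning all", n, length(means)))
    n <- length(means)
  }
  features(x)[ord[seq_len(n)]]
}
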