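# TSV readers/writers. All tables are plain UTF-8 TSV: abundance matrices
# have a feature-id first column and one column per sample; annotation and
# pathway maps use the two KEGG-mapping-style layouts documented below.

#' Read an abundance table from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids and
#' numeric cells. Duplicate ids, non-numeric or negative cells and empty
#' files are rejected with the offending row/column named.
#'
#' @param path file path.
#' @param level feature level of the rows.
#' @param normalized logical or `NA` (default): when `NA` the flag is set
#'   automatically if every column sums to 1 within 1e-6 (columns are then
#'   renormalized exactly to absorb the limited precision of the text round
#'   trip).
#' @return an [abundance_table()].
#' @export
read_abundance_tsv <- function(path, level = "gene", normalized = NA) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", fill = FALSE)
  if (ncol(df) < 2L) stop_validation("%s: need a feature-id column plus at least one sample column", path)
  if (nrow(df) == 0L) stop_validation("%s: no features", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_validation("%s: duplicate feature id(s): %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_validation("%s: non-numeric value '%s' at data line %d, column '%s'",
                      path, df[[j]][bad], bad, names(df)[j])
    }
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      stop_validation("%s: negative value at data line %d (feature '%s'), column '%s'",
                      path, bad, ids[bad], names(df)[j])
    }
    m[, j - 1L] <- v
  }
  if (is.na(normalized)) {
    cs <- colSums(m)
    normalized <- all(abs(cs - 1) <= 1e-6 | cs == 0)
  }
  if (isTRUE(normalized)) {
    cs <- colSums(m)
    nz <- cs > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  abundance_table(m, level = level, normalized = isTRUE(normalized))
}

#' Write an abundance table to TSV
#'
#' Values are written with 10 significant digits so that write/read round
#' trips are reproducible to high precision.
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  x <- as_abundance_table(x)
  df <- data.frame(feature = features(x),
                   signif(x$values, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "feature_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path file path.
#' @param require_paired passed to [validate_metadata()].
#' @return validated metadata data.frame.
#' @export
read_metadata_tsv <- function(path, require_paired = FALSE) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  md <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_metadata(md, require_paired = require_paired)
  md
}

#' Write sample metadata to TSV
#' @param metadata metadata data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation and pathway maps
#'
#' The annotation TSV has columns `gene`, `phylum`, `genus`, `species`,
#' `kos` (semicolon-delimited KO ids; empty = no KO). The pathway TSV has
#' two columns `pathway`, `ko`. Duplicated pathway rows are deduplicated
#' with a message; pathway KOs absent from the annotation's KO universe are
#' retained with a warning (they may still match user-supplied KO tables).
#'
#' @param annotation_path path to the annotation TSV.
#' @param pathway_path path to the pathway-map TSV.
#' @return list with `annotation` and `pathways` data.frames.
#' @export
read_maps <- function(annotation_path, pathway_path) {
  for (p in c(annotation_path, pathway_path)) {
    if (!file.exists(p)) stop_validation("file not found: %s", p)
  }
  ann <- utils::read.delim(annotation_path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "", fill = FALSE)
  need <- c("gene", "phylum", "genus", "species", "kos")
  if (!all(need %in% names(ann))) {
    stop_validation("%s: annotation must have columns %s", annotation_path,
                    paste(need, collapse = ", "))
  }
  ann$kos[is.na(ann$kos)] <- ""
  if (anyDuplicated(ann$gene)) stop_validation("%s: duplicate gene id(s)", annotation_path)
  sp_gn <- unique(ann[ann$species != "unclassified", c("species", "genus")])
  if (anyDuplicated(sp_gn$species)) {
    stop_validation("%s: inconsistent taxonomy (a species maps to more than one genus)", annotation_path)
  }
  gn_ph <- unique(ann[ann$genus != "unclassified", c("genus", "phylum")])
  if (anyDuplicated(gn_ph$genus)) {
    stop_validation("%s: inconsistent taxonomy (a genus maps to more than one phylum)", annotation_path)
  }
  pw <- utils::read.delim(pathway_path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "", fill = FALSE)
  if (!all(c("pathway", "ko") %in% names(pw))) {
    stop_validation("%s: pathway map must have columns 'pathway' and 'ko'", pathway_path)
  }
  dup <- duplicated(pw[, c("pathway", "ko")])
  if (any(dup)) {
    message(sprintf("%d duplicated pathway row(s) removed", sum(dup)))
    pw <- pw[!dup, , drop = FALSE]
    rownames(pw) <- NULL
  }
  ko_universe <- unique(unlist(strsplit(ann$kos, ";", fixed = TRUE)))
  dangling <- setdiff(pw$ko, ko_universe)
  if (length(dangling)) {
    warning(sprintf("%d pathway KO(s) not present in the annotation (retained): %s",
                    length(dangling), paste(utils::head(dangling, 5L), collapse = ", ")),
            call. = FALSE)
  }
  list(annotation = ann, pathways = pw)
}

#' Write a simulated study to a directory
#'
#' Writes the abundance TSV, metadata TSV, annotation TSV, pathway-map TSV
#' and a ground-truth JSON for a [simulate_cohort_study()] result.
#'
#' @param sim list from [simulate_cohort_study()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abundance = file.path(outdir, "abundance.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    pathways = file.path(outdir, "pathways.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"))
  write_abundance_tsv(sim$table, paths["abundance"])
  write_metadata_tsv(sim$metadata, paths["metadata"])
  utils::write.table(sim$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pathways, paths["pathways"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a differential-result table to TSV
#' @param result data.frame from [differential_screen()] or the phenotype
#'   screens.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_differential_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
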