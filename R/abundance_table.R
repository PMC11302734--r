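#' Feature-by-sample abundance table
#'
#' The central data container: a non-negative numeric matrix of features
#' (rows) by samples (columns) together with the feature level
#' (`"gene"`, `"phylum"`, `"genus"`, `"species"` or `"KO"`) and a flag
#' recording whether columns have been normalized to relative abundances.
#'
#' When `normalized` is `TRUE` every sample column must sum to 1 (within
#' 1e-9) or to 0 for an all-absent sample. KO-level tables are never marked
#' normalized because a gene carrying several KO annotations contributes its
#' full abundance to each of them (columns need not sum to 1).
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all entries must be finite and >= 0.
#' @param level feature level of the rows.
#' @param normalized logical; are columns relative abundances summing to 1?
#' @return an object of class `abundance_table` with elements `values`,
#'   `level`, `normalized`.
#' @examples
#' m <- matrix(c(2, 2, 4, 1, 3, 4), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' abundance_table(m, level = "gene")
#' @export
abundance_table <- function(values,
                            level = c("gene", "phylum", "genus", "species", "KO"),
                            normalized = FALSE) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("'values' must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_validation("duplicate feature ids: %s",
                    paste(unique(rownames(values)[duplicated(rownames(values))]),
                          collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_validation("duplicate sample ids: %s",
                    paste(unique(colnames(values)[duplicated(colnames(values))]),
                          collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)[1, ]
    stop_validation("abundance values must be finite and non-negative (first offender: feature '%s', sample '%s')",
                    rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  if (isTRUE(normalized)) {
    cs <- colSums(values)
    ok <- abs(cs - 1) <= 1e-9 | cs == 0
    if (!all(ok)) {
      stop_validation("table marked normalized but sample(s) %s do not sum to 1",
                      paste(colnames(values)[!ok], collapse = ", "))
    }
  }
  structure(list(values = values, level = level, normalized = isTRUE(normalized)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d %s feature(s) x %d sample(s)%s\n",
              nrow(x$values), x$level, ncol(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Feature identifiers of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of feature ids.
#' @export
features <- function(x) rownames(x$values)

#' Sample identifiers of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

as_abundance_table <- function(x, level = "gene", normalized = FALSE) {
  if (inherits(x, "abundance_table")) return(x)
  abundance_table(as.matrix(x), level = level, normalized = normalized)
}

#' Validate a sample metadata table
#'
#' Metadata describe one sample per row: `sample_id`, `subject_id`,
#' `site` (`"mucosa"` or `"feces"`), `age` (years), `gender`
#' (`"male"`/`"female"`), `bmi` (kg/m2) and `polyp_group` (1 = hyperplastic
#' polyps / low risk, 2 = tubular adenomas / moderate risk,
#' 3 = tubulovillous adenomas / high risk).
#'
#' @param metadata data.frame of per-sample phenotypes.
#' @param require_paired if `TRUE`, every subject must contribute exactly one
#'   mucosa and one feces sample.
#' @return the validated data.frame, invisibly.
#' @export
validate_metadata <- function(metadata, require_paired = FALSE) {
  required <- c("sample_id", "subject_id", "site", "age", "gender", "bmi", "polyp_group")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop_validation("metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop_validation("duplicate sample ids in metadata")
  if (!all(metadata$site %in% c("mucosa", "feces"))) {
    stop_validation("metadata 'site' must be 'mucosa' or 'feces'")
  }
  if (anyDuplicated(metadata[, c("subject_id", "site")])) {
    stop_validation("each subject may contribute at most one sample per site")
  }
  if (any(!is.na(metadata$age) & metadata$age <= 0) ||
      any(!is.na(metadata$bmi) & metadata$bmi <= 0)) {
    stop_validation("age and bmi must be positive")
  }
  if (require_paired) {
    tab <- table(metadata$subject_id, metadata$site)
    if (!all(dim(tab) == c(length(unique(metadata$subject_id)), 2L)) || !all(tab == 1L)) {
      stop_validation("metadata is not fully paired: every subject needs exactly one mucosa and one feces sample")
    }
  }
  invisible(metadata)
}
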