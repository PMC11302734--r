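# Phenotype groupings (age / gender / BMI / polyp risk) and the
# between-subject rank-sum screens run within one site.

#' Phenotype grouping scheme
#'
#' Defines how samples are split into contrast groups. The built-in default
#' rules follow the motivating study's printed intervals:
#'
#' * `age`: `LOW` for 44-53 years, `HIGH` for 54-68 years;
#' * `bmi`: `DOWN` for 19.7-23 kg/m2, `UP` for 23.5-27 kg/m2 (values in the
#'   printed gap 23-23.5 are excluded with a warning rather than snapped);
#' * `gender`: `female` versus `male` (categories pass through);
#' * `polyp_risk`: `Group 1` / `Group 2` / `Group 3` from the `polyp_group`
#'   code (1 = hyperplastic/low, 2 = tubular/moderate,
#'   3 = tubulovillous/high risk).
#'
#' The first label is group A of downstream contrasts (the group whose
#' enrichment is reported with a positive sign); defaults put `HIGH`, `female`
#' and `UP` first, matching the convention of the phenotype enrichment
#' figures the package mirrors.
#'
#' Values outside every interval are excluded (label `NA`) with a warning.
#'
#' @param variable `"age"`, `"gender"`, `"bmi"` or `"polyp_risk"`.
#' @param intervals for numeric variables, a named list of `[min, max]`
#'   intervals (inclusive); names are the group labels, in group-A-first
#'   order. Ignored for categorical variables.
#' @param labels for categorical variables, the labels in group-A-first
#'   order (named by category value where renaming is wanted).
#' @return object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(variable = c("age", "gender", "bmi", "polyp_risk"),
                            intervals = NULL, labels = NULL) {
  variable <- match.arg(variable)
  if (variable %in% c("age", "bmi")) {
    intervals <- intervals %||% switch(variable,
      age = list(HIGH = c(54, 68), LOW = c(44, 53)),
      bmi = list(UP = c(23.5, 27), DOWN = c(19.7, 23)))
    if (is.null(names(intervals)) || length(intervals) < 2L) {
      stop_config("intervals", "must be a named list of at least two [min, max] intervals")
    }
    for (nm in names(intervals)) check_range(intervals[[nm]], sprintf("intervals$%s", nm))
    labels <- names(intervals)
  } else {
    labels <- labels %||% switch(variable,
      gender = c(female = "female", male = "male"),
      polyp_risk = c(`1` = "Group 1", `2` = "Group 2", `3` = "Group 3"))
    if (is.null(names(labels))) names(labels) <- labels
  }
  structure(list(variable = variable, intervals = intervals,
                 labels = labels, group_labels = unname(labels)),
            class = "grouping_scheme")
}

#' Assign samples to phenotype groups
#'
#' Applies a [grouping_scheme()] to sample metadata. Every sample receives
#' exactly one group label or an explicit `NA` exclusion (with a warning
#' naming the excluded samples, e.g. BMI values in the printed 23-23.5 gap).
#'
#' @param metadata sample metadata.
#' @param scheme a [grouping_scheme()].
#' @return data.frame with columns `sample_id`, `subject_id`, `value`,
#'   `group` (`NA` = excluded).
#' @examples
#' md <- generate_cohort(cohort_config(), seed = 1)
#' table(assign_groups(md, grouping_scheme("age"))$group)
#' @export
assign_groups <- function(metadata, scheme) {
  if (!inherits(scheme, "grouping_scheme")) stop_validation("'scheme' must be a grouping_scheme")
  validate_metadata(metadata)
  col <- switch(scheme$variable, age = "age", bmi = "bmi",
                gender = "gender", polyp_risk = "polyp_group")
  value <- metadata[[col]]
  if (anyNA(value)) {
    stop_validation("missing %s value(s) for sample(s): %s", scheme$variable,
                    paste(metadata$sample_id[is.na(value)], collapse = ", "))
  }
  if (scheme$variable %in% c("age", "bmi")) {
    group <- rep(NA_character_, length(value))
    for (nm in names(scheme$intervals)) {
      iv <- scheme$intervals[[nm]]
      hit <- value >= iv[1] & value <= iv[2]
      overlap <- hit & !is.na(group)
      if (any(overlap)) stop_config("intervals", "must not overlap")
      group[hit] <- nm
    }
  } else {
    group <- unname(scheme$labels[as.character(value)])
  }
  if (anyNA(group)) {
    warning(sprintf("sample(s) excluded from the %s grouping (value outside all intervals): %s",
                    scheme$variable,
                    paste(metadata$sample_id[is.na(group)], collapse = ", ")), call. = FALSE)
  }
  data.frame(sample_id = metadata$sample_id, subject_id = metadata$subject_id,
             value = value, group = group, stringsAsFactors = FALSE)
}

#' Unpaired two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided Wilcoxon rank-sum comparison of two independent groups (via
#' [stats::wilcox.test()]; exact null when feasible, normal approximation
#' with tie correction otherwise). Used for phenotype contrasts, where the
#' compared groups contain different subjects and a paired test does not
#' apply.
#'
#' @param values_a,values_b numeric vectors for groups A and B (length >= 2
#'   each).
#' @return list of class `paired_test_result` (same shape as
#'   [paired_test()], `method = "rank_sum"`).
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_validation("each group needs at least 2 samples")
  }
  mean_a <- mean(values_a)
  mean_b <- mean(values_b)
  direction <- if (mean_a > mean_b) "higher_in_a" else if (mean_a < mean_b) "higher_in_b" else "none"
  if (all(values_a == values_a[1]) && all(values_b == values_b[1]) &&
      values_a[1] == values_b[1]) {
    warning("all values identical across groups; returning p = 1", call. = FALSE)
    res <- list(statistic = NA_real_, p_value = 1, direction = "none",
                method = "rank_sum", mean_a = mean_a, mean_b = mean_b,
                n_pairs = NA_integer_, n_used = length(values_a) + length(values_b),
                n_zero_dropped = 0L, untestable = FALSE)
    class(res) <- "paired_test_result"
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = NULL,
                                            correct = FALSE))
  res <- list(statistic = unname(wt$statistic),
              p_value = max(min(wt$p.value, 1), .Machine$double.xmin),
              direction = direction, method = "rank_sum",
              mean_a = mean_a, mean_b = mean_b, n_pairs = NA_integer_,
              n_used = length(values_a) + length(values_b),
              n_zero_dropped = 0L, untestable = FALSE)
  class(res) <- "paired_test_result"
  res
}

# Shared driver for phenotype screens on a site-filtered table.
two_group_screen <- function(x, metadata, sample_groups, group_a, group_b,
                             alpha = 0.05, min_per_group = 2L) {
  a_ids <- sample_groups$sample_id[!is.na(sample_groups$group) & sample_groups$group == group_a]
  b_ids <- sample_groups$sample_id[!is.na(sample_groups$group) & sample_groups$group == group_b]
  a_ids <- intersect(a_ids, sample_ids(x))
  b_ids <- intersect(b_ids, sample_ids(x))
  if (length(a_ids) < min_per_group || length(b_ids) < min_per_group) {
    stop_validation("group '%s' (%d sample(s)) or '%s' (%d sample(s)) has fewer than %d samples",
                    group_a, length(a_ids), group_b, length(b_ids), min_per_group)
  }
  A <- x$values[, a_ids, drop = FALSE]
  B <- x$values[, b_ids, drop = FALSE]
  nonzero <- rowSums(A) > 0 | rowSums(B) > 0
  skipped <- features(x)[!nonzero]
  rows <- lapply(which(nonzero), function(f) {
    res <- suppressWarnings(rank_sum_test(A[f, ], B[f, ]))
    data.frame(feature = features(x)[f], level = x$level,
               mean_a = res$mean_a, mean_b = res$mean_b,
               statistic = res$statistic, p_value = res$p_value,
               direction = res$direction, n_used = res$n_used,
               n_zero_dropped = 0L, untestable = res$untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !out$untestable & !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- c(a = length(a_ids), b = length(b_ids))
  out
}

#' Phenotype-stratified differential screen within one site
#'
#' Splits the samples of one site into the two groups of a
#' [grouping_scheme()] and runs a per-feature rank-sum test. Group A is the
#' scheme's first label, so `direction = "higher_in_a"` means enriched in
#' that group; the result feeds [reporter_enrich()] unchanged.
#'
#' @param x an [abundance_table()] at any level.
#' @param metadata sample metadata.
#' @param scheme a two-group [grouping_scheme()] (`age`, `gender` or `bmi`;
#'   use [polyp_risk_contrast()] for the three-level polyp variable).
#' @param site site to analyze (default `"mucosa"`, the study's focus).
#' @param alpha significance level.
#' @return data.frame in the [differential_screen()] schema with a `groups`
#'   attribute naming the contrast.
#' @export
subgroup_screen <- function(x, metadata, scheme, site = c("mucosa", "feces"),
                            alpha = 0.05) {
  site <- match.arg(site)
  x <- as_abundance_table(x)
  validate_metadata(metadata)
  if (length(scheme$group_labels) != 2L) {
    stop_validation("subgroup_screen needs a two-group scheme; use polyp_risk_contrast() for polyp risk")
  }
  md <- metadata[metadata$site == site & metadata$sample_id %in% sample_ids(x), , drop = FALSE]
  if (!nrow(md)) stop_validation("no %s samples in the table", site)
  groups <- assign_groups(md, scheme)
  two_group_screen(x, md, groups, scheme$group_labels[1], scheme$group_labels[2],
                   alpha = alpha)
}

#' Low-risk versus high-risk polyp-group contrast
#'
#' Rank-sum screen of polyp risk Group 1 (hyperplastic, low risk) against
#' Group 3 (tubulovillous adenomas, high risk), excluding the moderate-risk
#' Group 2 — the comparison the motivating study restricted itself to in
#' order to avoid sample-number bias. Group A is Group 3, so a positive
#' direction means enrichment with risk. A warning is emitted when either
#' group has five or fewer samples (the study's own 3-versus-5 caveat).
#'
#' @inheritParams subgroup_screen
#' @return data.frame in the [differential_screen()] schema.
#' @export
polyp_risk_contrast <- function(x, metadata, site = c("mucosa", "feces"), alpha = 0.05) {
  site <- match.arg(site)
  x <- as_abundance_table(x)
  validate_metadata(metadata)
  md <- metadata[metadata$site == site & metadata$sample_id %in% sample_ids(x), , drop = FALSE]
  if (!nrow(md)) stop_validation("no %s samples in the table", site)
  groups <- assign_groups(md, grouping_scheme("polyp_risk"))
  n1 <- sum(groups$group == "Group 1", na.rm = TRUE)
  n3 <- sum(groups$group == "Group 3", na.rm = TRUE)
  if (n1 == 0L || n3 == 0L) stop_validation("polyp risk Group 1 or Group 3 is empty")
  if (min(n1, n3) <= 5L) {
    warning(sprintf("small polyp-risk contrast: Group 1 has %d and Group 3 has %d sample(s); interpret with caution",
                    n1, n3), call. = FALSE)
  }
  two_group_screen(x, md, groups, "Group 3", "Group 1", alpha = alpha)
}
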