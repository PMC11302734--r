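# Paired per-feature location tests and cross-site correlation diagnostics.

# Exact two-sided p for the signed-rank statistic via a generating-function
# convolution over doubled midranks (handles ties exactly; equivalent to
# enumerating all 2^n sign assignments).
signed_rank_exact_p <- function(r, w_obs) {
  R <- as.integer(round(2 * r))
  total <- sum(R)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in R) {
    g <- f
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] + f[seq_len(total + 1L - ri)]
    f <- g / 2
  }
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# Core Wilcoxon signed-rank machinery on a difference vector (zeros already
# dropped). Exact null for n <= exact_max (psignrank when ranks are untied,
# the DP above otherwise), tie-corrected normal approximation beyond.
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= exact_max) {
    if (!ties) {
      p <- min(1, 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n)))
    } else {
      p <- signed_rank_exact_p(r, W)
    }
    exact <- TRUE
  } else {
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_counts^3 - tie_counts) / 48
    z <- (W - n * (n + 1) / 4) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = W, p_value = max(p, .Machine$double.xmin), exact = exact)
}

#' Paired two-sample location test
#'
#' Two-sided paired comparison of site A versus site B values aligned by
#' subject. The default Wilcoxon signed-rank test drops zero differences
#' (their count is reported), uses the exact sign-permutation null for
#' `n <= exact_max` pairs (ties handled exactly) and a tie-corrected normal
#' approximation above; the paired t-test uses the usual t statistic on
#' differences. The reported direction follows the sign of
#' `mean(values_a) - mean(values_b)`.
#'
#' Degenerate inputs are flagged rather than raised: all-zero differences
#' give `p = 1` with direction `"none"` and a warning; fewer than 2 usable
#' pairs marks the result untestable (`p = NA`).
#'
#' @param values_a,values_b numeric vectors of equal length >= 2, one entry
#'   per subject.
#' @param method `"wilcoxon"` (signed-rank, default) or `"paired_t"`.
#' @param exact_max largest n for which the exact signed-rank null is used.
#' @return list of class `paired_test_result`: `statistic`, `p_value`,
#'   `direction` (`"higher_in_a"`, `"higher_in_b"`, `"none"`), `method`,
#'   `mean_a`, `mean_b`, `n_pairs`, `n_used`, `n_zero_dropped`, `untestable`.
#' @examples
#' paired_test(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value  # 0.0625
#' @export
paired_test <- function(values_a, values_b, method = c("wilcoxon", "paired_t"),
                        exact_max = 25L) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b)) {
    stop_validation("paired vectors must have equal length (aligned by subject)")
  }
  if (length(values_a) < 2L) stop_validation("need at least 2 pairs")
  if (anyNA(values_a) || anyNA(values_b)) stop_validation("paired values must not contain NA")
  mean_a <- mean(values_a)
  mean_b <- mean(values_b)
  direction <- if (mean_a > mean_b) "higher_in_a" else if (mean_a < mean_b) "higher_in_b" else "none"
  d <- values_a - values_b
  out <- list(method = method, mean_a = mean_a, mean_b = mean_b,
              n_pairs = length(d), n_used = length(d), n_zero_dropped = 0L,
              untestable = FALSE)
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1", call. = FALSE)
    out <- c(out, list(statistic = NA_real_, p_value = 1, direction = "none"))
    out$n_used <- 0L
    out$n_zero_dropped <- length(d)
    class(out) <- "paired_test_result"
    return(out)
  }
  if (method == "wilcoxon") {
    nz <- d != 0
    out$n_zero_dropped <- sum(!nz)
    dd <- d[nz]
    out$n_used <- length(dd)
    if (length(dd) < 2L) {
      out <- c(out, list(statistic = NA_real_, p_value = NA_real_, direction = direction))
      out$untestable <- TRUE
      class(out) <- "paired_test_result"
      return(out)
    }
    w <- wilcoxon_signed_rank(dd, exact_max = exact_max)
    out$statistic <- w$statistic
    out$p_value <- w$p_value
  } else {
    if (stats::sd(d) == 0) {
      # nonzero constant differences: t statistic is unbounded
      out <- c(out, list(statistic = Inf * sign(mean(d)), p_value = NA_real_,
                         direction = direction))
      out$untestable <- TRUE
      class(out) <- "paired_test_result"
      return(out)
    }
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    out$statistic <- unname(tt$statistic)
    out$p_value <- max(tt$p.value, .Machine$double.xmin)
  }
  out$direction <- direction
  class(out) <- "paired_test_result"
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s, direction = %s (n used = %d, zeros dropped = %d)%s\n",
              x$method, format(x$statistic), format(x$p_value), x$direction,
              x$n_used, x$n_zero_dropped,
              if (x$untestable) " [untestable]" else ""))
  invisible(x)
}

# Split a paired table into aligned site A / site B column indices.
paired_site_columns <- function(x, metadata, site_a = "mucosa", site_b = "feces") {
  idx <- match(sample_ids(x), metadata$sample_id)
  if (anyNA(idx)) {
    stop_validation("metadata does not cover sample(s): %s",
                    paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  }
  md <- metadata[idx, ]
  subjects <- intersect(md$subject_id[md$site == site_a], md$subject_id[md$site == site_b])
  if (length(subjects) < 2L) stop_validation("fewer than 2 complete %s/%s pairs", site_a, site_b)
  a_cols <- match(paste(subjects, site_a), paste(md$subject_id, md$site))
  b_cols <- match(paste(subjects, site_b), paste(md$subject_id, md$site))
  list(subjects = subjects, a = a_cols, b = b_cols)
}

#' Per-feature paired differential-abundance screen between sites
#'
#' Runs [paired_test()] on every feature of a (typically rank-aggregated)
#' abundance table, pairing mucosa (site A) against feces (site B) samples
#' by subject. Features absent from both sites are skipped and reported in
#' the `skipped` attribute. Raw p-values are compared against `alpha`
#' without multiple-testing correction by default; Benjamini-Hochberg
#' adjusted p-values can be requested and are then used for the
#' significance flag.
#'
#' @param x an [abundance_table()].
#' @param metadata paired sample metadata.
#' @param method `"wilcoxon"` or `"paired_t"`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per tested feature: `feature`, `level`,
#'   `mean_a`, `mean_b`, `statistic`, `p_value`, `direction`, `n_used`,
#'   `n_zero_dropped`, `untestable`, `significant` (plus `p_adjusted` under
#'   BH). Attributes: `groups` (`c(a = "mucosa", b = "feces")`), `skipped`
#'   (features all-zero in both sites).
#' @export
differential_screen <- function(x, metadata, method = c("wilcoxon", "paired_t"),
                                alpha = 0.05, p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  x <- as_abundance_table(x)
  validate_metadata(metadata, require_paired = TRUE)
  cols <- paired_site_columns(x, metadata)
  A <- x$values[, cols$a, drop = FALSE]
  B <- x$values[, cols$b, drop = FALSE]
  nonzero <- rowSums(A) > 0 | rowSums(B) > 0
  skipped <- features(x)[!nonzero]
  keep <- which(nonzero)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    f <- keep[i]
    res <- suppressWarnings(paired_test(A[f, ], B[f, ], method = method))
    rows[[i]] <- data.frame(
      feature = features(x)[f], level = x$level,
      mean_a = res$mean_a, mean_b = res$mean_b,
      statistic = res$statistic, p_value = res$p_value,
      direction = res$direction, n_used = res$n_used,
      n_zero_dropped = res$n_zero_dropped, untestable = res$untestable,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !out$untestable & !is.na(out$p_adjusted) & out$p_adjusted < alpha
  } else {
    out$significant <- !out$untestable & !is.na(out$p_value) & out$p_value < alpha
  }
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = "mucosa", b = "feces")
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  if (length(skipped)) {
    message(sprintf("%d feature(s) absent from both sites were skipped", length(skipped)))
  }
  out
}

site_mean_vectors <- function(x, metadata, features_use) {
  idx <- match(sample_ids(x), metadata$sample_id)
  site <- metadata$site[idx]
  v <- x$values[features_use, , drop = FALSE]
  list(a = rowMeans(v[, site == "mucosa", drop = FALSE]),
       b = rowMeans(v[, site == "feces", drop = FALSE]))
}

#' Correlation of per-feature mean abundances between sites
#'
#' Squared Pearson correlation between the per-feature mean relative
#' abundance in mucosa and in feces, over a feature set (by default the
#' features present in both sites), optionally excluding one feature — the
#' diagnostic behind leave-one-out discriminator screening.
#'
#' @param x an [abundance_table()].
#' @param metadata sample metadata.
#' @param features feature ids to use; default: features with nonzero
#'   abundance in at least one sample of each site.
#' @param exclude optional single feature id to drop before correlating.
#' @return list of class `correlation_result`: `r`, `r_squared`,
#'   `n_features`, `excluded_feature`.
#' @export
group_mean_correlation <- function(x, metadata, features = NULL, exclude = NULL) {
  x <- as_abundance_table(x)
  validate_metadata(metadata)
  if (is.null(features)) {
    features <- shared_exclusive_taxa(x, metadata)$shared
  }
  unknown <- setdiff(features, features(x))
  if (length(unknown)) stop_validation("unknown feature id(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(exclude)) {
    if (length(exclude) != 1L || !exclude %in% features) {
      stop_validation("'exclude' must be a single feature id within 'features'")
    }
    features <- setdiff(features, exclude)
  }
  if (length(features) < 3L) stop_validation("need at least 3 features after exclusion")
  m <- site_mean_vectors(x, metadata, features)
  r <- stats::cor(m$a, m$b)
  structure(list(r = r, r_squared = r^2, n_features = length(features),
                 excluded_feature = if (is.null(exclude)) NA_character_ else exclude),
            class = "correlation_result")
}

#' Leave-one-feature-out correlation screen
#'
#' For each feature, the change in cross-site squared correlation when that
#' feature is excluded: `delta_r_squared = r2(without) - r2(all)`. The
#' top-ranked feature is the strongest single discriminator between the two
#' sites (the role the mucosa-enriched Burkholderia genus plays in the
#' motivating data).
#'
#' @inheritParams group_mean_correlation
#' @return data.frame sorted by decreasing `delta_r_squared` with columns
#'   `feature`, `r_squared_without`, `delta_r_squared`; attribute
#'   `r_squared_all`.
#' @export
leave_one_out_screen <- function(x, metadata, features = NULL) {
  x <- as_abundance_table(x)
  if (is.null(features)) features <- shared_exclusive_taxa(x, metadata)$shared
  if (length(features) < 4L) stop_validation("need at least 4 features for leave-one-out screening")
  base <- group_mean_correlation(x, metadata, features = features)
  r2_wo <- vapply(features, function(f) {
    group_mean_correlation(x, metadata, features = features, exclude = f)$r_squared
  }, numeric(1))
  out <- data.frame(feature = features, r_squared_without = unname(r2_wo),
                    delta_r_squared = unname(r2_wo) - base$r_squared,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta_r_squared, out$feature), ]
  rownames(out) <- NULL
  attr(out, "r_squared_all") <- base$r_squared
  out
}

#' Sensitivity of a paired test to the highest-leverage pair
#'
#' Recomputes the paired test after removing the subject with the largest
#' absolute paired difference, flagging whether significance at `alpha`
#' changes — the check under which the motivating study's Desulfovibrio
#' signal disappeared.
#'
#' @inheritParams paired_test
#' @param alpha significance level at which the change is judged.
#' @return list: `p_full`, `p_reduced`, `dropped_index`, `flag_changed`,
#'   plus the full and reduced `paired_test_result`s.
#' @export
outlier_sensitivity <- function(values_a, values_b, method = c("wilcoxon", "paired_t"),
                                alpha = 0.05) {
  method <- match.arg(method)
  if (length(values_a) < 3L) stop_validation("need at least 3 pairs for outlier sensitivity")
  full <- suppressWarnings(paired_test(values_a, values_b, method = method))
  drop_i <- which.max(abs(values_a - values_b))
  reduced <- suppressWarnings(paired_test(values_a[-drop_i], values_b[-drop_i], method = method))
  sig_full <- !is.na(full$p_value) && full$p_value < alpha
  sig_red <- !is.na(reduced$p_value) && reduced$p_value < alpha
  list(p_full = full$p_value, p_reduced = reduced$p_value,
       dropped_index = drop_i, flag_changed = sig_full != sig_red,
       full = full, reduced = reduced)
}
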