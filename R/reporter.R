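# Signed reporter-score pathway enrichment over KO-level differential results.

#' Signed z-score for a KO differential result
#'
#' Converts a two-sided p-value and a direction into a signed standard
#' normal score: `z = sign * qnorm(1 - p/2)`, positive when the KO is
#' higher in group A. p-values are clamped to `[1e-10, 1 - 1e-10]` before
#' inversion so the score stays finite. A direction of `"none"` with
#' `p < 1` yields the unsigned magnitude with a warning.
#'
#' @param p_value two-sided p-value(s) in `(0, 1]`.
#' @param direction `"higher_in_a"`, `"higher_in_b"` or `"none"` (recycled).
#' @return numeric vector of signed z-scores.
#' @examples
#' ko_zscore(0.05, "higher_in_a")  # ~ +1.96
#' @export
ko_zscore <- function(p_value, direction) {
  if (any(is.na(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  n <- max(length(p_value), length(direction))
  p_value <- rep_len(p_value, n)
  direction <- rep_len(direction, n)
  if (!all(direction %in% c("higher_in_a", "higher_in_b", "none"))) {
    stop_validation("direction must be 'higher_in_a', 'higher_in_b' or 'none'")
  }
  if (any(direction == "none" & p_value < 1)) {
    warning("direction 'none' with p < 1: returning unsigned z magnitude", call. = FALSE)
  }
  p <- pmin(pmax(p_value, 1e-10), 1 - 1e-10)
  z <- stats::qnorm(1 - p / 2)
  sgn <- ifelse(direction == "higher_in_b", -1, 1)
  sgn * z
}

#' Raw reporter score of a pathway
#'
#' Aggregates the signed z-scores of the pathway's `k` member KOs as
#' `sum(z) / sqrt(k)`.
#'
#' @param z_values numeric vector of member-KO z-scores (length >= 1).
#' @return the raw reporter score.
#' @examples
#' pathway_raw_score(c(1, 2, 3))  # 6 / sqrt(3)
#' @export
pathway_raw_score <- function(z_values) {
  if (!length(z_values)) stop_validation("a pathway needs at least one scored KO")
  if (any(!is.finite(z_values))) stop_validation("z-scores must be finite")
  sum(z_values) / sqrt(length(z_values))
}

# Background distribution of raw scores for random k-subsets of the scored
# KO population. Subsets are drawn by index so that negating the population
# exactly negates the background mean (sign antisymmetry of the corrected
# score). One seeded stream per k.
reporter_background <- function(all_z, k, n_draws = 1000L, seed = 1L) {
  if (!is_count(k) || k > length(all_z)) {
    stop_validation("subset size k must satisfy 1 <= k <= number of scored KOs")
  }
  if (!is_count(n_draws, min = 100L)) stop_validation("n_draws must be an integer >= 100")
  draws <- with_seed(stream_seed(seed, 100L + k), {
    vapply(seq_len(n_draws), function(i) {
      sum(all_z[sample.int(length(all_z), k)]) / sqrt(k)
    }, numeric(1))
  })
  mu <- mean(draws)
  sigma <- stats::sd(draws)
  if (!is.finite(sigma) || sigma < 1e-12) {
    stop_validation("degenerate KO z-score population: background SD for k = %d is zero (all subset scores equal %.4g)",
                    k, mu)
  }
  list(mu = mu, sigma = sigma)
}

#' Background-corrected reporter score
#'
#' Standardizes a raw pathway score against the null distribution of raw
#' scores of `n_draws` random size-`k` subsets of all scored KO z-values
#' (drawn without replacement within each draw, seeded):
#' `corrected = (raw - mu_k) / sigma_k`.
#'
#' @param raw raw reporter score from [pathway_raw_score()].
#' @param k number of scored member KOs of the pathway.
#' @param all_z z-scores of the full scored-KO population.
#' @param n_draws number of background subsets (>= 100, default 1000).
#' @param seed integer seed for the background draws.
#' @return the corrected score, in standard normal units.
#' @export
background_correct <- function(raw, k, all_z, n_draws = 1000L, seed = 1L) {
  bg <- reporter_background(all_z, k, n_draws = n_draws, seed = seed)
  (raw - bg$mu) / bg$sigma
}

#' Classify a corrected reporter score
#'
#' Five-way label with strict thresholds: `"++"` above 2.3, `"+"` above
#' 1.96, `"--"` below -2.3, `"-"` below -1.96, otherwise `"0"`. 1.96 is the
#' two-sided 5% standard normal quantile (97.5% confidence level); scores at
#' a boundary are not called.
#'
#' @param corrected numeric vector of corrected reporter scores.
#' @return character vector of labels among `"--"`, `"-"`, `"0"`, `"+"`,
#'   `"++"`.
#' @export
classify_score <- function(corrected) {
  if (any(!is.finite(corrected))) stop_validation("corrected scores must be finite")
  ifelse(corrected > 2.3, "++",
         ifelse(corrected > 1.96, "+",
                ifelse(corrected < -2.3, "--",
                       ifelse(corrected < -1.96, "-", "0"))))
}

#' Reporter-score pathway enrichment
#'
#' Full chain over KO-level differential results: signed z per KO
#' ([ko_zscore()]), raw pathway aggregation ([pathway_raw_score()]),
#' resampled background correction ([background_correct()], background
#' population = all scored KOs, one cached background per distinct pathway
#' size) and classification ([classify_score()]). Positive scores mean
#' enrichment in group A (mucosa, in the site contrast). KOs with an
#' untestable or missing p-value are dropped with a message; pathways left
#' without scored KOs are omitted with a message; single-KO pathways are
#' scored but flagged low-confidence.
#'
#' @param ko_results data.frame of KO-level differential results with
#'   columns `feature` (KO id), `p_value`, `direction` (e.g. from
#'   [differential_screen()] on a KO table).
#' @param pathway_map data.frame with columns `pathway`, `ko`.
#' @param n_draws background draws per distinct pathway size (default 1000).
#' @param seed integer seed for all background streams.
#' @return data.frame sorted by decreasing corrected score: `pathway`, `k`,
#'   `raw_score`, `corrected_score`, `label`, `low_confidence`.
#' @export
reporter_enrich <- function(ko_results, pathway_map, n_draws = 1000L, seed = 1L) {
  need <- c("feature", "p_value", "direction")
  if (!all(need %in% names(ko_results))) {
    stop_validation("ko_results must have columns: %s", paste(need, collapse = ", "))
  }
  if (!all(c("pathway", "ko") %in% names(pathway_map))) {
    stop_validation("pathway_map must have columns 'pathway' and 'ko'")
  }
  usable <- !is.na(ko_results$p_value)
  if ("untestable" %in% names(ko_results)) usable <- usable & !ko_results$untestable
  if (any(!usable)) {
    message(sprintf("%d KO result(s) without a usable p-value were dropped", sum(!usable)))
  }
  ko_results <- ko_results[usable, , drop = FALSE]
  if (!nrow(ko_results)) stop_validation("no scored KOs available")
  z <- suppressWarnings(ko_zscore(ko_results$p_value, ko_results$direction))
  names(z) <- ko_results$feature

  members <- pathway_map[pathway_map$ko %in% names(z), , drop = FALSE]
  if (!nrow(members)) {
    stop_validation("no overlap between the pathway map and the scored KOs")
  }
  all_paths <- unique(pathway_map$pathway)
  scored_paths <- unique(members$pathway)
  empty <- setdiff(all_paths, scored_paths)
  if (length(empty)) {
    message(sprintf("%d pathway(s) with no scored KOs were omitted", length(empty)))
  }

  member_z <- split(z[members$ko], members$pathway)
  ks <- lengths(member_z)
  bg_cache <- new.env(parent = emptyenv())
  get_bg <- function(k) {
    key <- as.character(k)
    if (is.null(bg_cache[[key]])) {
      bg_cache[[key]] <- reporter_background(z, k, n_draws = n_draws, seed = seed)
    }
    bg_cache[[key]]
  }
  raw <- vapply(member_z, pathway_raw_score, numeric(1))
  spans_all <- ks == length(z)
  if (any(spans_all)) {
    # a pathway covering the whole scored population cannot be enriched
    # relative to it: every background subset is the population itself
    message(sprintf("%d pathway(s) span the entire scored KO population; corrected score set to 0",
                    sum(spans_all)))
  }
  corrected <- vapply(seq_along(raw), function(i) {
    if (spans_all[i]) return(0)
    bg <- get_bg(ks[i])
    (raw[i] - bg$mu) / bg$sigma
  }, numeric(1))

  out <- data.frame(pathway = names(member_z), k = unname(ks),
                    raw_score = unname(raw), corrected_score = corrected,
                    label = classify_score(corrected),
                    low_confidence = unname(ks) == 1L,
                    stringsAsFactors = FALSE)
  if (any(out$low_confidence)) {
    message(sprintf("%d single-KO pathway(s) scored but flagged low-confidence",
                    sum(out$low_confidence)))
  }
  out <- out[order(-out$corrected_score, out$pathway), ]
  rownames(out) <- NULL
  out
}
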