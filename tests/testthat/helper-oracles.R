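# Independent oracles and small fixture builders used across the suite.

# Two-sided signed-rank p by exhaustive enumeration of all 2^n sign
# assignments on the (mid)ranks of |differences| (zeros dropped first).
enum_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided rank-sum p by exhaustive enumeration of all group-label
# assignments (Mann-Whitney U on pooled ranks).
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Squared Pearson correlation from the definition (no stats::cor).
hand_r_squared <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy)^2 / (sum(dx^2) * sum(dy^2))
}

# Minimal fully paired metadata for n subjects.
tiny_metadata <- function(n = 4L) {
  subj <- sprintf("S%02d", seq_len(n))
  data.frame(
    sample_id = paste(rep(subj, each = 2L), rep(c("mucosa", "feces"), n), sep = "_"),
    subject_id = rep(subj, each = 2L),
    site = rep(c("mucosa", "feces"), n),
    age = rep(seq(45, length.out = n), each = 2L),
    gender = rep(rep(c("male", "female"), length.out = n), each = 2L),
    bmi = rep(seq(20, 26, length.out = n), each = 2L),
    polyp_group = rep(rep(1:3, length.out = n), each = 2L),
    stringsAsFactors = FALSE)
}

# Random normalized gene-level table over the samples of a metadata frame.
random_gene_table <- function(metadata, n_genes = 30L, seed = 1L, sparsity = 0) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * nrow(metadata)), nrow = n_genes,
              dimnames = list(sprintf("gene%03d", seq_len(n_genes)), metadata$sample_id))
  if (sparsity > 0) m[runif(length(m)) < sparsity] <- 0
  m <- sweep(m, 2, colSums(m), "/")
  abundance_table(m, level = "gene", normalized = TRUE)
}

# Small community configuration for fast simulator-backed tests.
small_community <- function(...) {
  community_config(n_genes = 600L, n_phyla = 4L, n_genera = 20L, n_species = 40L,
                   n_kos = 60L, n_pathways = 8L,
                   mucosa_occupancy = 0.3, feces_occupancy = 0.9,
                   mucosa_exclusive_genera = 2L, feces_exclusive_genera = 5L, ...)
}

# Site-exchangeable null configuration (equal occupancies, nothing planted).
null_community <- function(n_genes = 1000L, ...) {
  community_config(n_genes = n_genes, n_phyla = 4L, n_genera = 40L, n_species = 80L,
                   n_kos = 100L, n_pathways = 10L,
                   mucosa_occupancy = 0.9, feces_occupancy = 0.9,
                   mucosa_exclusive_genera = 0L, feces_exclusive_genera = 0L, ...)
}
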