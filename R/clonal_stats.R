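# Clone-level cluster probability distributions and Jensen-Shannon-distance
# statistics: fate-homogeneity resampling tests within a differentiation and
# pairwise cross-split comparisons between parallel differentiations.

kl2 <- function(p, q) {
  # Kullback-Leibler divergence in log base 2, with 0 * log(0) := 0.
  nz <- p > 0
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

#' Jensen-Shannon distance between two probability distributions
#'
#' Computed with log-base-2 Kullback-Leibler terms so that the maximum —
#' reached by distributions with disjoint support — is exactly 1 and
#' identical distributions score exactly 0. The default `"distance"` form
#' is the square root of the Jensen-Shannon divergence and is a metric;
#' `"divergence"` returns the divergence itself (also bounded by 1 in log
#' base 2).
#'
#' @param p,q Probability vectors of equal length (nonnegative, summing
#'   to 1 within `tol`).
#' @param form `"distance"` (square root, the default) or `"divergence"`.
#' @param tol Tolerance on the sum-to-1 check.
#' @return A single number in `[0, 1]`.
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1))        # 1
#' jensen_shannon_distance(c(0.5, 0.5), c(0.5, 0.5)) # 0
#' @export
jensen_shannon_distance <- function(p, q, form = c("distance", "divergence"),
                                    tol = 1e-9) {
  form <- match.arg(form)
  if (length(p) != length(q)) stop("`p` and `q` must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol) {
    stop("`p` and `q` must each sum to 1")
  }
  m <- (p + q) / 2
  jsdiv <- 0.5 * kl2(p, m) + 0.5 * kl2(q, m)
  jsdiv <- min(max(jsdiv, 0), 1)  # clamp tiny negative round-off
  if (form == "distance") sqrt(jsdiv) else jsdiv
}

as_cluster_pool <- function(pool, exclude_clusters = NULL) {
  stopifnot(all(c("cell_id", "cluster") %in% names(pool)))
  if (anyDuplicated(pool$cell_id)) stop("duplicate cell_id in cluster table")
  pool <- pool[!(pool$cluster %in% exclude_clusters), , drop = FALSE]
  pool$cluster <- as.character(pool$cluster)
  pool
}

#' Derive a clone's cluster probability distribution
#'
#' For each retained cluster, the clone's raw cell count is divided by the
#' total number of pooled cells in that cluster (controlling for cluster
#' size), and the resulting proportions are renormalized to sum to 1:
#' `p_k = (c_k / N_k) / sum_j (c_j / N_j)`. Clusters with zero pooled cells
#' are dropped before normalization.
#'
#' @param clone_cells Character vector of cell ids belonging to the clone.
#' @param pool data.frame with columns `cell_id`, `cluster` covering every
#'   analyzed cell (the denominator population).
#' @param exclude_clusters Cluster labels to remove from the analysis
#'   entirely (e.g. a cluster with too few barcoded cells to interpret).
#' @return Named numeric vector of probabilities over retained clusters
#'   (sums to 1), with attribute `n_cells` (clone size).
#' @export
derive_cluster_probability <- function(clone_cells, pool,
                                       exclude_clusters = NULL) {
  pool <- as_cluster_pool(pool, exclude_clusters)
  if (length(clone_cells) == 0L) stop("clone has no cells")
  if (!all(clone_cells %in% pool$cell_id)) {
    stop("clone contains cells absent from the pool")
  }
  lev <- sort(unique(pool$cluster))
  nk <- table(factor(pool$cluster, levels = lev))
  ck <- table(factor(pool$cluster[match(clone_cells, pool$cell_id)],
                     levels = lev))
  ratio <- as.numeric(ck) / as.numeric(nk)
  p <- ratio / sum(ratio)
  names(p) <- lev
  attr(p, "n_cells") <- length(clone_cells)
  p
}

# Fast path used by the resampling machinery: pool encoded once as an
# integer cluster index vector plus per-cluster totals.
encode_pool <- function(pool) {
  lev <- sort(unique(pool$cluster))
  idx <- match(pool$cluster, lev)
  list(levels = lev, idx = idx, nk = tabulate(idx, nbins = length(lev)))
}

sample_probs <- function(enc, size, n_samples) {
  # matrix of n_samples normalized cluster probability distributions from
  # without-replacement samples of `size` cells
  K <- length(enc$levels)
  out <- matrix(0, nrow = K, ncol = n_samples)
  for (j in seq_len(n_samples)) {
    s <- enc$idx[sample.int(length(enc$idx), size)]
    ratio <- tabulate(s, nbins = K) / enc$nk
    out[, j] <- ratio / sum(ratio)
  }
  out
}

#' Expected cluster probability distribution of a random clone
#'
#' Averages the normalized cluster probability distributions of `n_samples`
#' uniform without-replacement samples of `clone_size` cells from the pool,
#' renormalized to sum to 1. Because the normalization already divides by
#' cluster size, this reference is close to uniform over retained clusters
#' regardless of how unbalanced the clusters are.
#'
#' @inheritParams derive_cluster_probability
#' @param clone_size Number of cells per random sample.
#' @param n_samples Number of resamples to average (default 1000).
#' @param seed Integer seed.
#' @return Named probability vector over retained clusters (sums to 1).
#' @export
reference_distribution <- function(pool, clone_size, n_samples = 1000L,
                                   seed = 1L, exclude_clusters = NULL) {
  pool <- as_cluster_pool(pool, exclude_clusters)
  clone_size <- check_count(clone_size, "clone_size")
  n_samples <- check_count(n_samples, "n_samples")
  if (clone_size > nrow(pool)) stop("`clone_size` exceeds pool size")
  enc <- encode_pool(pool)
  local_seed(seed, {
    m <- rowMeans(sample_probs(enc, clone_size, n_samples))
    p <- m / sum(m)
    names(p) <- enc$levels
    p
  })
}

#' Jensen-Shannon resampling test of clonal fate homogeneity
#'
#' Tests whether a clone's cluster probability distribution is further from
#' the random-clone reference than size-matched random samples are. The
#' reference is the average distribution of `n_samples` without-replacement
#' samples of the clone's size; the null is the JSD of `n_samples` fresh
#' matched-size samples against that same reference; the empirical p-value
#' is `(1 + #{null >= observed}) / (1 + n_samples)`.
#'
#' @inheritParams derive_cluster_probability
#' @param n_samples Resamples for both the reference and the null.
#' @param min_cells Minimum clone size; smaller clones are rejected with an
#'   error (screen clones upstream, e.g. with [clone_jsd_table()]).
#' @param seed Integer seed.
#' @param form JSD form, passed to [jensen_shannon_distance()].
#' @return An object of class `jsd_test`: list with `observed_jsd`,
#'   `p_value`, `n_cells`, `clone_distribution`, `reference`, `null_jsds`
#'   (length `n_samples`), `n_samples`, `seed`.
#' @export
jsd_homogeneity_test <- function(clone_cells, pool, n_samples = 1000L,
                                 min_cells = 20L, seed = 1L,
                                 exclude_clusters = NULL,
                                 form = c("distance", "divergence")) {
  form <- match.arg(form)
  pool <- as_cluster_pool(pool, exclude_clusters)
  n_samples <- check_count(n_samples, "n_samples")
  if (length(clone_cells) < min_cells) {
    stop("clone has fewer than `min_cells` cells")
  }
  p_clone <- derive_cluster_probability(clone_cells, pool)
  enc <- encode_pool(pool)
  size <- length(clone_cells)
  local_seed(seed, {
    ref <- rowMeans(sample_probs(enc, size, n_samples))
    ref <- ref / sum(ref)
    null_mat <- sample_probs(enc, size, n_samples)
    null_jsds <- apply(null_mat, 2, jensen_shannon_distance, q = ref,
                       form = form)
    observed <- jensen_shannon_distance(as.numeric(p_clone), ref, form = form)
    p_value <- (1 + sum(null_jsds >= observed)) / (1 + n_samples)
    structure(list(
      observed_jsd = observed,
      p_value = p_value,
      n_cells = size,
      clone_distribution = p_clone,
      reference = stats::setNames(ref, enc$levels),
      null_jsds = null_jsds,
      n_samples = n_samples,
      seed = as.integer(seed)
    ), class = "jsd_test")
  })
}

#' Per-clone fate-homogeneity results for a whole experiment
#'
#' Screens barcode clones by size and runs [jsd_homogeneity_test()] on each
#' qualifying clone against the pool of all analyzed cells.
#'
#' @param assignments data.frame with columns `cell_id`, `barcode` (one row
#'   per assigned cell, e.g. the `table` of [assign_cells()]).
#' @param clusters data.frame with columns `cell_id`, `cluster`.
#' @param min_cells Minimum clone size for inclusion (default 20).
#' @param n_samples Resamples per clone.
#' @param seed Integer seed (per-clone seeds are derived from it).
#' @param exclude_clusters Cluster labels dropped from the analysis.
#' @param pool Which cells form the normalization pool: `"assigned"`
#'   (default; all cells of qualifying clones) or `"all"` (every cell in
#'   `assignments` with a cluster label).
#' @return data.frame with one row per qualifying clone: `barcode`,
#'   `n_cells`, `observed_jsd`, `p_value`.
#' @export
clone_jsd_table <- function(assignments, clusters, min_cells = 20L,
                            n_samples = 1000L, seed = 1L,
                            exclude_clusters = NULL,
                            pool = c("assigned", "all")) {
  pool <- match.arg(pool)
  stopifnot(all(c("cell_id", "barcode") %in% names(assignments)))
  cl <- as_cluster_pool(clusters, exclude_clusters)
  df <- merge(assignments[, c("cell_id", "barcode")], cl, by = "cell_id")
  sizes <- table(df$barcode)
  keep_bc <- names(sizes)[sizes >= min_cells]
  if (length(keep_bc) == 0L) {
    return(data.frame(barcode = character(0), n_cells = integer(0),
                      observed_jsd = numeric(0), p_value = numeric(0)))
  }
  pool_df <- if (pool == "assigned") {
    df[df$barcode %in% keep_bc, c("cell_id", "cluster")]
  } else {
    df[, c("cell_id", "cluster")]
  }
  res <- lapply(seq_along(keep_bc), function(i) {
    b <- keep_bc[i]
    cells_b <- df$cell_id[df$barcode == b]
    t <- jsd_homogeneity_test(cells_b, pool_df, n_samples = n_samples,
                              min_cells = min_cells,
                              seed = stage_seed(seed, paste0("clone:", b)))
    data.frame(barcode = b, n_cells = t$n_cells,
               observed_jsd = t$observed_jsd, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$observed_jsd, decreasing = TRUE), , drop = FALSE]
}

#' Pairwise cross-split Jensen-Shannon distance matrix
#'
#' For barcode clones present with at least `min_cells_per_split` cells in
#' each of two parallel split differentiations, computes each clone's
#' cluster probability distribution separately per split (normalizing, by
#' default, against cluster totals pooled over both splits) and returns the
#' full matrix of Jensen-Shannon distances between split-A and split-B
#' distributions. Entry `(i, j)` compares A-clone `i` with B-clone `j`;
#' the diagonal compares each clone with itself across splits.
#'
#' @param cells_A,cells_B data.frames with columns `cell_id`, `barcode`,
#'   `cluster` for the analyzed cells of each split.
#' @param min_cells_per_split Minimum clone size within each split.
#' @param normalization `"pooled"` (cluster totals over both splits,
#'   default) or `"per_split"`.
#' @param exclude_clusters Cluster labels dropped from the analysis.
#' @return An object of class `cross_split_jsd`: list with `barcodes`,
#'   `matrix` (shared barcodes x shared barcodes), `diagonal`,
#'   `diag_mean`, `offdiag_mean`, and `diag_rank` (rank of each diagonal
#'   entry within its row, 1 = smallest distance).
#' @export
cross_split_jsd <- function(cells_A, cells_B, min_cells_per_split = 5L,
                            normalization = c("pooled", "per_split"),
                            exclude_clusters = NULL) {
  normalization <- match.arg(normalization)
  need <- c("cell_id", "barcode", "cluster")
  stopifnot(all(need %in% names(cells_A)), all(need %in% names(cells_B)))
  A <- cells_A[!(cells_A$cluster %in% exclude_clusters), need]
  B <- cells_B[!(cells_B$cluster %in% exclude_clusters), need]

  nA <- table(A$barcode); nB <- table(B$barcode)
  shared <- sort(intersect(names(nA)[nA >= min_cells_per_split],
                           names(nB)[nB >= min_cells_per_split]))
  if (length(shared) == 0L) {
    stop("no barcode with >= min_cells_per_split cells in both splits")
  }
  A <- A[A$barcode %in% shared, ]
  B <- B[B$barcode %in% shared, ]

  lev <- sort(unique(c(A$cluster, B$cluster)))
  pooled_nk <- table(factor(c(A$cluster, B$cluster), levels = lev))
  probs_for <- function(df) {
    nk <- if (normalization == "pooled") pooled_nk else
      table(factor(df$cluster, levels = lev))
    sapply(shared, function(b) {
      ck <- table(factor(df$cluster[df$barcode == b], levels = lev))
      ratio <- as.numeric(ck) / pmax(as.numeric(nk), 1)
      ratio[as.numeric(nk) == 0] <- 0
      ratio / sum(ratio)
    })
  }
  PA <- probs_for(A)  # clusters x barcodes
  PB <- probs_for(B)

  n <- length(shared)
  m <- matrix(NA_real_, n, n, dimnames = list(A = shared, B = shared))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- jensen_shannon_distance(PA[, i], PB[, j])
    }
  }
  diag_rank <- vapply(seq_len(n), function(i) rank(m[i, ])[i], numeric(1))
  structure(list(
    barcodes = shared,
    matrix = m,
    diagonal = diag(m),
    diag_mean = mean(diag(m)),
    offdiag_mean = if (n > 1) mean(m[row(m) != col(m)]) else NA_real_,
    diag_rank = diag_rank
  ), class = "cross_split_jsd")
}

#' Per-split barcode abundance table
#'
#' Full outer join of two cell-barcode assignment tables on barcode,
#' counting cells per barcode in each split (0 where absent), sorted by
#' combined abundance.
#'
#' @param table_A,table_B data.frames with a `barcode` column (one row per
#'   assigned cell), e.g. the `table` of [assign_cells()].
#' @return data.frame with columns `barcode`, `cells_A`, `cells_B`,
#'   `total`, sorted by `total` descending.
#' @export
split_abundance_table <- function(table_A, table_B) {
  cnt <- function(df) {
    if (nrow(df) == 0L) return(data.frame(barcode = character(0),
                                          n = integer(0)))
    t <- table(df$barcode)
    data.frame(barcode = names(t), n = as.integer(t),
               stringsAsFactors = FALSE)
  }
  a <- cnt(table_A); b <- cnt(table_B)
  out <- merge(a, b, by = "barcode", all = TRUE, suffixes = c("_A", "_B"))
  if (nrow(out) == 0L) {
    return(data.frame(barcode = character(0), cells_A = integer(0),
                      cells_B = integer(0), total = integer(0)))
  }
  names(out) <- c("barcode", "cells_A", "cells_B")
  out$cells_A[is.na(out$cells_A)] <- 0L
  out$cells_B[is.na(out$cells_B)] <- 0L
  out$total <- out$cells_A + out$cells_B
  out <- out[order(-out$total, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of variance explained per principal component, with a
#' randomized-data baseline
#'
#' Runs PCA on a cells-by-features matrix of variance-stabilized values and
#' reports, for the top `n_pcs` components, the eigenvalue divided by the
#' total variance (sum of per-feature variances). The chance baseline
#' repeats the computation after independently permuting each feature's
#' values across cells, which destroys covariance structure while
#' preserving every feature's marginal distribution.
#'
#' @param mat Numeric matrix, cells in rows, features in columns.
#' @param n_pcs Number of leading components to report.
#' @param seed Integer seed for the permutation.
#' @return An object of class `variance_profile`: list with `fractions`,
#'   `baseline_fractions` (each length `n_pcs`), and `total_variance`.
#' @export
variance_profile <- function(mat, n_pcs = 10L, seed = 1L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) stop("need >= 2 cells and features")
  n_pcs <- min(check_count(n_pcs, "n_pcs"), nrow(mat) - 1L, ncol(mat))
  total_var <- sum(apply(mat, 2, stats::var))
  if (total_var == 0) stop("matrix has zero total variance")
  frac <- function(m) {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    (pc$sdev^2 / sum(apply(m, 2, stats::var)))[seq_len(n_pcs)]
  }
  fractions <- frac(mat)
  baseline <- local_seed(seed, {
    perm <- apply(mat, 2, function(col) col[sample.int(length(col))])
    frac(perm)
  })
  structure(list(fractions = fractions, baseline_fractions = baseline,
                 total_variance = total_var),
            class = "variance_profile")
}
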