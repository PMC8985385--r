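# Shared fixtures and independent oracle implementations used to
# cross-check the package's own code paths.

# Brute-force Jensen-Shannon distance written directly from the definition,
# independent of the package implementation (explicit per-element loop,
# no shared helpers).
oracle_jsd <- function(p, q, root = TRUE) {
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * log(p[i] / m[i], base = 2)
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * log(q[i] / m[i], base = 2)
  }
  if (root) sqrt(acc) else acc
}

# Exhaustive center-based clustering oracle: computes the full Levenshtein
# distance matrix up front, then replays the abundance-ordered center
# assignment from it. Same contract as the greedy incremental scheme but a
# different code path (full matrix vs on-the-fly distances).
oracle_cluster <- function(prefixes, counts, max_dist) {
  ord <- order(-counts, prefixes)
  D <- utils::adist(prefixes)
  centers <- integer(0)
  assign <- integer(length(prefixes))
  for (i in ord) {
    hit <- centers[D[i, centers] <= max_dist]
    if (length(hit)) {
      assign[i] <- match(hit[1L], centers)
    } else {
      centers <- c(centers, i)
      assign[i] <- length(centers)
    }
  }
  assign
}

random_probs <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# A small balanced cluster pool for statistics tests.
make_pool <- function(n_cells = 600, n_clusters = 6, seed = 42,
                      weights = NULL) {
  withr::with_seed(seed, {
    if (is.null(weights)) weights <- rep(1 / n_clusters, n_clusters)
    data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      cluster = sample(sprintf("k%02d", seq_len(n_clusters)), n_cells,
                       replace = TRUE, prob = weights),
      stringsAsFactors = FALSE
    )
  })
}

# Build a FASTQ data.frame from explicit read fields (10x layout).
make_10x_read <- function(cell, umi, barcode, anchor = default_anchor(),
                          qual_char = "F") {
  seq <- paste0(cell, umi, anchor, barcode)
  data.frame(id = paste0("r", seq_len(length(seq))), seq = seq,
             qual = strrep(qual_char, nchar(seq)), stringsAsFactors = FALSE)
}
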