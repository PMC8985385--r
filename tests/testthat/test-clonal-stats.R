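# Cluster probability distributions, Jensen-Shannon distance, resampling
# homogeneity tests, cross-split comparison and the PCA variance profile.

test_that("jensen_shannon_distance matches the definition and its bounds", {
  # bounds under log-base-2 KL
  expect_identical(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)
  expect_identical(jensen_shannon_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  p14 <- rep(1 / 14, 14)
  expect_identical(jensen_shannon_distance(p14, p14), 0)
  # direct evaluation of the two KL terms (independent oracle)
  expect_equal(jensen_shannon_distance(c(0.5, 0.5), c(1, 0)),
               oracle_jsd(c(0.5, 0.5), c(1, 0)))
  expect_equal(round(jensen_shannon_distance(c(0.5, 0.5), c(1, 0)), 4),
               0.5579)
  # divergence form is the square of the distance form
  p <- c(0.2, 0.5, 0.3); q <- c(0.6, 0.1, 0.3)
  expect_equal(jensen_shannon_distance(p, q, form = "divergence"),
               jensen_shannon_distance(p, q)^2)
  # input validation
  expect_error(jensen_shannon_distance(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(jensen_shannon_distance(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
  expect_error(jensen_shannon_distance(c(1.2, -0.2), c(0.5, 0.5)),
               "nonnegative")
})

test_that("JSD is a symmetric metric on random instances", {
  withr::with_seed(101, {
    for (i in 1:200) {
      k <- sample(2:10, 1)
      p <- random_probs(k); q <- random_probs(k); r <- random_probs(k)
      d_pq <- jensen_shannon_distance(p, q)
      expect_identical(d_pq, jensen_shannon_distance(q, p))
      expect_true(d_pq >= 0 && d_pq <= 1)
      # triangle inequality of the distance (root) form
      expect_lte(d_pq, jensen_shannon_distance(p, r) +
                   jensen_shannon_distance(r, q) + 1e-12)
      # agreement with the brute-force oracle
      expect_equal(d_pq, oracle_jsd(p, q), tolerance = 1e-12)
    }
  })
})

test_that("derive_cluster_probability implements the two-stage normalization", {
  pool <- data.frame(cell_id = sprintf("c%03d", 1:50),
                     cluster = rep(c("k0", "k1"), c(10, 40)))
  # clone with counts {k0: 5, k1: 10} against totals {10, 40}:
  # ratios (0.5, 0.25) -> (2/3, 1/3)
  clone <- c(sprintf("c%03d", 1:5), sprintf("c%03d", 11:20))
  p <- derive_cluster_probability(clone, pool)
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3))
  expect_equal(attr(p, "n_cells"), 15L)
  # clone entirely in one cluster -> indicator distribution
  p1 <- derive_cluster_probability(sprintf("c%03d", 11:15), pool)
  expect_equal(as.numeric(p1), c(0, 1))
  # clone = whole pool -> uniform over retained clusters
  pu <- derive_cluster_probability(pool$cell_id, pool)
  expect_equal(as.numeric(pu), c(0.5, 0.5))
  # cluster exclusion removes the cluster before normalization
  pe <- derive_cluster_probability(sprintf("c%03d", 11:15), pool,
                                   exclude_clusters = "k0")
  expect_equal(as.numeric(pe), 1)
  expect_error(derive_cluster_probability(character(0), pool), "no cells")
  expect_error(derive_cluster_probability("absent", pool), "absent")
})

test_that("probability distributions are normalized on random clones", {
  pool <- make_pool(400, 7, seed = 7, weights = (7:1) / sum(7:1))
  withr::with_seed(8, {
    for (i in 1:50) {
      clone <- sample(pool$cell_id, sample(5:80, 1))
      p <- derive_cluster_probability(clone, pool)
      expect_true(all(p >= 0))
      expect_lt(abs(sum(p) - 1), 1e-9)
    }
  })
})

test_that("reference distribution is near uniform, deterministic and convergent", {
  # strongly unbalanced pool: the per-cluster normalization still yields a
  # near-uniform reference
  pool <- make_pool(800, 6, seed = 9, weights = c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04))
  ref <- reference_distribution(pool, clone_size = 30, n_samples = 400,
                                seed = 2)
  expect_lt(max(abs(ref - 1 / 6)), 0.02)
  expect_identical(ref, reference_distribution(pool, 30, 400, seed = 2))
  # sampling the whole pool gives the exactly uniform distribution
  ref_all <- reference_distribution(pool, nrow(pool), n_samples = 3, seed = 1)
  expect_equal(unname(ref_all), rep(1 / 6, 6))
  # doubling the sample count moves the reference by < 2% total variation
  r1 <- reference_distribution(pool, 30, 1000, seed = 3)
  r2 <- reference_distribution(pool, 30, 2000, seed = 4)
  expect_lt(0.5 * sum(abs(r1 - r2)), 0.02)
  expect_error(reference_distribution(pool, nrow(pool) + 1, 10), "pool size")
})

test_that("homogeneity test flags concentrated clones and spares random ones", {
  pool <- make_pool(1000, 6, seed = 11)
  # fully concentrated clone in a large uniform pool: observed JSD beats
  # every null draw, p = 1 / (n_samples + 1)
  conc <- head(pool$cell_id[pool$cluster == "k01"], 25)
  res1 <- jsd_homogeneity_test(conc, pool, n_samples = 1000, seed = 5)
  expect_equal(res1$p_value, 1 / 1001)
  expect_length(res1$null_jsds, 1000)
  expect_gt(res1$observed_jsd, max(res1$null_jsds))
  # clone drawn uniformly from the pool: p is approximately Uniform(0, 1]
  withr::with_seed(12, {
    ps <- vapply(1:60, function(i) {
      clone <- sample(pool$cell_id, 25)
      jsd_homogeneity_test(clone, pool, n_samples = 200,
                           seed = 1000 + i)$p_value
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
  # clones below the size floor are refused
  expect_error(jsd_homogeneity_test(conc[1:5], pool, min_cells = 20),
               "min_cells")
})

test_that("clone_jsd_table screens by size and returns per-clone results", {
  pool <- make_pool(600, 5, seed = 13)
  withr::with_seed(14, {
    assignments <- data.frame(
      cell_id = pool$cell_id,
      barcode = sample(c(rep("bigA", 200), rep("bigB", 150),
                         rep("tiny", 10), rep(NA, 240))))
    assignments <- assignments[!is.na(assignments$barcode), ]
  })
  res <- clone_jsd_table(assignments, pool, min_cells = 20, n_samples = 200,
                         seed = 15)
  expect_setequal(res$barcode, c("bigA", "bigB"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_identical(res, clone_jsd_table(assignments, pool, min_cells = 20,
                                        n_samples = 200, seed = 15))
})

test_that("cross-split JSD matrix has the stated geometry", {
  mk <- function(barcodes, clusters, split) {
    data.frame(cell_id = sprintf("%s%04d", split, seq_along(barcodes)),
               barcode = barcodes, cluster = clusters)
  }
  # two clones, 6 cells each per split; clone b1 identically distributed in
  # both splits, clone b2 on a disjoint cluster in B
  A <- mk(rep(c("b1", "b2"), each = 6),
          c(rep("k1", 3), rep("k2", 3), rep("k3", 6)), "A")
  B <- mk(rep(c("b1", "b2"), each = 6),
          c(rep("k1", 3), rep("k2", 3), rep("k4", 6)), "B")
  xs <- cross_split_jsd(A, B, min_cells_per_split = 5)
  expect_equal(xs$barcodes, c("b1", "b2"))
  expect_equal(unname(xs$matrix["b1", "b1"]), 0)
  expect_equal(unname(xs$matrix["b2", "b2"]), 1)  # disjoint clusters
  # swapping split labels transposes the matrix
  xs_sw <- cross_split_jsd(B, A, min_cells_per_split = 5)
  expect_equal(xs_sw$matrix, t(xs$matrix), ignore_attr = TRUE)
  # too-small clones are screened out
  expect_error(cross_split_jsd(A[1:3, ], B[1:3, ], min_cells_per_split = 5),
               "min_cells_per_split")
})

test_that("split_abundance_table outer-joins and conserves totals", {
  tA <- data.frame(cell_id = sprintf("a%02d", 1:9),
                   barcode = c(rep("b1", 7), rep("b2", 2)))
  tB <- data.frame(cell_id = sprintf("b%02d", 1:4),
                   barcode = c(rep("b2", 3), "b3"))
  out <- split_abundance_table(tA, tB)
  expect_equal(out$barcode, c("b1", "b2", "b3"))
  expect_equal(out$cells_A, c(7L, 2L, 0L))
  expect_equal(out$cells_B, c(0L, 3L, 1L))
  expect_equal(sum(out$cells_A), nrow(tA))
  expect_equal(sum(out$cells_B), nrow(tB))
  empty <- split_abundance_table(tA[0, ], tB[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("variance profile separates signal from the permutation baseline", {
  withr::with_seed(16, {
    # rank-1 signal: every feature a noisy copy of one latent direction
    latent <- rnorm(80)
    sig <- sapply(1:30, function(i) latent * runif(1, 0.8, 1.2) +
                    rnorm(80, sd = 0.05))
    vp <- variance_profile(sig, n_pcs = 5, seed = 3)
    expect_gt(vp$fractions[1], 0.9)
    expect_true(all(diff(vp$fractions) <= 1e-12))
    expect_lt(vp$baseline_fractions[1], vp$fractions[1])
    # iid noise: top fraction close to the permuted baseline
    noise <- matrix(rnorm(80 * 30), 80, 30)
    vn <- variance_profile(noise, n_pcs = 5, seed = 4)
    expect_lt(abs(vn$fractions[1] - vn$baseline_fractions[1]), 0.03)
  })
  expect_error(variance_profile(matrix(1, 10, 10)), "zero total variance")
})
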