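# Barcode recovery: anchored extraction, prefix merging, cell assignment,
# and the diversity / MOI estimators.

anchor <- default_anchor()
wsn30 <- function(seed) {
  substr(generate_barcode_library(1, seed = seed)$sequences[[1]], 1, 100)
}

test_that("extract_barcodes applies the anchor, quality and homopolymer filters", {
  cell <- strrep("A", 16); umi <- strrep("C", 12)
  good_bc <- wsn30(1)
  reads <- rbind(
    make_10x_read(cell, umi, good_bc),                       # clean
    data.frame(id = "no_anchor",
               seq = paste0(cell, umi, strrep("T", 20), good_bc),
               qual = strrep("F", 16 + 12 + 20 + 100)),
    make_10x_read(cell, umi,
                  paste0(substr(good_bc, 1, 40), strrep("A", 8),
                         substr(good_bc, 49, 100))),          # 8-base A run
    make_10x_read(cell, umi, good_bc, qual_char = "+")        # Phred 10
  )
  reads$id <- c("clean", "no_anchor", "homopolymer", "lowq")
  ex <- extract_barcodes(reads, anchor = anchor, max_homopolymer = 6,
                         min_quality = 30)
  expect_equal(ex$records$read_id, "clean")
  expect_equal(ex$records$cell_id, cell)
  expect_equal(ex$records$umi, umi)
  expect_equal(ex$records$barcode_seq, good_bc)
  expect_equal(unname(ex$drops[c("no_anchor", "homopolymer", "low_quality")]),
               c(1L, 1L, 1L))
  # one anchor mismatch is tolerated, two are not
  mm1 <- anchor; substr(mm1, 3, 3) <- ifelse(substr(mm1, 3, 3) == "A", "C", "A")
  mm2 <- mm1; substr(mm2, 7, 7) <- ifelse(substr(mm2, 7, 7) == "A", "C", "A")
  r1 <- data.frame(id = "mm1", seq = paste0(cell, umi, mm1, good_bc),
                   qual = strrep("F", 148))
  r2 <- data.frame(id = "mm2", seq = paste0(cell, umi, mm2, good_bc),
                   qual = strrep("F", 148))
  expect_equal(nrow(extract_barcodes(r1, anchor = anchor)$records), 1L)
  expect_warning(ex2 <- extract_barcodes(r2, anchor = anchor), "anchor")
  expect_equal(nrow(ex2$records), 0L)
})

test_that("merge_barcodes merges near prefixes, sums counts, keeps dominant representative", {
  b1 <- wsn30(2)
  b1_err <- b1; substr(b1_err, 5, 5) <- ifelse(substr(b1_err, 5, 5) == "A", "T", "A")
  recs <- data.frame(
    read_id = sprintf("r%03d", 1:105),
    cell_id = "CELL",
    umi = sprintf("U%03d", 1:105),
    barcode_seq = c(rep(b1, 100), rep(b1_err, 5)),
    mean_quality = 37, stringsAsFactors = FALSE)
  cat1 <- merge_barcodes(recs, max_dist = 6)
  expect_equal(nrow(cat1$entries), 1L)
  expect_equal(cat1$entries$reads, 105L)
  expect_equal(cat1$entries$umis, 105L)
  expect_equal(cat1$entries$representative, b1)

  # identical sequences collapse to a single entry with summed counts
  recs2 <- recs; recs2$barcode_seq <- b1
  expect_equal(nrow(merge_barcodes(recs2)$entries), 1L)

  # prefixes exactly at distance 7 stay separate at max_dist 6, merge at 8
  b2 <- b1
  pos <- seq(3, by = 3, length.out = 7)  # N positions: free substitutions
  for (p in pos) substr(b2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                             substr(b2, p, p))[1]
  expect_equal(c(utils::adist(substr(b1, 1, 30), substr(b2, 1, 30))), 7)
  recs3 <- recs
  recs3$barcode_seq <- c(rep(b1, 100), rep(b2, 5))
  expect_equal(nrow(merge_barcodes(recs3, max_dist = 6)$entries), 2L)
  expect_equal(nrow(merge_barcodes(recs3, max_dist = 7)$entries), 1L)
})

test_that("catalog read counts are conserved and merging is idempotent and order-invariant", {
  withr::with_seed(5, {
    lib <- generate_barcode_library(20, seed = 5)$sequences
    true_bc <- sample(lib, 400, replace = TRUE)
    noisy <- vapply(true_bc, function(b) {
      if (runif(1) < 0.3) {
        p <- sample.int(30, 1)
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      b
    }, character(1), USE.NAMES = FALSE)
    recs <- data.frame(read_id = sprintf("r%04d", seq_along(noisy)),
                       cell_id = "CELL", umi = sprintf("U%04d", seq_along(noisy)),
                       barcode_seq = noisy, mean_quality = 37,
                       stringsAsFactors = FALSE)
    cat1 <- merge_barcodes(recs, max_dist = 6)
    expect_equal(sum(cat1$entries$reads), nrow(recs))
    # idempotence: merging the representatives again changes nothing
    reps <- data.frame(read_id = seq_len(nrow(cat1$entries)),
                       cell_id = "CELL", umi = seq_len(nrow(cat1$entries)),
                       barcode_seq = cat1$entries$representative,
                       mean_quality = 37)
    cat2 <- merge_barcodes(reps, max_dist = 6)
    expect_equal(sort(cat2$entries$representative),
                 sort(cat1$entries$representative))
    # input-order invariance
    perm <- sample.int(nrow(recs))
    cat3 <- merge_barcodes(recs[perm, ], max_dist = 6)
    expect_equal(cat3$entries, cat1$entries)
  })
})

test_that("greedy prefix clustering matches the exhaustive-matrix oracle", {
  withr::with_seed(6, {
    for (rep in 1:8) {
      n <- sample(10:50, 1)
      base <- generate_barcode_library(6, seed = rep)$sequences
      prefixes <- unique(vapply(seq_len(n), function(i) {
        b <- substr(sample(base, 1), 1, 30)
        for (k in seq_len(sample(0:6, 1))) {
          p <- sample.int(30, 1)
          substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        b
      }, character(1)))
      counts <- sample.int(100, length(prefixes), replace = TRUE)
      got <- clonefate:::cluster_prefixes(prefixes, counts, max_dist = 6)
      want <- oracle_cluster(prefixes, counts, max_dist = 6)
      expect_equal(got, want)
    }
  })
})

test_that("assign_cells applies UMI and dominance filters with a pre-filter denominator", {
  df <- data.frame(
    cell_id = c("c1", "c1", "c2", "c2", "c2", "c3"),
    barcode = c("b1", "b2", "b1", "b2", "b3", "b1"),
    umi_count = c(5L, 1L, 4L, 3L, 2L, 1L))
  res <- assign_cells(df, min_umi = 2, dominance_fraction = 0.30)
  # c1: b2 fails UMI filter, b1 has 5/6 ~ 83% -> assigned
  # c2: all pass UMI filter; shares 44/33/22% -> b3 dropped, two remain -> cell dropped
  # c3: single barcode below UMI filter -> cell dropped
  expect_equal(res$table$cell_id, "c1")
  expect_equal(res$table$barcode, "b1")
  expect_equal(res$table$umi_count, 5L)
  expect_equal(unname(res$drops["cells_multiple_barcodes"]), 1L)
  expect_equal(unname(res$drops["cells_no_barcode"]), 1L)
  # duplicate pair is an error
  expect_error(assign_cells(rbind(df, df[1, ])), "duplicate")
})

test_that("gdna catalog drops NNN representatives and respects distance 8", {
  b1 <- wsn30(7); b2 <- wsn30(8)
  b_nnn <- paste0(substr(b1, 1, 50), "NNN", substr(b1, 54, 100))
  umis <- sprintf("A%s", substr(wsn30(9), 1, 5))
  mk <- function(bc, n, tag) {
    data.frame(id = sprintf("%s_%d", tag, 1:n),
               seq = paste0("ACAAAT", anchor, bc),
               qual = strrep("F", 6 + nchar(anchor) + nchar(bc)))
  }
  fq <- rbind(mk(b2, 50, "a"), mk(b_nnn, 40, "n"))
  d <- withr::local_tempdir()
  path <- file.path(d, "g.fastq.gz")
  write_fastq(fq, path)
  cat1 <- recover_gdna_catalog(path, anchor = anchor)
  expect_equal(cat1$entries$representative, b2)
  expect_equal(unname(cat1$drops["nnn_entries"]), 1L)
  # distance-8 merge semantics on prefixes
  b3 <- b2
  pos <- seq(3, by = 3, length.out = 8)
  for (p in pos) substr(b3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                             substr(b3, p, p))[1]
  fq2 <- rbind(mk(b2, 50, "a"), mk(b3, 5, "b"))
  path2 <- file.path(d, "g2.fastq.gz")
  write_fastq(fq2, path2)
  expect_equal(nrow(recover_gdna_catalog(path2, anchor = anchor,
                                         max_dist = 8)$entries), 1L)
  expect_equal(nrow(recover_gdna_catalog(path2, anchor = anchor,
                                         max_dist = 7)$entries), 2L)
})

test_that("round trip: error-free reads reproduce catalog and assignments exactly", {
  cfg <- sim_config(n_cells = 150, moi = 0.4, n_divisions_pre_split = 2,
                    n_divisions_post_split = 1, n_clusters = 5,
                    loss_coefficient = 0.9, seed = 81)
  tt <- simulate_clonal_differentiation(cfg)
  d <- withr::local_tempdir()
  rr <- simulate_reads(tt, d, mode = "10x", error_rate = 0, seed = 3)
  ex <- extract_barcodes(rr$fastq[["A"]])
  expect_equal(sum(ex$drops), 0L)
  catalog <- merge_barcodes(ex)
  truth_A <- rr$read_truth[rr$read_truth$split == "A", ]
  true_seqs <- sort(unique(unname(tt$library$sequences[truth_A$barcode_id])))
  expect_equal(sort(catalog$entries$representative), true_seqs)
  # per-entry read counts match the truth table
  want <- table(unname(tt$library$sequences[truth_A$barcode_id]))
  expect_equal(catalog$entries$reads,
               as.integer(want[catalog$entries$representative]))
  # single-barcode cells with >= 2 UMIs are all correctly assigned
  asg <- assign_cells(cell_umi_table(ex, catalog))
  cells <- tt$cells[tt$cells$split == "A" & tt$cells$survived &
                      !is.na(tt$cells$barcode_id), ]
  single <- cells[!grepl(";", cells$barcode_id), ]
  umis_per_cell <- tapply(truth_A$umi, truth_A$cell_id,
                          function(u) length(unique(u)))
  eligible <- single[umis_per_cell[single$cell_id] >= 2, ]
  got <- setNames(asg$table$barcode, asg$table$cell_id)
  expect_true(all(got[eligible$cell_id] ==
                    unname(tt$library$sequences[eligible$barcode_id])))
})

test_that("mark-recapture and MOI estimators match their closed forms", {
  expect_equal(estimate_diversity(100, 100, 100), 100)
  expect_equal(estimate_diversity(1000, 2000, 10), 200000)
  expect_error(estimate_diversity(10, 10, 0), "undefined")
  expect_error(estimate_diversity(10, 10, 11), "exceed")

  expect_equal(estimate_moi(0), 0)
  # oracle: numerically invert 1 - exp(-m) = 0.39
  inv <- uniroot(function(m) 1 - exp(-m) - 0.39, c(0, 5), tol = 1e-12)$root
  expect_equal(estimate_moi(0.39), inv, tolerance = 1e-9)
  expect_equal(round(estimate_moi(0.39), 3), 0.494)
  expect_warning(m5 <- estimate_moi(0.5), "0.40")
  expect_equal(m5, log(2))
  expect_error(estimate_moi(1), "gfp_fraction")
})
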