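# Barcode recovery: anchored extraction of barcode records from amplicon
# reads, Levenshtein-prefix merging of sequencing variants into a barcode
# catalog, and filtered one-to-one cell-barcode assignment.

#' Extract raw barcode records from amplicon reads
#'
#' Scans each read for the constant anchor sequence (allowing up to
#' `max_anchor_mismatch` mismatches) and takes the barcode as the
#' `barcode_length` bases that follow it. Reads are discarded when the
#' anchor is absent, when the barcode region is shorter than `min_length`,
#' when its mean Phred quality falls below `min_quality`, or when it
#' contains a homopolymer run longer than `max_homopolymer` (the WSN
#' barcode design cannot produce runs above 2 in W/S positions, so long
#' runs indicate artifacts).
#'
#' In `"10x"` mode the 16-nt cell identifier and 12-nt UMI preceding the
#' anchor are recorded; in `"gdna"` mode the 6-nt pseudo-UMI at the read
#' start is recorded and `cell_id` is `NA`.
#'
#' @param fastq Path to a FASTQ(.gz) file, or a data.frame as returned by
#'   [read_fastq()].
#' @param anchor Anchor sequence expected 5' of the barcode.
#' @param mode `"10x"` or `"gdna"` read layout.
#' @param min_quality Minimum mean Phred score over the barcode region.
#' @param max_homopolymer Longest allowed single-base run in the barcode.
#' @param barcode_length Barcode bases taken after the anchor.
#' @param min_length Minimum barcode-region length (reads truncated shorter
#'   than this are dropped).
#' @param max_anchor_mismatch Mismatches tolerated in the anchor match.
#' @return An object of class `barcode_records`: list with `records`
#'   (data.frame: `read_id`, `cell_id`, `umi`, `barcode_seq`,
#'   `mean_quality`) and `drops` (named integer vector of discarded-read
#'   counts by reason: `no_anchor`, `too_short`, `low_quality`,
#'   `homopolymer`).
#' @export
extract_barcodes <- function(fastq,
                             anchor = default_anchor(),
                             mode = c("10x", "gdna"),
                             min_quality = 30,
                             max_homopolymer = 6L,
                             barcode_length = 100L,
                             min_length = 30L,
                             max_anchor_mismatch = 1L) {
  mode <- match.arg(mode)
  if (!nzchar(anchor)) stop("`anchor` must be nonempty")
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))

  n <- nrow(reads)
  drops <- c(no_anchor = 0L, too_short = 0L, low_quality = 0L,
             homopolymer = 0L)
  empty <- data.frame(read_id = character(0), cell_id = character(0),
                      umi = character(0), barcode_seq = character(0),
                      mean_quality = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(records = empty, drops = drops),
                     class = "barcode_records"))
  }

  seqs <- Biostrings::DNAStringSet(reads$seq)
  hits <- Biostrings::vmatchPattern(anchor, seqs,
                                    max.mismatch = max_anchor_mismatch)
  starts <- vapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s) || length(s) == 0L) NA_integer_ else s[[1L]]
  }, integer(1))

  has_anchor <- !is.na(starts)
  drops["no_anchor"] <- sum(!has_anchor)
  if (!any(has_anchor)) {
    warning("anchor not found in any read")
    return(structure(list(records = empty, drops = drops),
                     class = "barcode_records"))
  }

  idx <- which(has_anchor)
  bc_start <- starts[idx] + nchar(anchor)
  read_len <- nchar(reads$seq[idx])
  avail <- pmax(0L, read_len - bc_start + 1L)
  long_enough <- avail >= min_length
  drops["too_short"] <- sum(!long_enough)
  idx <- idx[long_enough]
  bc_start <- bc_start[long_enough]
  avail <- avail[long_enough]
  if (length(idx) == 0L) {
    return(structure(list(records = empty, drops = drops),
                     class = "barcode_records"))
  }

  bc_end <- bc_start + pmin(avail, barcode_length) - 1L
  barcode <- substr(reads$seq[idx], bc_start, bc_end)
  bq <- substr(reads$qual[idx], bc_start, bc_end)
  mq <- mean_phred(bq)

  good_q <- mq >= min_quality
  drops["low_quality"] <- sum(!good_q)

  run_re <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}|N{%d,}",
                    max_homopolymer + 1L, max_homopolymer + 1L,
                    max_homopolymer + 1L, max_homopolymer + 1L,
                    max_homopolymer + 1L)
  good_run <- !grepl(run_re, barcode)
  drops["homopolymer"] <- sum(good_q & !good_run)

  keep <- good_q & good_run
  idx <- idx[keep]
  barcode <- barcode[keep]
  mq <- mq[keep]
  bc_start <- bc_start[keep]

  if (mode == "10x") {
    cell_id <- substr(reads$seq[idx], 1L, 16L)
    umi <- substr(reads$seq[idx], 17L, 28L)
  } else {
    cell_id <- rep(NA_character_, length(idx))
    umi <- substr(reads$seq[idx], 1L, 6L)
  }

  records <- data.frame(
    read_id = reads$id[idx],
    cell_id = cell_id,
    umi = umi,
    barcode_seq = barcode,
    mean_quality = mq,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, drops = drops),
            class = "barcode_records")
}

# Greedy center-based clustering of barcode prefixes by Levenshtein
# distance. Prefixes are processed in descending read-count order
# (lexicographic tie-break); each joins the first existing center within
# `max_dist` (centers are held in founding order, i.e. descending
# abundance), else founds a new center. Returns an integer cluster id per
# input prefix.
cluster_prefixes <- function(prefixes, counts, max_dist) {
  ord <- order(-counts, prefixes)
  centers <- character(0)
  assign <- integer(length(prefixes))
  for (i in ord) {
    if (length(centers)) {
      d <- utils::adist(prefixes[i], centers)[1L, ]
      hit <- which(d <= max_dist)
    } else {
      hit <- integer(0)
    }
    if (length(hit)) {
      assign[i] <- hit[1L]
    } else {
      centers <- c(centers, prefixes[i])
      assign[i] <- length(centers)
    }
  }
  assign
}

#' Merge barcode records into a catalog by prefix Levenshtein distance
#'
#' Sequencing and PCR errors scatter each true barcode into a cloud of
#' near-identical sequences. Following the starcode-style approach, the
#' first `prefix_len` bases of every distinct barcode sequence are
#' clustered greedily: prefixes are visited in descending read-abundance
#' order (ties broken lexicographically) and each joins the most abundant
#' existing cluster center within Levenshtein distance `max_dist`, founding
#' a new center otherwise. Read and UMI counts are summed per cluster and
#' the representative is the most abundant full-length member sequence.
#'
#' @param records A `barcode_records` object or its `records` data.frame.
#' @param prefix_len Prefix length used for distance computation
#'   (default 30).
#' @param max_dist Maximum Levenshtein distance for merging (6 for 10x-mode
#'   amplicons, 8 for genomic DNA).
#' @return An object of class `barcode_catalog`: list with
#'   `entries` (data.frame: `entry`, `representative`, `reads`, `umis`,
#'   ordered by reads descending), and `prefix_map` (data.frame mapping
#'   each observed prefix to its entry). UMIs are counted as distinct
#'   `(cell_id, umi)` pairs per entry.
#' @export
merge_barcodes <- function(records, prefix_len = 30L, max_dist = 6L) {
  if (inherits(records, "barcode_records")) records <- records$records
  if (nrow(records) == 0L) stop("no records to merge")
  if (max_dist < 0L || prefix_len < 1L) stop("invalid merge configuration")

  prefix <- substr(records$barcode_seq, 1L, prefix_len)
  upfx <- sort(unique(prefix))
  pcount <- as.integer(table(factor(prefix, levels = upfx)))

  cl <- cluster_prefixes(upfx, pcount, max_dist)
  rec_cl <- cl[match(prefix, upfx)]

  entries <- lapply(sort(unique(cl)), function(k) {
    in_k <- rec_cl == k
    seq_counts <- sort(table(records$barcode_seq[in_k]), decreasing = TRUE)
    top <- max(seq_counts)
    rep_seq <- min(names(seq_counts)[seq_counts == top])  # lexicographic tie-break
    umi_key <- paste(records$cell_id[in_k], records$umi[in_k], sep = "\r")
    data.frame(representative = rep_seq,
               reads = sum(in_k),
               umis = length(unique(umi_key)),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, entries)
  entries$cluster <- sort(unique(cl))
  ord <- order(-entries$reads, entries$representative)
  entries <- entries[ord, , drop = FALSE]
  entries$entry <- seq_len(nrow(entries))
  renumber <- match(cl, entries$cluster)
  entries <- entries[, c("entry", "representative", "reads", "umis")]
  rownames(entries) <- NULL

  prefix_map <- data.frame(prefix = upfx, entry = renumber,
                           stringsAsFactors = FALSE)
  structure(list(entries = entries, prefix_map = prefix_map,
                 prefix_len = prefix_len, max_dist = max_dist),
            class = "barcode_catalog")
}

#' Tabulate distinct UMIs per (cell, catalog entry)
#'
#' Maps every extracted record to its merged catalog entry and counts the
#' distinct UMIs supporting each (cell, barcode) pair — the input
#' [assign_cells()] filters on.
#'
#' @param records A `barcode_records` object or its `records` data.frame.
#' @param catalog A `barcode_catalog` from [merge_barcodes()].
#' @return data.frame with columns `cell_id`, `barcode` (the entry's
#'   representative sequence), `umi_count`.
#' @export
cell_umi_table <- function(records, catalog) {
  if (inherits(records, "barcode_records")) records <- records$records
  stopifnot(inherits(catalog, "barcode_catalog"))
  prefix <- substr(records$barcode_seq, 1L, catalog$prefix_len)
  entry <- catalog$prefix_map$entry[match(prefix, catalog$prefix_map$prefix)]
  if (anyNA(entry)) stop("records contain prefixes absent from the catalog")
  rep_seq <- catalog$entries$representative[entry]
  key <- paste(records$cell_id, rep_seq, sep = "\r")
  agg <- tapply(records$umi, key, function(u) length(unique(u)))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    cell_id = vapply(parts, `[`, character(1), 1L),
    barcode = vapply(parts, `[`, character(1), 2L),
    umi_count = as.integer(agg),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Assign barcodes to cells with UMI and dominance filters
#'
#' Per cell: barcodes supported by fewer than `min_umi` distinct UMIs are
#' dropped; among the survivors only barcodes carrying at least
#' `dominance_fraction` of the cell's total UMI count (total taken before
#' the UMI filter) are kept; cells left with exactly one barcode are
#' assigned to it, cells with none or several are discarded. The result is
#' one-to-one: at most one barcode per cell.
#'
#' @param umi_counts data.frame with columns `cell_id`, `barcode`,
#'   `umi_count` (one row per pair; duplicated pairs are an error).
#' @param min_umi Minimum distinct UMIs per (cell, barcode) pair.
#' @param dominance_fraction Minimum share of the cell's total UMIs.
#' @return An object of class `cell_barcode_table`: list with `table`
#'   (data.frame `cell_id`, `barcode`, `umi_count`) and `drops` (named
#'   integer vector: `cells_no_barcode`, `cells_multiple_barcodes`, plus
#'   `pairs_low_umi`, `pairs_low_dominance`).
#' @export
assign_cells <- function(umi_counts, min_umi = 2L, dominance_fraction = 0.30) {
  stopifnot(all(c("cell_id", "barcode", "umi_count") %in% names(umi_counts)))
  if (dominance_fraction <= 0 || dominance_fraction > 1) {
    stop("`dominance_fraction` must be in (0, 1]")
  }
  if (any(umi_counts$umi_count < 0) ||
      any(umi_counts$umi_count != round(umi_counts$umi_count))) {
    stop("`umi_count` must contain nonnegative integers")
  }
  if (anyDuplicated(paste(umi_counts$cell_id, umi_counts$barcode, sep = "\r"))) {
    stop("duplicate (cell_id, barcode) pairs in input")
  }

  total <- tapply(umi_counts$umi_count, umi_counts$cell_id, sum)
  cell_total <- as.numeric(total[umi_counts$cell_id])

  pass_umi <- umi_counts$umi_count >= min_umi
  pass_dom <- umi_counts$umi_count >= dominance_fraction * cell_total
  keep <- pass_umi & pass_dom

  drops <- c(
    pairs_low_umi = sum(!pass_umi),
    pairs_low_dominance = sum(pass_umi & !pass_dom),
    cells_no_barcode = 0L,
    cells_multiple_barcodes = 0L
  )

  kept <- umi_counts[keep, , drop = FALSE]
  n_per_cell <- table(kept$cell_id)
  all_cells <- unique(umi_counts$cell_id)
  zero_cells <- setdiff(all_cells, names(n_per_cell))
  multi_cells <- names(n_per_cell)[n_per_cell > 1L]
  drops["cells_no_barcode"] <- length(zero_cells)
  drops["cells_multiple_barcodes"] <- length(multi_cells)

  out <- kept[!(kept$cell_id %in% multi_cells), , drop = FALSE]
  out <- out[order(out$cell_id), c("cell_id", "barcode", "umi_count")]
  rownames(out) <- NULL
  structure(list(table = out, drops = drops), class = "cell_barcode_table")
}

#' Recover a barcode catalog from genomic-DNA amplicon reads
#'
#' Runs anchored extraction in gDNA mode (pseudo-UMI layout), merges
#' prefixes at Levenshtein distance `max_dist` (default 8, the looser
#' threshold used for genomic-DNA libraries), then removes catalog entries
#' whose representative contains three consecutive unknown bases ("NNN").
#'
#' @inheritParams extract_barcodes
#' @param max_dist Maximum Levenshtein merge distance (default 8).
#' @param prefix_len Prefix length for merging (default 30).
#' @return A `barcode_catalog` (see [merge_barcodes()]) with an added
#'   `drops` element recording extraction-stage and NNN-filter losses.
#' @export
recover_gdna_catalog <- function(fastq,
                                 anchor = default_anchor(),
                                 max_dist = 8L,
                                 prefix_len = 30L,
                                 min_length = 30L,
                                 min_quality = 30) {
  ext <- extract_barcodes(fastq, anchor = anchor, mode = "gdna",
                          min_quality = min_quality, min_length = min_length)
  catalog <- merge_barcodes(ext, prefix_len = prefix_len, max_dist = max_dist)
  has_nnn <- grepl("NNN", catalog$entries$representative, fixed = TRUE)
  n_nnn <- sum(has_nnn)
  if (n_nnn > 0L) {
    dropped_entries <- catalog$entries$entry[has_nnn]
    catalog$entries <- catalog$entries[!has_nnn, , drop = FALSE]
    catalog$prefix_map <- catalog$prefix_map[
      !(catalog$prefix_map$entry %in% dropped_entries), , drop = FALSE]
    catalog$entries$entry <- seq_len(nrow(catalog$entries))
    # re-key the prefix map onto the renumbered entries
    catalog$prefix_map$entry <- match(
      catalog$prefix_map$entry,
      setdiff(seq_len(nrow(catalog$entries) + n_nnn), dropped_entries))
  }
  catalog$drops <- c(ext$drops, nnn_entries = n_nnn)
  catalog
}

#' Lincoln-Petersen mark-recapture diversity estimate
#'
#' Estimates total barcode-library diversity from two independent
#' transductions: with `n1` and `n2` barcodes observed and `overlap` seen
#' in both, the estimate is `n1 * n2 / overlap`.
#'
#' @param n1,n2 Barcodes observed in each sample.
#' @param overlap Barcodes observed in both.
#' @return The diversity estimate (a single number).
#' @examples
#' estimate_diversity(1000, 2000, 10)  # 200000
#' @export
estimate_diversity <- function(n1, n2, overlap) {
  n1 <- check_count(n1, "n1")
  n2 <- check_count(n2, "n2")
  if (!is.numeric(overlap) || length(overlap) != 1L || overlap < 0 ||
      overlap != round(overlap)) {
    stop("`overlap` must be a single nonnegative integer")
  }
  if (overlap > min(n1, n2)) stop("`overlap` cannot exceed min(n1, n2)")
  if (overlap == 0) stop("overlap of 0: diversity estimate is undefined")
  n1 * n2 / overlap
}

#' Estimate MOI from the transduced (GFP-positive) fraction
#'
#' Under a Poisson model of integrations the fraction of cells with at
#' least one integration is `1 - exp(-moi)`, so
#' `moi = -log(1 - gfp_fraction)`. Titration practice restricts the
#' inversion to fractions below 0.40, where the Poisson inversion is
#' reliable; larger inputs produce a warning.
#'
#' @param gfp_fraction Fraction of transduced (marker-positive) cells,
#'   in `[0, 1)`.
#' @return Estimated MOI.
#' @examples
#' estimate_moi(0.39)
#' @export
estimate_moi <- function(gfp_fraction) {
  if (!is.numeric(gfp_fraction) || length(gfp_fraction) != 1L ||
      is.na(gfp_fraction) || gfp_fraction < 0 || gfp_fraction >= 1) {
    stop("`gfp_fraction` must be a single value in [0, 1)")
  }
  if (gfp_fraction >= 0.40) {
    warning("gfp_fraction >= 0.40: outside the recommended titration range")
  }
  -log(1 - gfp_fraction)
}
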