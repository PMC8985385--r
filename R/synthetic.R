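# Synthetic barcoded-clone data generator.
#
# Emulates the statistical structure of a lineage-barcoding experiment:
# a WSN-patterned lentiviral barcode library, Poisson transduction at low
# MOI, clonal expansion, an even split across two parallel differentiations,
# cell loss during differentiation (independent or clone-heritable), clonal
# fate memory over expression clusters (Dirichlet-parameterized), and
# error-bearing amplicon reads in both 10X side-reaction and genomic-DNA
# layouts.

WSN_BASES <- list(W = c("A", "T"), S = c("G", "C"), N = c("A", "C", "G", "T"))

#' Generate a WSN-patterned lineage barcode library
#'
#' Barcodes are random 100-mers following a repeating "WSN" degenerate-base
#' pattern: positions 1, 4, 7, ... are W (A or T), positions 2, 5, 8, ... are
#' S (G or C), and positions 3, 6, 9, ... are N (any base). The pattern keeps
#' base composition balanced and rules out long homopolymer runs, which the
#' read-filtering stage exploits.
#'
#' @param n Number of unique barcodes to generate.
#' @param seed Integer seed; the same `(n, seed)` always yields the same
#'   library.
#' @param width Barcode length in nucleotides (default 100).
#' @return An object of class `barcode_library`: a list with `sequences`
#'   (character vector of unique pattern-conforming barcodes, named
#'   `bc0001`, `bc0002`, ...) and `seed`.
#' @examples
#' lib <- generate_barcode_library(10, seed = 1)
#' substr(lib$sequences[1], 1, 6)
#' @export
generate_barcode_library <- function(n, seed = 1L, width = 100L) {
  n <- check_count(n, "n")
  width <- check_count(width, "width")
  # capacity of the degenerate design (2 * 2 * 4 per triplet)
  pat <- rep(c("W", "S", "N"), length.out = width)
  log2_capacity <- sum(c(W = 1, S = 1, N = 2)[pat])
  if (log2_capacity <= 40 && n > 2^log2_capacity) {
    stop("n exceeds the capacity of the WSN pattern at this width")
  }
  local_seed(seed, {
    draw <- function(m) {
      cols <- lapply(pat, function(p) {
        sample(WSN_BASES[[p]], m, replace = TRUE)
      })
      do.call(paste0, cols)
    }
    seqs <- unique(draw(n))
    while (length(seqs) < n) {
      seqs <- unique(c(seqs, draw(n - length(seqs))))
    }
    seqs <- seqs[seq_len(n)]
    names(seqs) <- sprintf("bc%04d", seq_len(n))
    structure(list(sequences = seqs, seed = as.integer(seed)),
              class = "barcode_library")
  })
}

#' Simulate lentiviral transduction at a given MOI
#'
#' Each cell receives `k ~ Poisson(moi)` distinct barcodes drawn uniformly
#' from the library; cells with `k = 0` remain unbarcoded. The expected
#' barcoded fraction is `1 - exp(-moi)`.
#'
#' @param n_cells Number of cells exposed to virus.
#' @param moi Multiplicity of infection (Poisson mean integrations per cell).
#' @param library A `barcode_library`.
#' @param seed Integer seed.
#' @return A list of length `n_cells`; element `i` is an integer vector of
#'   library indices integrated in cell `i` (length 0 for unbarcoded cells).
#' @export
simulate_transduction <- function(n_cells, moi, library, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  if (!is.numeric(moi) || length(moi) != 1L || is.na(moi) || moi < 0) {
    stop("`moi` must be a single nonnegative number")
  }
  stopifnot(inherits(library, "barcode_library"))
  nlib <- length(library$sequences)
  local_seed(seed, {
    k <- rpois(n_cells, moi)
    k <- pmin(k, nlib)
    lapply(k, function(ki) {
      if (ki == 0L) integer(0) else sample.int(nlib, ki)
    })
  })
}

#' Simulation configuration for a split-differentiation experiment
#'
#' Bundles and validates the knobs of [simulate_clonal_differentiation()].
#' Defaults describe a transduction of 4000 hiPS cells at MOI 0.04, three
#' population doublings before an even split into two parallel
#' differentiations, four doublings after, and 14 expression clusters.
#'
#' @param n_cells Founder cells exposed to virus.
#' @param moi Poisson mean lentiviral integrations per cell.
#' @param n_divisions_pre_split Doublings between transduction and the split.
#' @param n_divisions_post_split Doublings after the split (applied to
#'   surviving cells).
#' @param n_clusters Number of expression clusters.
#' @param pool_cluster_weights Population-level cluster probabilities
#'   (default uniform); must sum to 1.
#' @param memory_concentration Dirichlet concentration for clone fate
#'   distributions: each clone draws its fate distribution from
#'   `Dirichlet(memory_concentration * pool_cluster_weights)`. Small values
#'   give strong clonal fate memory (each clone concentrates in one or a few
#'   clusters); large values make every clone's fate distribution approach
#'   the pool weights (no memory). The default of 3 over 14 uniform clusters
#'   gives per-cluster concentration ~0.2, i.e. clones spread over a
#'   handful of clusters, the regime the fate-homogeneity test is built
#'   to detect.
#' @param priming_mode If `TRUE`, a clone's fate distribution is drawn once
#'   and shared by both splits (heritable priming); if `FALSE`, each split
#'   draws its own.
#' @param survival_mode `"independent"`: each cell survives differentiation
#'   with probability `loss_coefficient` independently. `"heritable"`: one
#'   Bernoulli per clone decides survival of all its members.
#' @param loss_coefficient Survival probability in `[0, 1]`.
#' @param read_error_rate Per-base substitution probability used by
#'   [simulate_reads()].
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 4000L,
                       moi = 0.04,
                       n_divisions_pre_split = 3L,
                       n_divisions_post_split = 4L,
                       n_clusters = 14L,
                       pool_cluster_weights = NULL,
                       memory_concentration = 3,
                       priming_mode = TRUE,
                       survival_mode = c("independent", "heritable"),
                       loss_coefficient = 0.5,
                       read_error_rate = 0.005,
                       seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  n_clusters <- check_count(n_clusters, "n_clusters")
  n_divisions_pre_split <- check_count(n_divisions_pre_split,
                                       "n_divisions_pre_split", min = 0L)
  n_divisions_post_split <- check_count(n_divisions_post_split,
                                        "n_divisions_post_split", min = 0L)
  if (is.null(pool_cluster_weights)) {
    pool_cluster_weights <- rep(1 / n_clusters, n_clusters)
  }
  if (length(pool_cluster_weights) != n_clusters ||
      any(pool_cluster_weights < 0) ||
      abs(sum(pool_cluster_weights) - 1) > 1e-8) {
    stop("`pool_cluster_weights` must be a probability vector of length ",
         n_clusters)
  }
  if (!is.numeric(moi) || moi < 0) stop("`moi` must be >= 0")
  if (!is.numeric(memory_concentration) || memory_concentration <= 0) {
    stop("`memory_concentration` must be > 0")
  }
  stopifnot_scalar_prob(loss_coefficient, "loss_coefficient")
  stopifnot_scalar_prob(read_error_rate, "read_error_rate")
  structure(list(
    n_cells = n_cells,
    moi = moi,
    n_divisions_pre_split = n_divisions_pre_split,
    n_divisions_post_split = n_divisions_post_split,
    n_clusters = n_clusters,
    pool_cluster_weights = pool_cluster_weights,
    memory_concentration = memory_concentration,
    priming_mode = isTRUE(priming_mode),
    survival_mode = match.arg(survival_mode),
    loss_coefficient = loss_coefficient,
    read_error_rate = read_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate clonal expansion, splitting, survival and differentiation
#'
#' Founder cells are transduced (Poisson at `config$moi`), expand
#' `2^n_divisions_pre_split`-fold, and their progeny are allocated to splits
#' A and B by a fair binomial. Cells then survive differentiation either
#' independently (per-cell Bernoulli at `loss_coefficient`) or as whole
#' clones (one Bernoulli per clone). Survivors expand
#' `2^n_divisions_post_split`-fold, and every surviving cell draws an
#' expression-cluster label from its clone's fate distribution — shared
#' across the splits when `priming_mode` is on, drawn per split otherwise.
#' Unbarcoded founders follow the same demography with cluster labels drawn
#' from the pool weights.
#'
#' @param config A [sim_config()].
#' @param library Optional `barcode_library`; generated from the config seed
#'   when omitted.
#' @return An object of class `clone_truth`: list with
#'   \describe{
#'     \item{cells}{data.frame with one row per final cell: `cell_id`
#'       (16-nt sequence), `split` ("A"/"B"), `barcode_id` (semicolon-joined
#'       library names, `NA` for unbarcoded), `founder`, `cluster`
#'       (`cluster01`...; `NA` for dead cells), `survived` (logical).}
#'     \item{fates}{data.frame of clone fate distributions, one row per
#'       (barcode, split, cluster): columns `barcode_id`, `split`,
#'       `cluster`, `prob`.}
#'     \item{library}{the `barcode_library` used.}
#'     \item{config}{the input config.}
#'   }
#' @export
simulate_clonal_differentiation <- function(config, library = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_clusters < 1L || length(config$pool_cluster_weights) == 0L) {
    stop("degenerate config: need at least one cluster with weights")
  }
  if (is.null(library)) {
    n_lib <- max(1000L, ceiling(config$n_cells * config$moi * 3))
    library <- generate_barcode_library(n_lib,
                                        seed = stage_seed(config$seed, "library"))
  }
  clusters <- sprintf("cluster%02d", seq_len(config$n_clusters))
  alpha0 <- config$memory_concentration * config$pool_cluster_weights

  local_seed(stage_seed(config$seed, "differentiation"), {
    integ <- simulate_transduction(config$n_cells, config$moi, library,
                                   seed = stage_seed(config$seed, "transduction"))
    n_barcodes <- lengths(integ)
    founders <- seq_len(config$n_cells)
    barcode_id <- vapply(integ, function(ix) {
      if (length(ix) == 0L) NA_character_ else
        paste(names(library$sequences)[sort(ix)], collapse = ";")
    }, character(1))

    clone_size_pre <- 2L^config$n_divisions_pre_split
    expansion_post <- 2L^config$n_divisions_post_split

    # per-founder fate distributions (priming on: one draw shared by splits)
    draw_fate <- function() rdirichlet1(alpha0)
    fate_A <- lapply(founders, function(i) draw_fate())
    fate_B <- if (config$priming_mode) fate_A else
      lapply(founders, function(i) draw_fate())
    # unbarcoded cells sample from the pool weights, not a clone memory
    unbarcoded <- n_barcodes == 0L
    fate_A[unbarcoded] <- list(config$pool_cluster_weights)
    fate_B[unbarcoded] <- list(config$pool_cluster_weights)

    clone_survival <- rbinom(config$n_cells, 1L, config$loss_coefficient) == 1L

    rows <- vector("list", config$n_cells)
    for (i in founders) {
      n_a <- rbinom(1L, clone_size_pre, 0.5)
      n_b <- clone_size_pre - n_a
      per_split <- function(n_split, split, fate) {
        if (n_split == 0L) return(NULL)
        survived <- if (config$survival_mode == "independent" || unbarcoded[i]) {
          rbinom(n_split, 1L, config$loss_coefficient) == 1L
        } else {
          rep(clone_survival[i], n_split)
        }
        n_alive <- sum(survived)
        n_final <- n_alive * expansion_post
        cl <- if (n_final > 0L) {
          clusters[sample.int(config$n_clusters, n_final, replace = TRUE,
                              prob = fate)]
        } else character(0)
        data.frame(
          split = split,
          barcode_id = barcode_id[i],
          founder = i,
          cluster = c(cl, rep(NA_character_, n_split - n_alive)),
          survived = c(rep(TRUE, n_final), rep(FALSE, n_split - n_alive)),
          stringsAsFactors = FALSE
        )
      }
      rows[[i]] <- rbind(per_split(n_a, "A", fate_A[[i]]),
                         per_split(n_b, "B", fate_B[[i]]))
    }
    cells <- do.call(rbind, rows)
    cells$cell_id <- random_dna(nrow(cells), 16L)
    while (anyDuplicated(cells$cell_id)) {
      dup <- duplicated(cells$cell_id)
      cells$cell_id[dup] <- random_dna(sum(dup), 16L)
    }
    cells <- cells[, c("cell_id", "split", "barcode_id", "founder",
                       "cluster", "survived")]

    barcoded <- founders[!unbarcoded]
    # a barcode can hit two founders (as in a real library, where diversity
    # only makes this improbable, not impossible); keep the first founding
    # clone's fate rows so (barcode, split) keys are unique
    seen <- character(0)
    fates <- do.call(rbind, lapply(barcoded, function(i) {
      ids <- strsplit(barcode_id[i], ";", fixed = TRUE)[[1]]
      ids <- setdiff(ids, seen)
      seen <<- c(seen, ids)
      if (length(ids) == 0L) return(NULL)
      do.call(rbind, lapply(ids, function(b) {
        rbind(
          data.frame(barcode_id = b, split = "A", cluster = clusters,
                     prob = fate_A[[i]], stringsAsFactors = FALSE),
          data.frame(barcode_id = b, split = "B", cluster = clusters,
                     prob = fate_B[[i]], stringsAsFactors = FALSE)
        )
      }))
    }))

    structure(list(cells = cells, fates = fates, library = library,
                   config = config),
              class = "clone_truth")
  })
}

DEFAULT_ANCHOR <- "CTAGCATCGGTACCTAACGG"  # constant amplicon anchor 5' of the barcode

#' Default amplicon anchor sequence
#'
#' The constant 20-nt sequence placed immediately 5' of the lineage barcode
#' in simulated reads, standing in for the primer-adjacent constant region
#' that real amplicon reads carry.
#' @return A length-1 character vector.
#' @export
default_anchor <- function() DEFAULT_ANCHOR

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs, "", fixed = TRUE)
  widths <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < error_rate
  if (any(hit)) {
    # substitute with one of the three other bases, uniformly
    cur <- flat[hit]
    repl <- bases[(match(cur, bases) - 1L + sample.int(3L, sum(hit),
                                                       replace = TRUE)) %% 4L + 1L]
    flat[hit] <- repl
  }
  vapply(split(flat, rep(seq_along(widths), widths)), paste0, character(1),
         collapse = "", USE.NAMES = FALSE)
}

#' Simulate barcode amplicon reads from a simulated experiment
#'
#' Writes gzipped FASTQ files plus companion truth tables for one or both
#' splits of a `clone_truth` object.
#'
#' In `"10x"` mode each read is laid out as 16-nt cell identifier, 12-nt
#' UMI, the constant anchor, then the 100-nt barcode (mirroring a 10X v3
#' side-reaction amplicon). Each surviving barcoded cell yields a Poisson
#' number of distinct UMIs (at least one) per integrated barcode and
#' `reads_per_umi` reads per UMI. In `"gdna"` mode each read is a 6-nt
#' pseudo-UMI with pattern NHNNNN (H = A/C/T at position 2), the anchor, and
#' the barcode; every surviving barcoded cell contributes
#' `gdna_umis_per_cell` pseudo-UMIs. Substitution errors are applied
#' independently to every base of every read at `error_rate`.
#'
#' @param truth A `clone_truth` from [simulate_clonal_differentiation()].
#' @param out_dir Output directory (created if missing).
#' @param mode `"10x"` or `"gdna"`.
#' @param error_rate Per-base substitution probability; defaults to the
#'   config's `read_error_rate`.
#' @param splits Which splits to emit (default both).
#' @param mean_umis_per_cell Mean distinct UMIs per (cell, barcode) in 10x
#'   mode (Poisson, floored at 1).
#' @param reads_per_umi Reads sequenced per UMI.
#' @param gdna_umis_per_cell Pseudo-UMIs contributed per cell in gdna mode.
#' @param anchor Anchor sequence inserted 5' of the barcode.
#' @param seed Integer seed.
#' @return Invisibly, a list with `fastq` (named vector of file paths per
#'   split), `truth_cells` (path to the cell truth TSV) and `read_truth`
#'   (data.frame of per-read ground truth).
#' @export
simulate_reads <- function(truth, out_dir,
                           mode = c("10x", "gdna"),
                           error_rate = NULL,
                           splits = c("A", "B"),
                           mean_umis_per_cell = 6,
                           reads_per_umi = 3L,
                           gdna_umis_per_cell = 2L,
                           anchor = default_anchor(),
                           seed = 1L) {
  stopifnot(inherits(truth, "clone_truth"))
  mode <- match.arg(mode)
  if (is.null(error_rate)) error_rate <- truth$config$read_error_rate
  if (error_rate < 0 || error_rate >= 1) stop("`error_rate` must be in [0, 1)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lib <- truth$library$sequences
  cells <- truth$cells
  alive <- cells[cells$survived & !is.na(cells$barcode_id) &
                   cells$split %in% splits, , drop = FALSE]

  fastq_paths <- character(0)
  read_truth <- list()
  local_seed(seed, {
    for (sp in splits) {
      sub <- alive[alive$split == sp, , drop = FALSE]
      ids <- character(0); seqs <- character(0)
      tr <- list()
      if (nrow(sub) > 0L) {
        for (r in seq_len(nrow(sub))) {
          bcs <- strsplit(sub$barcode_id[r], ";", fixed = TRUE)[[1]]
          for (b in bcs) {
            bc_seq <- lib[[b]]
            if (mode == "10x") {
              n_umi <- max(1L, rpois(1L, mean_umis_per_cell))
              umis <- random_dna(n_umi, 12L)
              while (anyDuplicated(umis)) {
                umis[duplicated(umis)] <- random_dna(sum(duplicated(umis)), 12L)
              }
              payload <- paste0(sub$cell_id[r], rep(umis, each = reads_per_umi),
                                anchor, bc_seq)
              tr[[length(tr) + 1L]] <- data.frame(
                cell_id = sub$cell_id[r], split = sp, barcode_id = b,
                umi = rep(umis, each = reads_per_umi),
                stringsAsFactors = FALSE)
            } else {
              n_umi <- gdna_umis_per_cell
              umis <- paste0(
                random_dna(n_umi, 1L),
                random_dna(n_umi, 1L, alphabet = c("A", "C", "T")),
                random_dna(n_umi, 4L))
              payload <- paste0(rep(umis, each = reads_per_umi), anchor, bc_seq)
              tr[[length(tr) + 1L]] <- data.frame(
                cell_id = sub$cell_id[r], split = sp, barcode_id = b,
                umi = rep(umis, each = reads_per_umi),
                stringsAsFactors = FALSE)
            }
            seqs <- c(seqs, payload)
          }
        }
      }
      seqs <- apply_substitutions(seqs, error_rate)
      ids <- sprintf("read_%s_%06d", sp, seq_along(seqs))
      path <- file.path(out_dir, sprintf("reads_%s_%s.fastq.gz", mode, sp))
      write_fastq(data.frame(id = ids, seq = seqs,
                             qual = strrep("F", nchar(seqs)),
                             stringsAsFactors = FALSE), path)
      fastq_paths[sp] <- path
      read_truth[[sp]] <- if (length(tr)) do.call(rbind, tr) else NULL
    }
  })

  truth_path <- file.path(out_dir, "truth_cells.tsv")
  write_tsv(cells[, c("cell_id", "split", "barcode_id", "cluster", "survived")],
            truth_path)
  invisible(list(fastq = fastq_paths, truth_cells = truth_path,
                 read_truth = do.call(rbind, read_truth)))
}
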