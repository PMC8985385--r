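# End-to-end orchestration: a validated configuration object, a run
# function chaining recovery -> assignment -> clonal statistics ->
# split-survival analysis, and a run manifest recording counts, drop
# reasons and checksums for every stage.

PIPELINE_FIELDS <- c("seed", "out_dir", "simulate", "inputs", "recover",
                     "assign", "stats", "split_compare", "survival")

#' Build and validate a pipeline configuration
#'
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   stable hashing of stage names, so each stage is reproducible
#'   independently of execution order.
#' @param out_dir Output directory for all artifacts.
#' @param simulate `NULL`, or a named list of [sim_config()] arguments; when
#'   given, the synthetic generator produces the pipeline inputs.
#' @param inputs `NULL`, or a named list with `fastq_A`, `fastq_B` (paths),
#'   and `clusters` (path to a TSV with `cell_id`, `cluster`). Exactly one
#'   of `simulate` / `inputs` must be supplied.
#' @param recover Named list of overrides for the recovery stage: `anchor`,
#'   `max_dist`, `prefix_len`, `min_quality`, `max_homopolymer`.
#' @param assign Overrides: `min_umi`, `dominance_fraction`.
#' @param stats Overrides: `min_cells`, `n_samples`, `exclude_clusters`.
#' @param split_compare Overrides: `min_cells_per_split`.
#' @param survival Overrides: `n_simulations`, `presence_threshold`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("clonefate_run_"),
                            simulate = NULL, inputs = NULL,
                            recover = list(), assign = list(),
                            stats = list(), split_compare = list(),
                            survival = list()) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("supply exactly one of `simulate` or `inputs`")
  }
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
    }
  }
  check_keys(recover, c("anchor", "max_dist", "prefix_len", "min_quality",
                        "max_homopolymer"), "recover")
  check_keys(assign, c("min_umi", "dominance_fraction"), "assign")
  check_keys(stats, c("min_cells", "n_samples", "exclude_clusters"), "stats")
  check_keys(split_compare, "min_cells_per_split", "split_compare")
  check_keys(survival, c("n_simulations", "presence_threshold"), "survival")
  if (!is.null(simulate)) {
    check_keys(simulate, setdiff(names(formals(sim_config)), "seed"),
               "simulate")
  }
  if (!is.null(inputs)) {
    check_keys(inputs, c("fastq_A", "fastq_B", "clusters"), "inputs")
    missing <- setdiff(c("fastq_A", "fastq_B", "clusters"), names(inputs))
    if (length(missing)) {
      stop("inputs must name: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, inputs = inputs, recover = recover,
                 assign = assign, stats = stats,
                 split_compare = split_compare, survival = survival),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly; unknown keys are rejected on read.
#'
#' @param config A `pipeline_config`.
#' @param path File path (`.yaml`/`.yml`).
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  bad <- setdiff(names(x), PIPELINE_FIELDS)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

default_arg <- function(overrides, name, default) {
  if (name %in% names(overrides)) overrides[[name]] else default
}

#' Run the full clonal-barcode analysis pipeline
#'
#' Executes, in order: (optional) synthetic-data generation, barcode
#' recovery and cell assignment per split, within-split clonal
#' fate-homogeneity tests, cross-split pairwise JSD, per-split abundance
#' table, and the split-survival randomness test (with the loss coefficient
#' calibrated to the observed survival proportion when initial abundances
#' are available). All artifacts are written under `config$out_dir` and
#' summarized in a run manifest (JSON). The same config and seed reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "clonefate",
    version = as.character(utils::packageVersion("clonefate")),
    seed = config$seed,
    stages = list()
  )

  # --- stage: inputs ------------------------------------------------------
  initial_abundance <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, c(config$simulate,
                                 list(seed = stage_seed(config$seed, "simulate"))))
    truth <- simulate_clonal_differentiation(cfg)
    reads <- simulate_reads(truth, file.path(out, "inputs"), mode = "10x",
                            seed = stage_seed(config$seed, "reads"))
    fastq <- reads$fastq
    alive <- truth$cells[truth$cells$survived, ]
    clusters_df <- alive[, c("cell_id", "cluster")]
    write_tsv(clusters_df, file.path(out, "inputs", "clusters.tsv"))
    # initial abundance at split time: progeny count per barcode before
    # loss. Dead cells are single rows; survivors appear expanded
    # 2^post-fold, so scale their row count back down.
    bc_rows <- truth$cells[!is.na(truth$cells$barcode_id), ]
    expand_post <- 2L^cfg$n_divisions_post_split
    w <- ifelse(bc_rows$survived, 1 / expand_post, 1)
    bcs <- strsplit(bc_rows$barcode_id, ";", fixed = TRUE)
    pre <- tapply(rep(w, lengths(bcs)), unlist(bcs), sum)
    initial_abundance <- stats::setNames(as.integer(round(pre)), names(pre))
    initial_abundance <- initial_abundance[initial_abundance >= 1L]
    manifest$stages$simulate <- list(
      n_cells = nrow(truth$cells),
      n_barcoded_cells = sum(!is.na(truth$cells$barcode_id)),
      n_barcodes = length(initial_abundance))
  } else {
    for (p in unlist(config$inputs)) {
      if (!file.exists(p)) stop("input not found: ", p)
    }
    fastq <- c(A = config$inputs$fastq_A, B = config$inputs$fastq_B)
    clusters_df <- read_table_checked(config$inputs$clusters,
                                      c("cell_id", "cluster"))
  }
  manifest$inputs <- lapply(as.list(fastq), function(p)
    unname(tools::md5sum(p)))

  # --- stage: recovery + assignment per split -----------------------------
  rc <- config$recover
  anchor <- default_arg(rc, "anchor", default_anchor())
  tables <- list()
  for (sp in c("A", "B")) {
    ext <- extract_barcodes(
      fastq[[sp]], anchor = anchor, mode = "10x",
      min_quality = default_arg(rc, "min_quality", 30),
      max_homopolymer = default_arg(rc, "max_homopolymer", 6L))
    catalog <- merge_barcodes(
      ext, prefix_len = default_arg(rc, "prefix_len", 30L),
      max_dist = default_arg(rc, "max_dist", 6L))
    umis <- cell_umi_table(ext, catalog)
    asg <- assign_cells(
      umis,
      min_umi = default_arg(config$assign, "min_umi", 2L),
      dominance_fraction = default_arg(config$assign, "dominance_fraction",
                                       0.30))
    write_tsv(catalog$entries, file.path(out, sprintf("catalog_%s.tsv", sp)))
    write_tsv(asg$table, file.path(out, sprintf("assignments_%s.tsv", sp)))
    manifest$stages[[paste0("recover_", sp)]] <- list(
      reads_in = sum(ext$drops) + nrow(ext$records),
      records = nrow(ext$records),
      drops = as.list(ext$drops),
      catalog_entries = nrow(catalog$entries))
    manifest$stages[[paste0("assign_", sp)]] <- list(
      cells_in = length(unique(umis$cell_id)),
      cells_assigned = nrow(asg$table),
      drops = as.list(asg$drops))
    tables[[sp]] <- asg$table
  }

  # --- stage: clonal statistics -------------------------------------------
  st <- config$stats
  min_cells <- default_arg(st, "min_cells", 20L)
  n_samples <- default_arg(st, "n_samples", 1000L)
  excl <- default_arg(st, "exclude_clusters", NULL)
  clone_stats <- list()
  for (sp in c("A", "B")) {
    res <- clone_jsd_table(tables[[sp]], clusters_df, min_cells = min_cells,
                           n_samples = n_samples,
                           seed = stage_seed(config$seed, paste0("stats_", sp)),
                           exclude_clusters = excl)
    write_tsv(res, file.path(out, sprintf("clone_jsd_%s.tsv", sp)))
    clone_stats[[sp]] <- res
    manifest$stages[[paste0("clone_stats_", sp)]] <- list(
      clones_tested = nrow(res),
      clones_significant = sum(res$p_value < 0.05))
  }

  # --- stage: cross-split comparison --------------------------------------
  mk_cells <- function(tab) merge(tab, clusters_df, by = "cell_id")
  min_split <- default_arg(config$split_compare, "min_cells_per_split", 5L)
  xs <- tryCatch(
    cross_split_jsd(mk_cells(tables$A), mk_cells(tables$B),
                    min_cells_per_split = min_split,
                    exclude_clusters = excl),
    error = function(e) NULL)
  if (!is.null(xs)) {
    utils::write.csv(xs$matrix, file.path(out, "cross_split_jsd.csv"))
    manifest$stages$split_compare <- list(
      shared_barcodes = length(xs$barcodes),
      diag_mean = xs$diag_mean, offdiag_mean = xs$offdiag_mean)
  }
  abund <- split_abundance_table(tables$A, tables$B)
  write_tsv(abund, file.path(out, "split_abundance.tsv"))

  # --- stage: survival simulation -----------------------------------------
  if (!is.null(initial_abundance)) {
    sv <- config$survival
    set_A <- unique(tables$A$barcode)
    set_B <- unique(tables$B$barcode)
    # map recovered representatives back onto library barcode names where
    # the simulator provided truth
    seq_to_id <- stats::setNames(names(truth$library$sequences),
                                 unname(truth$library$sequences))
    set_A <- unname(seq_to_id[set_A]); set_A <- set_A[!is.na(set_A)]
    set_B <- unname(seq_to_id[set_B]); set_B <- set_B[!is.na(set_B)]
    obs_surv <- mean(c(length(intersect(set_A, names(initial_abundance))),
                       length(intersect(set_B, names(initial_abundance))))) /
      length(initial_abundance)
    if (obs_surv > 0) {
      cal <- calibrate_loss(initial_abundance, obs_surv,
                            presence_threshold = default_arg(sv, "presence_threshold", 1L))
      tst <- survival_randomness_test(
        initial_abundance, set_A, set_B, s = cal$s,
        n_simulations = default_arg(sv, "n_simulations", 1000L),
        presence_threshold = default_arg(sv, "presence_threshold", 1L),
        seed = stage_seed(config$seed, "survival"))
      jsonlite::write_json(
        list(s = cal$s, observed = tst$observed,
             quantile_A = tst$quantile_A, quantile_B = tst$quantile_B,
             flagged = tst$flagged),
        file.path(out, "survival_test.json"), auto_unbox = TRUE, digits = NA)
      manifest$stages$survival <- list(
        calibrated_s = cal$s, flagged = tst$flagged,
        quantile_A = tst$quantile_A, quantile_B = tst$quantile_B)
    }
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null")
  manifest$config_hash <- unname(tools::md5sum(
    local({f <- tempfile(); writeLines(cfg_json, f); f})))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
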