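#' Default pipeline run configuration
#'
#' Returns the full set of pipeline parameters with their defaults: grouping
#' distance 500 bp, promoter window 1000 bp, reciprocal overlap fraction
#' 0.5, 5-fold CV, 1000 null replicates, and the synthetic-study defaults
#' for the `simulate` stage.  Input paths default to the files the
#' `simulate` stage writes under `<outdir>/sim`; point them at real data to
#' skip simulation.  All coordinates are 0-based half-open (BED convention).
#'
#' @return A named list of parameters.
#' @export
default_run_config <- function() {
  list(outdir = "crmx_out", seed = 1L,
       max_gap = 500, tss_window = 1000, overlap_frac = 0.5,
       cv_folds = 5, null_B = 1000, dissim_B = 200, alpha = 0.05,
       de_threshold = 1, basis_cap = 8,
       target_cell_type = NULL, de_cell_a = NULL, de_cell_b = NULL,
       simulate = list(),
       peaks_a = NULL, peaks_b = NULL, annotation = NULL,
       tf_expression = NULL, gene_expression = NULL, replicate_map = NULL,
       motif = NULL, expressed = NULL)
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override [default_run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A named list of parameters.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- utils::modifyList(default_run_config(), config)
  config
}

sim_dir <- function(cfg) file.path(cfg$outdir, "sim")

input_path <- function(cfg, key, sim_file) {
  if (!is.null(cfg[[key]])) cfg[[key]] else file.path(sim_dir(cfg), sim_file)
}

peak_paths <- function(cfg, line = c("a", "b")) {
  line <- match.arg(line)
  key <- paste0("peaks_", line)
  if (!is.null(cfg[[key]])) return(unlist(cfg[[key]]))
  files <- dir(sim_dir(cfg), pattern = paste0("^peaks_", toupper(line),
                                              "_.*\\.bed$"),
               full.names = TRUE)
  stats::setNames(files, sub("^peaks_._(.*)\\.bed$", "\\1", basename(files)))
}

require_stage <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input(s) ", paste(missing, collapse = ", "),
         ": run stage '", stage, "' first", call. = FALSE)
}

log_line <- function(cfg, ...) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n", sep = "",
      file = file.path(cfg$outdir, "crmx.log"), append = TRUE)
}

read_crm_table <- function(bed_path, sites_path) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
  crms <- data.frame(crm_id = bed$V4, chrom = bed$V1, start = bed$V2,
                     end = bed$V3 - 1L,
                     center = (bed$V2 + bed$V3 - 1L) %/% 2L,
                     n_sites = NA_integer_, n_tfs = bed$V5, tfs = bed$V6,
                     stringsAsFactors = FALSE)
  sites <- utils::read.table(sites_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  crms$n_sites <- as.integer(table(sites$crm_id)[crms$crm_id])
  attr(crms, "sites") <- sites
  crms
}

write_crm_outputs <- function(crms, dir, line) {
  write_crms(crms, file.path(dir, sprintf("crms_%s.bed", line)))
  utils::write.table(attr(crms, "sites"),
                     file.path(dir, sprintf("crms_%s_sites.tsv", line)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

load_expression_inputs <- function(cfg) {
  tf_p <- input_path(cfg, "tf_expression", "tf_expression.tsv")
  g_p <- input_path(cfg, "gene_expression", "gene_expression.tsv")
  rm_p <- input_path(cfg, "replicate_map", "replicate_map.tsv")
  require_stage(c(tf_p, g_p, rm_p), "simulate")
  list(tf = mean_center(read_expression(tf_p, rm_p)),
       gene = mean_center(read_expression(g_p, rm_p)))
}

#' Run one pipeline stage
#'
#' Stages, in dependency order: `simulate` (write a synthetic fixture
#' bundle), `detect-crms`, `map-genes`, `combos`, `fit`, `evaluate`,
#' `nulls`, `compare`, `report`.  Each stage reads its inputs from the
#' configured paths (defaulting to the simulate stage's bundle), writes
#' TSV/BED outputs under `<outdir>/<stage>` and appends to
#' `<outdir>/crmx.log`.  The resolved configuration is written beside the
#' outputs for provenance.  Outputs are byte-identical across re-runs with
#' identical configuration and seeds (the log carries the timestamps).
#'
#' @param stage_name one of the stage names above.
#' @param config a configuration list (see [default_run_config()]) or the
#'   path to a YAML file.
#' @return Named character vector of the stage's output paths, invisibly.
#' @export
run_stage <- function(stage_name, config) {
  cfg <- resolve_config(config)
  stages <- c("simulate", "detect-crms", "map-genes", "combos", "fit",
              "evaluate", "nulls", "compare", "report")
  if (!stage_name %in% stages)
    stop("unknown stage '", stage_name, "'; stages: ",
         paste(stages, collapse = ", "))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)],
                   file.path(cfg$outdir, "config_used.yaml"))
  log_line(cfg, "stage ", stage_name, " seed=", cfg$seed,
           " crmx=", as.character(utils::packageVersion("crmx")))
  fn <- switch(stage_name,
               "simulate" = stage_simulate, "detect-crms" = stage_detect,
               "map-genes" = stage_map, "combos" = stage_combos,
               "fit" = stage_fit, "evaluate" = stage_evaluate,
               "nulls" = stage_nulls, "compare" = stage_compare,
               "report" = stage_report)
  out <- fn(cfg)
  log_line(cfg, "stage ", stage_name, " done: ",
           paste(basename(out), collapse = ", "))
  invisible(out)
}

stage_simulate <- function(cfg) {
  sc <- do.call(simulation_config,
                utils::modifyList(list(seed = cfg$seed), cfg$simulate))
  make_fixture_bundle(sc, sim_dir(cfg), force = TRUE)
}

stage_detect <- function(cfg) {
  dir <- file.path(cfg$outdir, "crms")
  dir.create(dir, showWarnings = FALSE)
  out <- c()
  for (line in c("A", "B")) {
    pp <- peak_paths(cfg, tolower(line))
    if (!length(pp)) {
      if (line == "B") next
      stop("no peak files found: run stage 'simulate' first or set peaks_a",
           call. = FALSE)
    }
    require_stage(pp, "simulate")
    peaks <- lapply(names(pp), function(tf) read_peaks(pp[[tf]], tf))
    crms <- detect_crms(peaks, max_gap = cfg$max_gap)
    write_crm_outputs(crms, dir, line)
    out <- c(out, file.path(dir, sprintf("crms_%s.bed", line)))
  }
  out
}

stage_map <- function(cfg) {
  dir <- file.path(cfg$outdir, "links")
  dir.create(dir, showWarnings = FALSE)
  ann_p <- input_path(cfg, "annotation", "annotation.bed")
  require_stage(ann_p, "simulate")
  ann <- read_annotation(ann_p)
  out <- c()
  for (line in c("A", "B")) {
    bed <- file.path(cfg$outdir, "crms", sprintf("crms_%s.bed", line))
    if (line == "B" && !file.exists(bed)) next
    require_stage(bed, "detect-crms")
    crms <- read_crm_table(bed, sub("\\.bed$", "_sites.tsv", bed))
    links <- map_crms_to_genes(crms, ann, window = cfg$tss_window)
    p <- file.path(dir, sprintf("links_%s.tsv", line))
    utils::write.table(links, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, p)
  }
  out
}

stage_combos <- function(cfg) {
  dir <- file.path(cfg$outdir, "combos")
  dir.create(dir, showWarnings = FALSE)
  bed <- file.path(cfg$outdir, "crms", "crms_A.bed")
  require_stage(bed, "detect-crms")
  crms <- read_crm_table(bed, sub("\\.bed$", "_sites.tsv", bed))
  stats <- combination_significance(crms, B = cfg$null_B, seed = cfg$seed)
  p <- file.path(dir, "combination_significance.tsv")
  utils::write.table(stats, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

pipeline_specs <- function(cfg, expr) {
  bed <- file.path(cfg$outdir, "crms", "crms_A.bed")
  links_p <- file.path(cfg$outdir, "links", "links_A.tsv")
  require_stage(bed, "detect-crms")
  require_stage(links_p, "map-genes")
  crms <- read_crm_table(bed, sub("\\.bed$", "_sites.tsv", bed))
  links <- utils::read.table(links_p, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  links <- links[links$gene_id %in% features(expr$gene), , drop = FALSE]
  build_model_specs(links, crms, expr$tf)
}

stage_fit <- function(cfg) {
  dir <- file.path(cfg$outdir, "fit")
  dir.create(dir, showWarnings = FALSE)
  expr <- load_expression_inputs(cfg)
  specs <- pipeline_specs(cfg, expr)
  folds <- make_folds(expr$gene, cfg$cv_folds, cfg$seed)
  basis <- make_tf_basis(expr$tf, basis_cap = cfg$basis_cap)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    cv <- kfold_cv(specs[i, ], expr$tf, expr$gene, folds = folds,
                   basis_cap = cfg$basis_cap, basis = basis)
    nl <- nonlinearity_test(specs[i, ], expr$tf, expr$gene,
                            basis_cap = cfg$basis_cap)
    data.frame(specs[i, ], mean_r2 = cv$mean_r2,
               nonlin_p = nl$p_value, nonlinear = nl$nonlinear,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p <- file.path(dir, "gene_cv.tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_evaluate <- function(cfg) {
  dir <- file.path(cfg$outdir, "evaluate")
  dir.create(dir, showWarnings = FALSE)
  expr <- load_expression_inputs(cfg)
  specs <- pipeline_specs(cfg, expr)
  ct <- loocv_by_celltype(specs, expr$tf, expr$gene,
                          basis_cap = cfg$basis_cap)
  p <- file.path(dir, "celltype_r2.tsv")
  utils::write.table(ct, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_nulls <- function(cfg) {
  dir <- file.path(cfg$outdir, "nulls")
  dir.create(dir, showWarnings = FALSE)
  expr <- load_expression_inputs(cfg)
  specs <- pipeline_specs(cfg, expr)
  require_stage(file.path(cfg$outdir, "fit", "gene_cv.tsv"), "fit")
  out <- c()
  ns <- null_spec("pool14", pool = features(expr$tf), B = cfg$null_B,
                  seed = cfg$seed)
  bat <- run_null_battery(specs, expr$tf, expr$gene, ns, k = cfg$cv_folds,
                          cv_seed = cfg$seed, basis_cap = cfg$basis_cap)
  p <- file.path(dir, "nulls_pool14.tsv")
  utils::write.table(bat, p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, p)
  motif_p <- input_path(cfg, "motif", "motif_table.tsv")
  expr_p <- input_path(cfg, "expressed", "expressed_tfs.tsv")
  if (file.exists(motif_p) && file.exists(expr_p)) {
    motif <- utils::read.table(motif_p, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    ex <- utils::read.table(expr_p, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cons <- motif_constraint(motif,
                             stats::setNames(as.logical(ex$expressed),
                                             ex$tf))
    pool <- sort(unique(c(features(expr$tf), motif$tf)))
    ns2 <- null_spec("motif41", pool = pool, B = cfg$null_B,
                     seed = cfg$seed + 1L)
    bat2 <- run_null_battery(specs, expr$tf, expr$gene, ns2,
                             constraints = cons, k = cfg$cv_folds,
                             cv_seed = cfg$seed, basis_cap = cfg$basis_cap)
    p2 <- file.path(dir, "nulls_motif41.tsv")
    utils::write.table(bat2, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, p2)
  }
  out
}

stage_compare <- function(cfg) {
  dir <- file.path(cfg$outdir, "compare")
  dir.create(dir, showWarnings = FALSE)
  beds <- file.path(cfg$outdir, "crms", c("crms_A.bed", "crms_B.bed"))
  require_stage(beds, "detect-crms")
  crms_a <- read_crm_table(beds[1], sub("\\.bed$", "_sites.tsv", beds[1]))
  crms_b <- read_crm_table(beds[2], sub("\\.bed$", "_sites.tsv", beds[2]))
  links_p <- file.path(cfg$outdir, "links", c("links_A.tsv", "links_B.tsv"))
  require_stage(links_p, "map-genes")
  links_a <- utils::read.table(links_p[1], sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  links_b <- utils::read.table(links_p[2], sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  expr <- load_expression_inputs(cfg)
  pairs <- find_overlapping_crms(crms_a, crms_b, min_frac = cfg$overlap_frac)
  out <- c(pairs = file.path(dir, "overlap_pairs.tsv"))
  utils::write.table(pairs, out["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(pairs)) {
    nd <- random_crm_dissimilarity(crms_a, crms_b, pairs, B = cfg$dissim_B,
                                   seed = cfg$seed)
    out["dissim_null"] <- file.path(dir, "dissimilarity_null.tsv")
    utils::write.table(nd, out["dissim_null"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    target <- if (is.null(cfg$target_cell_type))
      cell_types(expr$gene)[1] else cfg$target_cell_type
    dv <- dissimilarity_vs_error(pairs, crms_a, crms_b, links_a,
                                 expr$tf, expr$gene, target,
                                 basis_cap = cfg$basis_cap)
    out["mspe_ratio"] <- file.path(dir, "mspe_ratio_per_pair.tsv")
    utils::write.table(dv$per_pair, out["mspe_ratio"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out["mspe_bins"] <- file.path(dir, "mspe_ratio_bins.tsv")
    utils::write.table(dv$bins, out["mspe_bins"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cts <- cell_types(expr$gene)
  de_a <- if (is.null(cfg$de_cell_a)) cts[1] else cfg$de_cell_a
  de_b <- if (is.null(cfg$de_cell_b)) cts[2] else cfg$de_cell_b
  de <- classify_de(expr$gene, de_a, de_b, threshold = cfg$de_threshold)
  de_genes <- names(de)[de != "unchanged"]
  if (length(de_genes) &&
      all(c("under_expressed", "over_expressed") %in% de)) {
    enr <- de_gene_tf_enrichment(links_a, links_b, crms_a, crms_b, de)
    out["enrichment"] <- file.path(dir, "de_tf_enrichment.tsv")
    utils::write.table(enr, out["enrichment"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    de_links <- rbind(links_a, links_b)
    de_links <- de_links[de_links$gene_id %in% de_genes, , drop = FALSE]
    if (nrow(de_links)) {
      lk <- tryCatch(cluster_tf_cooccurrence(crms_a, crms_b, de_links),
                     error = function(e) NULL)
      if (!is.null(lk)) {
        out["tree"] <- file.path(dir, "tf_cooccurrence.nwk")
        write_newick(lk, out["tree"])
      }
    }
  }
  out
}

stage_report <- function(cfg) {
  write_report(cfg$outdir, cfg)
}

#' Assemble the final report tables
#'
#' Gathers the stage outputs into a report directory: the per-gene table
#' (CV accuracy, bootstrap p, nonlinearity flag), the per-cell-type
#' accuracy table, the dissimilarity-bin table, the DE-gene TF enrichment
#' table and the TF co-occurrence tree.
#'
#' @param outdir the pipeline output directory.
#' @param config optional resolved configuration (for provenance only).
#' @return Named character vector of report paths, invisibly.
#' @export
write_report <- function(outdir, config = NULL) {
  dir <- file.path(outdir, "report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit_p <- file.path(outdir, "fit", "gene_cv.tsv")
  nulls_p <- file.path(outdir, "nulls", "nulls_pool14.tsv")
  require_stage(fit_p, "fit")
  require_stage(nulls_p, "nulls")
  fit <- utils::read.table(fit_p, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  nulls <- utils::read.table(nulls_p, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  per_gene <- merge(fit, nulls[, c("gene_id", "crm_id", "observed_r2",
                                   "p_value", "null_q025", "null_q975")],
                    by = c("gene_id", "crm_id"), all.x = TRUE, sort = TRUE)
  out <- c(per_gene = file.path(dir, "per_gene.tsv"))
  utils::write.table(per_gene, out["per_gene"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  copies <- c(celltype = file.path(outdir, "evaluate", "celltype_r2.tsv"),
              bins = file.path(outdir, "compare", "mspe_ratio_bins.tsv"),
              enrichment = file.path(outdir, "compare",
                                     "de_tf_enrichment.tsv"),
              tree = file.path(outdir, "compare", "tf_cooccurrence.nwk"))
  for (k in names(copies)) {
    if (file.exists(copies[k])) {
      dest <- file.path(dir, basename(copies[k]))
      file.copy(copies[k], dest, overwrite = TRUE)
      out[k] <- dest
    }
  }
  invisible(out)
}
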