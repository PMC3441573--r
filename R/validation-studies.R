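# Self-contained validation studies on synthetic data with known ground
# truth.  Each study builds its own simulated inputs, runs the relevant
# pipeline stages and returns the summary metrics; the test suite asserts
# calibration/power bands on them and scripts/acceptance.R reports them.

#' Planted-CRM recovery and combination enrichment on a default track set
#'
#' Simulates a default genome, detects CRMs from the generated peak tracks
#' and measures the fraction of planted CRMs recovered (a detected CRM on
#' the planted chromosome whose span covers the planted sites and whose TF
#' set contains the planted TFs).
#'
#' @param seed integer seed.
#' @param n_genes number of genes (default 200).
#' @param B permutation replicates for combination significance.
#' @return A list: `recovery_rate`, `n_crms`, `n_combinations`,
#'   `frac_combos_significant` (at p < 0.01).
#' @export
study_crm_recovery <- function(seed, n_genes = 200, B = 200) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes)
  sim <- simulate_genome(cfg)
  crms <- detect_crms(sim$peaks)
  gt <- sim$ground_truth
  planted <- split(gt$planted_sites, gt$planted_sites$gene_id)
  hits <- vapply(planted, function(ps) {
    cand <- crms[crms$chrom == ps$chrom[1] &
                   crms$start <= max(ps$pos) & crms$end >= min(ps$pos), ,
                 drop = FALSE]
    any(vapply(tf_sets(cand), function(ts)
      all(unique(ps$tf) %in% ts), TRUE))
  }, TRUE)
  combos <- combination_significance(crms, B = B, seed = seed + 1L)
  list(recovery_rate = mean(hits), n_crms = nrow(crms),
       n_combinations = nrow(combos),
       frac_combos_significant = mean(combos$p_value < 0.01))
}

# One synthetic expression study panel: genome, detected CRMs, promoter
# links, expression, and one model spec per gene (closest CRM to the TSS).
study_panel <- function(cfg) {
  sim <- simulate_genome(cfg)
  crms <- detect_crms(sim$peaks)
  links <- map_crms_to_genes(crms, sim$annotation)
  expr <- simulate_expression(cfg, sim$ground_truth)
  specs <- build_model_specs(links, crms, expr$tf_matrix)
  specs <- specs[order(specs$gene_id, abs(specs$distance), specs$crm_id), ]
  specs <- specs[!duplicated(specs$gene_id), , drop = FALSE]
  list(sim = sim, crms = crms, links = links, expr = expr, specs = specs)
}

#' Null-model calibration and power of the bootstrap p-value
#'
#' Simulates the default study design (14 TFs, 38 cell types x 2
#' replicates, noise SD 0.5) with half the genes regulated by their planted
#' CRM TFs and half carrying non-functional binding, runs the `pool14` null
#' battery on both groups, and summarizes calibration (the non-functional
#' group) and power (the regulated group).
#'
#' @param seed integer seed.
#' @param n_each genes per group (default 200).
#' @param B null replicates per gene (default 200).
#' @return A list: `frac_sig_unregulated` (bootstrap p < 0.05 among
#'   non-functional genes), `ks_uniform_p` (KS test of p-uniformity),
#'   `frac_sig_regulated`, `wilcoxon_p` (regulated vs non-functional
#'   accuracy), `mean_r2_regulated`, `mean_r2_unregulated`, `n_regulated`,
#'   `n_unregulated`.
#' @export
study_null_calibration <- function(seed, n_each = 200, B = 200) {
  cfg <- simulation_config(seed = seed, n_genes = 2 * n_each)
  panel <- study_panel(cfg)
  gt <- panel$sim$ground_truth$genes
  specs <- panel$specs
  reg <- utils::head(
    specs[specs$gene_id %in% gt$gene_id[gt$regulated], , drop = FALSE],
    n_each)
  unreg <- utils::head(
    specs[specs$gene_id %in% gt$gene_id[!gt$regulated], , drop = FALSE],
    n_each)
  ns <- null_spec("pool14", pool = features(panel$expr$tf_matrix), B = B,
                  seed = seed + 2L)
  bat_u <- run_null_battery(unreg, panel$expr$tf_matrix,
                            panel$expr$gene_matrix, ns,
                            cv_seed = seed + 3L)
  bat_r <- run_null_battery(reg, panel$expr$tf_matrix,
                            panel$expr$gene_matrix, ns,
                            cv_seed = seed + 3L)
  list(frac_sig_unregulated = mean(bat_u$p_value < 0.05),
       ks_uniform_p = suppressWarnings(
         stats::ks.test(bat_u$p_value, "punif")$p.value),
       frac_sig_regulated = mean(bat_r$p_value < 0.05),
       wilcoxon_p = compare_groups(bat_r$observed_r2, bat_u$observed_r2,
                                   "greater"),
       mean_r2_regulated = mean(bat_r$observed_r2),
       mean_r2_unregulated = mean(bat_u$observed_r2),
       n_regulated = nrow(bat_r), n_unregulated = nrow(bat_u))
}

#' Type-I error and power of the nonlinearity test
#'
#' Type-I error: fraction of purely linear-truth regulated genes flagged
#' nonlinear at p < 0.01.  Power: fraction of U-shaped (quadratic) truth
#' genes at low noise flagged at p < 0.01.
#'
#' @param seed integer seed.
#' @param n_type1 linear-truth genes (default 200).
#' @param n_power quadratic-truth genes (default 60).
#' @return A list: `type1_rate`, `power`, `n_type1`, `n_power`.
#' @export
study_nonlinearity <- function(seed, n_type1 = 200, n_power = 60) {
  cfg_lin <- simulation_config(seed = seed, n_genes = 2 * n_type1 + 20,
                               response_library = "linear",
                               fraction_interacting = 0)
  p_lin <- study_panel(cfg_lin)
  gt <- p_lin$sim$ground_truth$genes
  reg <- utils::head(
    p_lin$specs[p_lin$specs$gene_id %in% gt$gene_id[gt$regulated], ,
                drop = FALSE], n_type1)
  p1 <- vapply(seq_len(nrow(reg)), function(i)
    nonlinearity_test(reg[i, ], p_lin$expr$tf_matrix,
                      p_lin$expr$gene_matrix)$p_value, 0)
  cfg_q <- simulation_config(seed = seed + 11L, n_genes = 2 * n_power + 20,
                             response_library = "ushaped",
                             fraction_interacting = 0, noise_sigma = 0.3)
  p_q <- study_panel(cfg_q)
  gtq <- p_q$sim$ground_truth$genes
  regq <- utils::head(
    p_q$specs[p_q$specs$gene_id %in% gtq$gene_id[gtq$regulated], ,
              drop = FALSE], n_power)
  p2 <- vapply(seq_len(nrow(regq)), function(i)
    nonlinearity_test(regq[i, ], p_q$expr$tf_matrix,
                      p_q$expr$gene_matrix)$p_value, 0)
  list(type1_rate = mean(p1 < 0.01), power = mean(p2 < 0.01),
       n_type1 = length(p1), n_power = length(p2))
}

#' Type-I error and power of the TF-TF interaction test
#'
#' Type-I error: fraction of tested TF pairs flagged at p < 0.01 among
#' regulated genes with purely additive truth.  Power: fraction of genes
#' carrying a planted multiplicative pair whose true pair is flagged at
#' p < 0.01.
#'
#' @param seed integer seed.
#' @param n_type1 additive-truth genes (default 200).
#' @param n_power interacting genes (default 60).
#' @return A list: `type1_rate`, `power`, `n_type1_pairs`, `n_power`.
#' @export
study_interaction <- function(seed, n_type1 = 200, n_power = 60) {
  cfg_add <- simulation_config(seed = seed, n_genes = 2 * n_type1 + 20,
                               fraction_interacting = 0)
  p_add <- study_panel(cfg_add)
  gt <- p_add$sim$ground_truth$genes
  reg <- utils::head(
    p_add$specs[p_add$specs$gene_id %in% gt$gene_id[gt$regulated], ,
                drop = FALSE], n_type1)
  p1 <- unlist(lapply(seq_len(nrow(reg)), function(i)
    suppressMessages(
      interaction_test(reg[i, ], p_add$expr$tf_matrix,
                       p_add$expr$gene_matrix))$p_value))
  # power on the canonical case: a two-TF CRM whose pair carries the
  # multiplicative term (larger CRMs dilute the pair's variance share and
  # are reported by the calibration studies instead)
  cfg_int <- simulation_config(seed = seed + 13L, n_genes = 5 * n_power,
                               fraction_interacting = 1,
                               crm_size_probs = c(1, 0, 0))
  p_int <- study_panel(cfg_int)
  gti <- p_int$sim$ground_truth$genes
  with_pair <- gti$gene_id[gti$regulated & gti$interaction != ""]
  regi <- p_int$specs[p_int$specs$gene_id %in% with_pair, , drop = FALSE]
  regi <- utils::head(
    regi[lengths(strsplit(regi$predictors, ",")) == 2, , drop = FALSE],
    n_power)
  # replace the power genes' expression with the canonical purely
  # multiplicative response y = x_A * x_B (unit variance) + noise
  tfm <- p_int$expr$tf_matrix
  gm_vals <- p_int$expr$gene_matrix$values
  x_ct <- p_int$expr$tf_cell_values
  rep_map <- p_int$expr$gene_matrix$replicate_map
  set.seed(seed + 14L)
  for (i in seq_len(nrow(regi))) {
    pair <- sort(strsplit(gti$interaction[gti$gene_id == regi$gene_id[i]],
                          "*", fixed = TRUE)[[1]])
    sig <- x_ct[pair[1], ] * x_ct[pair[2], ]
    sig <- (sig - mean(sig)) / stats::sd(sig)
    y_ct <- sig + stats::rnorm(ncol(x_ct), 0, cfg_int$noise_sigma)
    y <- y_ct[rep_map[colnames(gm_vals)]] +
      stats::rnorm(ncol(gm_vals), 0, 0.1)
    gm_vals[regi$gene_id[i], ] <- y - mean(y)
  }
  gm <- expression_matrix(gm_vals, rep_map)
  hit <- vapply(seq_len(nrow(regi)), function(i) {
    pair <- sort(strsplit(gti$interaction[gti$gene_id == regi$gene_id[i]],
                          "*", fixed = TRUE)[[1]])
    it <- suppressMessages(interaction_test(regi[i, ], tfm, gm))
    row <- it[it$tf_a == pair[1] & it$tf_b == pair[2], , drop = FALSE]
    nrow(row) == 1 && row$p_value < 0.01
  }, TRUE)
  list(type1_rate = mean(p1 < 0.01), power = mean(hit),
       n_type1_pairs = length(p1), n_power = length(hit))
}

#' Cross-cell-line transfer error versus binding dissimilarity
#'
#' Simulates a fully regulated gene panel, derives cell line B by
#' perturbing each planted CRM toward one of the Jaccard targets
#' {0, 0.25, 0.5, 0.75}, and measures the per-pair MSPE ratio
#' (B-model over A-model) when predicting a held-out target cell type.
#'
#' @param seed integer seed.
#' @param n_genes genes (default 200; split over the four targets).
#' @return A list: `median_ratio_j0` (pairs with identical TF sets),
#'   `spearman_rho`, `spearman_p` (ratio vs Jaccard across pairs),
#'   `bin_medians` (named by Jaccard bin), `n_pairs`.
#' @export
study_dissimilarity_transfer <- function(seed, n_genes = 200) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           fraction_regulated = 1)
  sim <- simulate_genome(cfg)
  gt <- sim$ground_truth
  planted_genes <- unique(gt$planted_sites$gene_id)
  targets <- stats::setNames(
    rep(c(0, 0.25, 0.5, 0.75), length.out = length(planted_genes)),
    planted_genes)
  pb <- perturb_binding(sim, targets, seed = seed + 2L)
  crms_a <- detect_crms(sim$peaks)
  crms_b <- detect_crms(pb$peaks)
  links_a <- map_crms_to_genes(crms_a, sim$annotation)
  expr <- simulate_expression(cfg, gt)
  pairs <- find_overlapping_crms(crms_a, crms_b)
  target_ct <- utils::tail(cell_types(expr$gene_matrix), 1)
  dv <- dissimilarity_vs_error(pairs, crms_a, crms_b, links_a,
                               expr$tf_matrix, expr$gene_matrix, target_ct)
  pp <- dv$per_pair
  ct <- suppressWarnings(
    stats::cor.test(pp$jaccard, pp$ratio, method = "spearman",
                    alternative = "greater"))
  list(median_ratio_j0 = stats::median(pp$ratio[pp$jaccard == 0]),
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       bin_medians = stats::setNames(dv$bins$median_ratio,
                                     dv$bins$jaccard_bin),
       n_pairs = nrow(pp))
}

#' Held-out cell-type prediction: concordant vs discordant regulation
#'
#' Simulates a fully regulated panel, then builds a second panel in which
#' the regulator assignments and response functions are re-randomized
#' (rotated among the genes) while the TF expression panel stays fixed.
#' The last cell type's expression columns are spliced from the discordant
#' panel into a copy of the concordant one; leave-one-cell-type-out
#' accuracy for that cell type is compared between the two versions.  On
#' the concordant panel, the held-out cell type's across-genes accuracy is
#' also compared with both resampled-TF null families.
#'
#' @param seed integer seed.
#' @param n_genes genes (default 50).
#' @param n_null null draws per family (default 50).
#' @return A list: `r2_concordant`, `r2_discordant` (held-out cell type),
#'   `null_q975_pool14`, `null_q975_motif41` (97.5th percentiles of the
#'   across-genes null accuracy), `n_genes`.
#' @export
study_celltype_transfer <- function(seed, n_genes = 50, n_null = 50) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           fraction_regulated = 1,
                           fraction_interacting = 0)
  panel <- study_panel(cfg)
  gt <- panel$sim$ground_truth
  # discordant ground truth: rotate regulator/response assignments among
  # regulated genes so each gene inherits another gene's regulators
  gt2 <- gt
  reg_idx <- which(gt$genes$regulated)
  rot <- c(reg_idx[-1], reg_idx[1])
  gt2$genes[reg_idx, c("regulators", "responses", "interaction")] <-
    gt$genes[rot, c("regulators", "responses", "interaction")]
  expr2 <- simulate_expression(cfg, gt2)
  held <- utils::tail(cell_types(panel$expr$gene_matrix), 1)
  held_samples <- samples_of(panel$expr$gene_matrix, held)
  hybrid_vals <- panel$expr$gene_matrix$values
  hybrid_vals[, held_samples] <-
    expr2$gene_matrix$values[rownames(hybrid_vals), held_samples]
  hybrid <- mean_center(expression_matrix(
    hybrid_vals, panel$expr$gene_matrix$replicate_map))
  loo_con <- loocv_by_celltype(panel$specs, panel$expr$tf_matrix,
                               panel$expr$gene_matrix)
  loo_dis <- loocv_by_celltype(panel$specs, panel$expr$tf_matrix, hybrid)
  r2_con <- loo_con$r2_across_genes[loo_con$cell_type == held]
  r2_dis <- loo_dis$r2_across_genes[loo_dis$cell_type == held]
  # null families for the held-out cell type on the concordant panel
  tfm <- panel$expr$tf_matrix; gm <- panel$expr$gene_matrix
  train <- setdiff(samples(gm), held_samples)
  basis <- make_tf_basis(tfm)
  specs <- panel$specs
  across_r2 <- function(pred_sets) {
    pred <- matrix(NA_real_, length(held_samples), nrow(specs),
                   dimnames = list(held_samples, specs$gene_id))
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      s$predictors <- pred_sets[[i]]
      m <- fit_gene_model(s, tfm, gm, train, basis = basis)
      pred[, i] <- stats::predict(m, tfm, held_samples)$y_hat
    }
    obs <- t(gm$values[specs$gene_id, held_samples, drop = FALSE])
    mean(vapply(seq_along(held_samples), function(r)
      r_squared(pred[r, ], obs[r, ]), 0))
  }
  pool <- features(tfm)
  motif <- gt$motif
  null_r2 <- function(family, rep_seed) {
    set.seed(rep_seed)
    sets <- lapply(seq_len(nrow(specs)), function(i) {
      m <- length(spec_predictors(specs[i, ]))
      eligible <- if (family == "pool14") pool else
        intersect(pool, motif$tf[motif$gene_id == specs$gene_id[i]])
      if (length(eligible) < m) eligible <- pool
      paste(sort(sample(eligible, m)), collapse = ",")
    })
    across_r2(sets)
  }
  q_pool14 <- stats::quantile(vapply(seq_len(n_null), function(r)
    null_r2("pool14", seed + 100L + r), 0), 0.975, names = FALSE)
  q_motif <- stats::quantile(vapply(seq_len(n_null), function(r)
    null_r2("motif41", seed + 500L + r), 0), 0.975, names = FALSE)
  list(r2_concordant = r2_con, r2_discordant = r2_dis,
       null_q975_pool14 = q_pool14, null_q975_motif41 = q_motif,
       n_genes = nrow(specs))
}

#' Byte-level determinism of the pipeline stages
#'
#' Runs every pipeline stage twice with identical configuration and seeds
#' in two fresh directories and compares all outputs byte for byte
#' (excluding the timestamped log).
#'
#' @param seed integer seed.
#' @param base_dir parent directory for the two runs (default a tempdir).
#' @return A list: `identical` (logical), `n_files` compared.
#' @export
study_determinism <- function(seed, base_dir = tempfile("crmx_det")) {
  dir.create(base_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "detect-crms", "map-genes", "combos", "fit",
              "evaluate", "nulls", "compare", "report")
  run <- function(d) {
    cfg <- list(outdir = d, seed = seed, null_B = 20, dissim_B = 50,
                simulate = list(n_genes = 25, n_tfs = 6,
                                n_cell_types = 10, target_jaccard = 0.4))
    for (s in stages) suppressMessages(suppressWarnings(run_stage(s, cfg)))
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    # the log carries timestamps and the resolved config carries the
    # run-specific output path; neither is a stage output
    files[!basename(files) %in% c("crmx.log", "config_used.yaml")]
  }
  f1 <- run(file.path(base_dir, "run1"))
  f2 <- run(file.path(base_dir, "run2"))
  rel <- function(f, d) sub(paste0("^", d, "/?"), "", f)
  same_names <- identical(rel(f1, file.path(base_dir, "run1")),
                          rel(f2, file.path(base_dir, "run2")))
  same_bytes <- all(mapply(function(a, b)
    identical(readBin(a, "raw", file.size(a)),
              readBin(b, "raw", file.size(b))), f1, f2))
  list(identical = same_names && same_bytes, n_files = length(f1))
}
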