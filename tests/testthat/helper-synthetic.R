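# Shared fixtures and independent oracles for the test suite.

# Small expression panel: n_tf TFs, n_ct cell types x 2 replicates
# (replicates share the cell-type value plus small measurement noise).
tiny_panel <- function(seed, n_tf = 4, n_ct = 10, rep_sd = 0.05) {
  set.seed(seed)
  cts <- sprintf("ct%02d", seq_len(n_ct))
  ids <- as.vector(t(outer(cts, c("r1", "r2"), paste, sep = "_")))
  rep_map <- setNames(rep(cts, each = 2), ids)
  ct_vals <- matrix(rnorm(n_tf * n_ct), n_tf, n_ct,
                    dimnames = list(sprintf("TF%02d", seq_len(n_tf)), cts))
  m <- ct_vals[, rep_map[ids], drop = FALSE] +
    matrix(rnorm(n_tf * length(ids), 0, rep_sd), n_tf, length(ids))
  colnames(m) <- ids
  mean_center(expression_matrix(m, rep_map))
}

# Gene panel whose rows are per-sample functions of the TF values plus
# cell-type-level Gaussian noise (replicates share the noise draw).
gene_panel_from <- function(tf_matrix, gene_ids, fn_list, noise = 0,
                            seed = 1) {
  set.seed(seed)
  rep_map <- tf_matrix$replicate_map
  cts <- unique(unname(rep_map))
  ids <- colnames(tf_matrix$values)
  vals <- t(sapply(seq_along(gene_ids), function(i) {
    base <- unname(fn_list[[i]](tf_matrix$values))
    ct_noise <- setNames(rnorm(length(cts), 0, noise), cts)
    base + unname(ct_noise[rep_map[ids]])
  }))
  rownames(vals) <- gene_ids
  colnames(vals) <- ids
  mean_center(expression_matrix(vals, rep_map))
}

spec_for <- function(gene_id, predictors, crm_id = "crm1") {
  list(gene_id = gene_id, crm_id = crm_id,
       predictors = paste(sort(predictors), collapse = ","))
}

# Quadratic brute-force single-linkage oracle for CRM detection: union-find
# over all site pairs within max_gap on one chromosome.
brute_force_crms <- function(sites, max_gap = 500) {
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sites$chrom[i] == sites$chrom[j] &&
        abs(sites$pos[i] - sites$pos[j]) <= max_gap) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), comp)
  out <- lapply(groups, function(i) {
    tfs <- sort(unique(sites$tf[i]))
    if (length(tfs) < 2) return(NULL)
    list(chrom = sites$chrom[i[1]],
         span = range(sites$pos[i]),
         tfs = paste(tfs, collapse = ","))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  # canonical order for comparison
  ch <- vapply(out, function(g) g$chrom, "")
  lo <- vapply(out, function(g) g$span[1], 0)
  hi <- vapply(out, function(g) g$span[2], 0)
  out[order(ch, lo, hi)]
}

random_sites <- function(seed, n_sites = 30, n_tfs = 5, n_chrom = 2,
                         span = 20000) {
  set.seed(seed)
  data.frame(tf = sprintf("TF%d", sample(n_tfs, n_sites, replace = TRUE)),
             chrom = sprintf("chr%d", sample(n_chrom, n_sites,
                                             replace = TRUE)),
             pos = sample.int(span, n_sites, replace = TRUE),
             stringsAsFactors = FALSE)
}

crms_as_canonical <- function(crms) {
  ord <- order(crms$chrom, crms$start, crms$end)
  lapply(ord, function(i) list(chrom = crms$chrom[i],
                               span = c(crms$start[i], crms$end[i]),
                               tfs = crms$tfs[i]))
}
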