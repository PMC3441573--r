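#' Assign cell types to cross-validation folds
#'
#' Folds stratify by cell type: biological replicates of one cell type always
#' land in the same fold, so a replicate can never leak from test to
#' training.
#'
#' @param em an [expression_matrix()] supplying the replicate structure.
#' @param k number of folds.
#' @param seed integer seed for the shuffle (required).
#' @return A named integer vector mapping each cell type to a fold in 1..k.
#' @export
make_folds <- function(em, k, seed) {
  cts <- cell_types(em)
  if (k > length(cts))
    stop("k = ", k, " exceeds the number of cell types (", length(cts), ")")
  if (k < 2) stop("need k >= 2")
  set.seed(seed)
  stats::setNames(rep_len(seq_len(k), length(cts)), sample(cts))
}

#' k-fold cross-validated prediction accuracy for one gene model
#'
#' Cell types are shuffled into `k` folds (replicates staying together); for
#' each fold the model is trained on the remaining samples and the held-out
#' fold's samples are predicted.  The reported accuracy is the squared
#' Pearson correlation per fold, averaged over folds.
#'
#' @inheritParams fit_gene_model
#' @param k number of folds (default 5).
#' @param seed fold-shuffle seed; ignored when `folds` is supplied.
#' @param folds optional precomputed [make_folds()] assignment, so observed
#'   and null models can share identical folds.
#' @param sp_mode how smoothing parameters are handled across folds.
#'   `"shared"` (default) selects them once per gene by GCV on the full
#'   panel and refits each fold's coefficients at those values by penalized
#'   least squares; `"per-fold"` reselects smoothing within every training
#'   fold.  Shared selection uses only predictor-response smoothness, is
#'   far cheaper, and is applied identically to observed and null models,
#'   so paired bootstrap comparisons are unaffected.
#' @param interactions optional 2-column matrix of TF pairs included as
#'   penalized tensor-product terms (e.g. the pairs that pass
#'   [interaction_test()]).
#' @return A list of class `"CVResult"`: `gene_id`, `crm_id`, `per_fold`
#'   (R-squared per fold), `mean_r2`.
#' @export
kfold_cv <- function(spec, tf_matrix, gene_matrix, k = 5, seed = NULL,
                     folds = NULL, basis_cap = 8, basis = NULL,
                     sp_mode = c("shared", "per-fold"),
                     interactions = NULL) {
  sp_mode <- match.arg(sp_mode)
  if (is.null(folds)) {
    if (is.null(seed)) stop("supply 'seed' or precomputed 'folds'")
    folds <- make_folds(gene_matrix, k, seed)
  }
  all_samples <- samples(tf_matrix)
  preds <- spec_predictors(spec)
  if (is.null(basis))
    basis <- make_tf_basis(tf_matrix, unique(preds), basis_cap)
  fold_ids <- sort(unique(folds))
  test_sets <- lapply(fold_ids, function(f)
    samples_of(gene_matrix, names(folds)[folds == f]))
  if (sp_mode == "shared") {
    y_all <- gene_matrix$values[spec$gene_id, all_samples]
    sds <- apply(tf_matrix$values[preds, , drop = FALSE], 1, stats::sd)
    preds <- preds[sds > 1e-10]
    if (!length(preds)) {
      per_fold <- rep(0, length(fold_ids))
    } else {
      inter <- list()
      if (!is.null(interactions) && nrow(interactions)) {
        for (i in seq_len(nrow(interactions))) {
          a <- as.character(interactions[i, 1])
          b <- as.character(interactions[i, 2])
          if (a %in% preds && b %in% preds)
            inter[[length(inter) + 1L]] <-
              make_interaction_basis(tf_matrix, a, b)
        }
      }
      design <- assemble_design(basis, preds, seq_along(all_samples), inter)
      full <- fit_penalized(y_all, design)
      P <- penalty_total(design, full$sp)
      per_fold <- vapply(seq_along(fold_ids), function(i) {
        te <- match(test_sets[[i]], all_samples)
        tr <- setdiff(seq_along(all_samples), te)
        beta <- pls_coef(design$X[tr, , drop = FALSE], y_all[tr], P)
        y_hat <- drop(design$X[te, , drop = FALSE] %*% beta)
        r_squared(y_hat, y_all[te])
      }, 0)
    }
  } else {
    per_fold <- vapply(seq_along(fold_ids), function(i) {
      test <- test_sets[[i]]
      train <- setdiff(all_samples, test)
      m <- fit_gene_model(spec, tf_matrix, gene_matrix, train,
                          interactions = interactions,
                          basis_cap = basis_cap, basis = basis)
      stats::predict(m, tf_matrix, test, gene_matrix)$r_squared
    }, 0)
  }
  structure(list(gene_id = spec$gene_id, crm_id = spec$crm_id,
                 per_fold = per_fold, mean_r2 = mean(per_fold)),
            class = "CVResult")
}

#' Leave-one-cell-type-out accuracy across genes
#'
#' For each cell type, every gene model is trained on all other cell types
#' and the held-out cell type is predicted.  Accuracy is the squared Pearson
#' correlation between predicted and observed expression across genes,
#' computed per replicate and averaged over replicates.  When several specs
#' target one gene, the CRM closest to the TSS is used.
#'
#' @param specs data frame from [build_model_specs()].
#' @param tf_matrix,gene_matrix mean-centered [expression_matrix()] objects.
#' @param basis_cap cap on the per-term basis dimension.
#' @return A data frame with columns `cell_type` and `r2_across_genes`;
#'   per-replicate values are attached as attribute `"per_replicate"`.
#' @export
loocv_by_celltype <- function(specs, tf_matrix, gene_matrix, basis_cap = 8) {
  cts <- cell_types(gene_matrix)
  if (length(cts) < 3) stop("need at least 3 cell types")
  if ("distance" %in% names(specs))
    specs <- specs[order(specs$gene_id, abs(specs$distance), specs$crm_id), ]
  specs <- specs[!duplicated(specs$gene_id), , drop = FALSE]
  if (nrow(specs) < 2)
    stop("need at least 2 genes for an across-genes correlation")
  basis <- make_tf_basis(tf_matrix, basis_cap = basis_cap)
  per_rep_list <- list()
  rows <- lapply(cts, function(ct) {
    test <- samples_of(gene_matrix, ct)
    if (!length(test)) return(NULL)
    train <- setdiff(samples(gene_matrix), test)
    pred <- matrix(NA_real_, length(test), nrow(specs),
                   dimnames = list(test, specs$gene_id))
    for (i in seq_len(nrow(specs))) {
      m <- fit_gene_model(specs[i, ], tf_matrix, gene_matrix, train,
                          basis_cap = basis_cap, basis = basis)
      pred[, i] <- stats::predict(m, tf_matrix, test)$y_hat
    }
    obs <- t(gene_matrix$values[specs$gene_id, test, drop = FALSE])
    per_rep <- vapply(seq_along(test), function(r)
      r_squared(pred[r, ], obs[r, ]), 0)
    per_rep_list[[ct]] <<- stats::setNames(per_rep, test)
    data.frame(cell_type = ct, r2_across_genes = mean(per_rep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "per_replicate") <- per_rep_list
  out
}

#' Compare two groups of accuracy statistics
#'
#' Wilcoxon rank-sum test between two groups of R-squared or MSPE values,
#' exact when both groups have at most 20 untied values, normal approximation
#' with continuity correction otherwise.
#'
#' @param a,b numeric vectors (>= 3 values each).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (for `a` vs `b`).
#' @return The p-value.
#' @export
compare_groups <- function(a, b, alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 3 || length(b) < 3) stop("both groups need >= 3 values")
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both groups")
    return(1)
  }
  exact <- max(length(a), length(b)) <= 20 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
}
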