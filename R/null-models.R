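#' Specify a resampled-TF null model family
#'
#' Two families are supported.  `pool14` replaces the CRM's TFs with TFs
#' drawn uniformly without replacement from the assayed TF panel.  `motif41`
#' draws from a larger candidate list (e.g. hematopoietic regulators) but a
#' TF is eligible for a given target gene only if it is flagged expressed in
#' the reference cell line and its binding motif is enriched near that gene's
#' TSS.
#'
#' @param null_type `"pool14"` or `"motif41"`.
#' @param pool character vector of candidate TF ids.
#' @param B number of null replicates (default 1000).
#' @param seed integer seed (required).
#' @return A list of class `"NullSpec"`.
#' @export
null_spec <- function(null_type = c("pool14", "motif41"), pool, B = 1000,
                      seed) {
  null_type <- match.arg(null_type)
  if (B < 1) stop("'B' must be >= 1")
  if (missing(seed)) stop("'seed' is required for resampling")
  if (!length(pool)) stop("empty TF pool")
  structure(list(null_type = null_type, pool = as.character(pool),
                 B = as.integer(B), seed = as.integer(seed)),
            class = "NullSpec")
}

#' Motif / expression constraints for the motif-informed null family
#'
#' @param motif data frame with columns `tf` and `gene_id` listing the
#'   (TF, gene) pairs whose binding motif is enriched near the gene's TSS
#'   (i.e. pairs passing the enrichment p-value threshold upstream).
#' @param expressed named logical vector: is each pool TF expressed in the
#'   reference cell line?
#' @return A list of class `"MotifConstraint"`.
#' @export
motif_constraint <- function(motif, expressed) {
  stopifnot(all(c("tf", "gene_id") %in% names(motif)),
            is.logical(expressed), !is.null(names(expressed)))
  structure(list(motif = motif, expressed = expressed),
            class = "MotifConstraint")
}

eligible_pool <- function(ns, constraints, gene_id) {
  if (ns$null_type == "pool14") return(ns$pool)
  if (is.null(constraints))
    stop("motif41 null requires motif/expression constraints")
  expr_ok <- names(constraints$expressed)[constraints$expressed]
  enriched <- constraints$motif$tf[constraints$motif$gene_id == gene_id]
  intersect(intersect(ns$pool, expr_ok), enriched)
}

#' Draw one null model specification
#'
#' Replaces the spec's predictors by the same number of TFs drawn uniformly
#' without replacement from the eligible pool.  The draw is deterministic
#' given the null spec's seed and the replicate index.
#'
#' @param spec one row of [build_model_specs()].
#' @param ns a [null_spec()].
#' @param constraints a [motif_constraint()] (required for `motif41`).
#' @param replicate_index integer in 1..B.
#' @return The spec with resampled predictors, or `NULL` when the eligible
#'   pool is smaller than the number of predictors (gene skipped, message
#'   emitted).
#' @export
sample_null_spec <- function(spec, ns, constraints = NULL, replicate_index) {
  preds <- spec_predictors(spec)
  pool <- eligible_pool(ns, constraints, spec$gene_id)
  if (length(pool) < length(preds)) {
    message("gene ", spec$gene_id, " skipped for ", ns$null_type,
            " null: eligible pool (", length(pool),
            ") smaller than predictor count (", length(preds), ")")
    return(NULL)
  }
  set.seed(ns$seed + as.integer(replicate_index))
  out <- spec
  out$predictors <- paste(sort(sample(pool, length(preds))), collapse = ",")
  out
}

#' Bootstrap p-value for observed prediction accuracy
#'
#' Add-one tail fraction: `p = (1 + #\{null >= observed\}) / (1 + B)`.  The
#' estimator never returns 0 and its minimum attainable value is
#' `1 / (B + 1)`.
#'
#' @param observed_r2 observed accuracy.
#' @param null_r2s numeric vector of null accuracies (length >= 1).
#' @return The p-value.
#' @export
bootstrap_pvalue <- function(observed_r2, null_r2s) {
  if (!length(null_r2s)) stop("need at least one null value")
  (1 + sum(null_r2s >= observed_r2)) / (1 + length(null_r2s))
}

#' Run the resampled-TF null battery over a set of gene models
#'
#' For each spec, the observed cross-validated accuracy is compared with `B`
#' null models in which the CRM's TFs are replaced by resampled TFs; null
#' models reuse the identical fold assignment (paired comparison), and the
#' bootstrap p-value is the add-one tail fraction.  Repeated identical null
#' TF sets within a gene reuse the already-computed accuracy (the CV result
#' is deterministic given the folds).
#'
#' With `interaction_alpha` set (default 0.01), every model — observed and
#' null alike — follows the pairwise interaction policy: main effects are
#' fitted first, TF pairs are tested one at a time with
#' [interaction_test()], and pairs passing the threshold are added to the
#' model as penalized tensor-product terms before cross-validation.
#' Applying the identical protocol on both sides keeps the bootstrap
#' comparison paired.  `interaction_alpha = NULL` fits main effects only.
#'
#' @param specs data frame from [build_model_specs()].
#' @param tf_matrix,gene_matrix mean-centered [expression_matrix()] objects.
#' @param ns a [null_spec()].
#' @param constraints a [motif_constraint()] for `motif41`.
#' @param k CV folds (default 5).
#' @param cv_seed seed for the shared fold assignment.
#' @param basis_cap cap on the per-term basis dimension.
#' @param interaction_alpha p-value threshold below which a tested TF pair
#'   joins the model; `NULL` disables interaction terms.
#' @return A data frame with columns `gene_id`, `crm_id`, `observed_r2`,
#'   `p_value`, `null_q025`, `null_q975`, `n_null`.  Per-gene null accuracy
#'   vectors are attached as attribute `"null_r2"`; skipped genes as
#'   attribute `"skipped"`.
#' @export
run_null_battery <- function(specs, tf_matrix, gene_matrix, ns,
                             constraints = NULL, k = 5, cv_seed = 1,
                             basis_cap = 8, interaction_alpha = 0.01) {
  folds <- make_folds(gene_matrix, k, cv_seed)
  basis <- make_tf_basis(tf_matrix, basis_cap = basis_cap)
  all_samples <- samples(tf_matrix)
  n <- length(all_samples)
  # replicate-averaging operator: cell types x samples
  cts <- cell_types(gene_matrix)
  C <- matrix(0, length(cts), n, dimnames = list(cts, all_samples))
  for (ct in cts) {
    s <- samples_of(gene_matrix, ct)
    C[ct, s] <- 1 / length(s)
  }
  n_c <- length(cts)
  fold_rows <- lapply(sort(unique(folds)), function(f)
    match(samples_of(gene_matrix, names(folds)[folds == f]), all_samples))
  ti_fx_cache <- new.env(parent = emptyenv())
  ti_avg <- function(a, b) {
    key <- paste(a, b, sep = "|")
    hit <- ti_fx_cache[[key]]
    if (is.null(hit)) {
      ib <- make_interaction_basis(tf_matrix, a, b, k_int = 3, fx = TRUE)
      hit <- C %*% ib$X
      ti_fx_cache[[key]] <- hit
    }
    hit
  }
  # One GCV smoothness selection per TF set: the full-panel additive fit
  # drives both the cross-validated refits and (at fixed smoothing, on
  # replicate-averaged design rows) the fixed-df interaction screen.
  cv_protocol <- function(spec) {
    preds <- spec_predictors(spec)
    sds <- apply(tf_matrix$values[preds, , drop = FALSE], 1, stats::sd)
    preds <- preds[sds > 1e-10]
    if (!length(preds)) return(0)
    y <- gene_matrix$values[spec$gene_id, all_samples]
    design <- assemble_design(basis, preds, seq_len(n))
    full <- fit_penalized(y, design)
    P <- penalty_total(design, full$sp)
    sig_pairs <- NULL
    if (!is.null(interaction_alpha) && length(preds) >= 2) {
      Xc <- C %*% design$X
      yc <- drop(C %*% y)
      b0 <- pls_coef(Xc, yc, P)
      rss0 <- sum((yc - drop(Xc %*% b0))^2)
      combos <- utils::combn(sort(preds), 2)
      for (j in seq_len(ncol(combos))) {
        Tc <- ti_avg(combos[1, j], combos[2, j])
        df_t <- ncol(Tc)
        if (n_c - (ncol(Xc) + df_t) < 5) next
        Xf <- cbind(Xc, Tc)
        Pf <- matrix(0, ncol(Xf), ncol(Xf))
        Pf[seq_len(ncol(Xc)), seq_len(ncol(Xc))] <- P
        A <- crossprod(Xf) + Pf
        beta <- tryCatch(solve(A, crossprod(Xf, yc)), error = function(e)
          solve(A + diag(1e-8 * max(diag(A)), ncol(A)),
                crossprod(Xf, yc)))
        rss1 <- sum((yc - drop(Xf %*% beta))^2)
        edf1 <- sum(diag(tryCatch(solve(A, crossprod(Xf)),
                                  error = function(e)
          solve(A + diag(1e-8 * max(diag(A)), ncol(A)), crossprod(Xf)))))
        if (n_c - edf1 < 1 || rss1 <= 0) next
        f_stat <- ((rss0 - rss1) / df_t) / (rss1 / (n_c - edf1))
        p <- if (f_stat <= 0) 1 else
          stats::pf(f_stat, df_t, n_c - edf1, lower.tail = FALSE)
        if (p < interaction_alpha)
          sig_pairs <- rbind(sig_pairs, combos[, j])
      }
    }
    if (!is.null(sig_pairs)) {
      inter <- lapply(seq_len(nrow(sig_pairs)), function(i)
        make_interaction_basis(tf_matrix, sig_pairs[i, 1],
                               sig_pairs[i, 2]))
      design <- assemble_design(basis, preds, seq_len(n), inter)
      full <- fit_penalized(y, design)
      P <- penalty_total(design, full$sp)
    }
    per_fold <- vapply(fold_rows, function(te) {
      tr <- setdiff(seq_len(n), te)
      beta <- pls_coef(design$X[tr, , drop = FALSE], y[tr], P)
      r_squared(drop(design$X[te, , drop = FALSE] %*% beta), y[te])
    }, 0)
    mean(per_fold)
  }
  rows <- list(); null_store <- list(); skipped <- character()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    pool <- eligible_pool(ns, constraints, spec$gene_id)
    n_pred <- length(spec_predictors(spec))
    if (length(pool) < n_pred) {
      message("gene ", spec$gene_id, " skipped for ", ns$null_type,
              " null: eligible pool too small")
      skipped <- c(skipped, spec$gene_id)
      next
    }
    obs <- tryCatch(cv_protocol(spec),
      error = function(e) {
        warning("observed fit failed for ", spec$gene_id, ": ",
                conditionMessage(e))
        NA_real_
      })
    if (is.na(obs)) { skipped <- c(skipped, spec$gene_id); next }
    cache <- new.env(parent = emptyenv())
    null_r2 <- numeric(ns$B)
    set.seed(ns$seed + i)
    for (b in seq_len(ns$B)) {
      tfs <- sort(sample(pool, n_pred))
      key <- paste(tfs, collapse = ",")
      if (!is.null(cache[[key]])) {
        null_r2[b] <- cache[[key]]
        next
      }
      nspec <- spec
      nspec$predictors <- key
      r2 <- tryCatch(cv_protocol(nspec), error = function(e) NA_real_)
      cache[[key]] <- r2
      null_r2[b] <- r2
    }
    null_r2 <- null_r2[!is.na(null_r2)]
    if (!length(null_r2)) { skipped <- c(skipped, spec$gene_id); next }
    q <- stats::quantile(null_r2, c(0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = spec$gene_id, crm_id = spec$crm_id, observed_r2 = obs,
      p_value = bootstrap_pvalue(obs, null_r2),
      null_q025 = q[1], null_q975 = q[2], n_null = length(null_r2),
      stringsAsFactors = FALSE)
    null_store[[spec$gene_id]] <- null_r2
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), crm_id = character(),
               observed_r2 = numeric(), p_value = numeric(),
               null_q025 = numeric(), null_q975 = numeric(),
               n_null = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_r2") <- null_store
  attr(out, "skipped") <- skipped
  out
}
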