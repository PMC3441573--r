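#' Build model specifications for CRM-gene pairs
#'
#' One specification per CRM-gene link: the model for a gene predicts its log
#' expression from the expressions of the TFs in the promoter CRM.
#' Predictors are the CRM's distinct TFs, sorted lexicographically.  Specs
#' whose CRM contains a TF with no row in the TF expression matrix are
#' dropped with a warning.
#'
#' @param links CRM-gene links from [map_crms_to_genes()].
#' @param crms CRM table from [call_crms()].
#' @param tf_matrix TF [expression_matrix()].
#' @return A data frame with columns `gene_id`, `crm_id`, `predictors`
#'   (comma-joined, sorted) and `distance`.
#' @export
build_model_specs <- function(links, crms, tf_matrix) {
  idx <- match(links$crm_id, crms$crm_id)
  if (anyNA(idx)) stop("links refer to unknown CRMs")
  preds <- tf_sets(crms)[idx]
  known <- vapply(preds, function(p) all(p %in% features(tf_matrix)), TRUE)
  if (any(!known))
    warning(sum(!known), " spec(s) dropped: predictor TF absent from ",
            "TF expression matrix")
  out <- data.frame(
    gene_id = links$gene_id[known],
    crm_id = links$crm_id[known],
    predictors = vapply(preds[known], function(p)
      paste(sort(p), collapse = ","), ""),
    distance = links$distance[known],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

spec_predictors <- function(spec) {
  p <- spec$predictors
  if (length(p) == 1 && grepl(",", p, fixed = TRUE))
    p <- strsplit(p, ",", fixed = TRUE)[[1]]
  as.character(p)
}

#' Fit the additive spline expression model for one gene-CRM pair
#'
#' Models the gene's mean-centered log expression across cell-type samples as
#' a sum of cubic-regression-spline functions of the TF expressions, with the
#' degree of smoothing chosen by generalized cross-validation (GCV).  The
#' basis dimension per term is `min(basis_cap, floor(n_samples / 3))`;
#' optional bivariate TF-TF interaction terms use a 4x4 tensor-product basis
#' with the main effects excluded.  Constant predictors are dropped.  When
#' every remaining term is linear (tiny panels) or the penalized fit fails,
#' the model falls back to ordinary least squares on linear terms with a
#' warning.
#'
#' @param spec one row of [build_model_specs()] (or an equivalent list with
#'   `gene_id`, `crm_id`, `predictors`).
#' @param tf_matrix,gene_matrix mean-centered [expression_matrix()] objects.
#' @param training_samples sample ids to train on (default: all).
#' @param interactions optional 2-column matrix / data frame of TF pairs to
#'   include as tensor-product interaction terms.
#' @param interactions_fx if `TRUE`, interaction blocks are unpenalized
#'   (fixed df), as used by [interaction_test()].
#' @param interactions_k marginal basis dimension of interaction tensor
#'   blocks (default 4).
#' @param basis_cap cap on the per-term basis dimension (default 8).
#' @param basis optional precomputed [make_tf_basis()] cache for `tf_matrix`.
#' @return An object of class `"crm_gam"`.
#' @export
fit_gene_model <- function(spec, tf_matrix, gene_matrix,
                           training_samples = NULL, interactions = NULL,
                           basis_cap = 8, basis = NULL,
                           interactions_fx = FALSE, interactions_k = 4) {
  all_samples <- samples(tf_matrix)
  if (is.null(training_samples)) training_samples <- all_samples
  if (length(training_samples) < 4)
    stop("need at least 4 training samples")
  rows <- match(training_samples, all_samples)
  if (anyNA(rows)) stop("unknown training samples")
  gene_id <- spec$gene_id
  y <- gene_matrix$values[gene_id, training_samples]
  preds <- spec_predictors(spec)
  missing <- setdiff(preds, features(tf_matrix))
  if (length(missing))
    stop("predictor TF(s) not in TF matrix: ", paste(missing, collapse = ", "))
  sds <- apply(tf_matrix$values[preds, training_samples, drop = FALSE], 1,
               stats::sd)
  dropped <- preds[sds < 1e-10]
  if (length(dropped)) {
    warning("constant predictor(s) dropped: ", paste(dropped, collapse = ", "))
    preds <- setdiff(preds, dropped)
  }
  if (is.null(basis))
    basis <- make_tf_basis(tf_matrix, unique(preds), basis_cap)
  inter <- list()
  if (!is.null(interactions) && length(preds) >= 2) {
    for (i in seq_len(nrow(interactions))) {
      a <- as.character(interactions[i, 1]); b <- as.character(interactions[i, 2])
      if (a %in% preds && b %in% preds)
        inter[[length(inter) + 1L]] <-
          make_interaction_basis(tf_matrix, a, b, k_int = interactions_k,
                                 fx = interactions_fx)
    }
  }
  if (!length(preds)) {
    fit <- list(coef = mean(y), fitted = rep(mean(y), length(y)),
                rss = sum((y - mean(y))^2), edf = 1,
                edf_col = 1, sp = numeric())
    design <- list(blocks = list(intercept = 1L))
  } else {
    design <- assemble_design(basis, preds, rows, inter)
    fit <- tryCatch(fit_penalized(y, design), error = function(e) NULL)
    if (is.null(fit)) {
      warning("penalized fit failed for ", gene_id,
              "; falling back to linear terms")
      X <- cbind(1, t(tf_matrix$values[preds, training_samples, drop = FALSE]))
      lf <- stats::lm.fit(X, y)
      co <- lf$coefficients; co[is.na(co)] <- 0
      return(structure(list(
        gene_id = gene_id, crm_id = spec$crm_id, predictors = preds,
        dropped = dropped, linear_fallback = TRUE, beta0 = co[1],
        coef = co, basis = NULL, interactions = list(),
        edf_by_term = stats::setNames(rep(1, length(preds)), preds),
        edf = sum(!is.na(lf$coefficients)),
        rss = sum(lf$residuals^2), fitted = drop(X %*% co),
        training_samples = training_samples, y = y),
        class = "crm_gam"))
    }
  }
  term_names <- setdiff(names(design$blocks), "intercept")
  term_edf <- vapply(term_names, function(tn)
    sum(fit$edf_col[design$blocks[[tn]]]), 0)
  structure(list(
    gene_id = gene_id, crm_id = spec$crm_id, predictors = preds,
    dropped = dropped, linear_fallback = FALSE,
    beta0 = unname(fit$coef[1]), coef = fit$coef,
    basis = basis[preds], interactions = inter,
    edf_by_term = term_edf, edf = fit$edf, rss = fit$rss,
    sp = fit$sp, fitted = fit$fitted,
    training_samples = training_samples, y = y),
    class = "crm_gam")
}

#' @export
print.crm_gam <- function(x, ...) {
  cat("Additive spline expression model for gene ", x$gene_id,
      " (CRM ", x$crm_id, ")\n", sep = "")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  total edf:", round(x$edf, 2), " RSS:", signif(x$rss, 4), "\n")
  invisible(x)
}

#' Squared Pearson correlation
#'
#' The package's prediction-accuracy statistic: the square of the Pearson
#' correlation between predicted and observed expression.  Returns 0 when
#' either vector is constant (no linear association measurable).
#'
#' @param y_hat,y_obs numeric vectors of equal length >= 2.
#' @return A value in \[0, 1\].
#' @export
r_squared <- function(y_hat, y_obs) {
  if (length(y_hat) != length(y_obs)) stop("length mismatch")
  if (length(y_hat) < 2) stop("correlation needs at least 2 points")
  if (stats::sd(y_hat) < 1e-12 || stats::sd(y_obs) < 1e-12) return(0)
  stats::cor(y_hat, y_obs)^2
}

#' Mean squared prediction error
#' @param y_hat,y_obs numeric vectors of equal length >= 1.
#' @return Mean of squared differences.
#' @export
mspe <- function(y_hat, y_obs) {
  if (!length(y_hat)) stop("empty input")
  if (length(y_hat) != length(y_obs)) stop("length mismatch")
  mean((y_hat - y_obs)^2)
}

#' Predict expression from a fitted CRM model
#'
#' Spline terms extend linearly beyond the training range by default;
#' `clamp = TRUE` instead clamps test predictor values to the boundary of the
#' spline's support.  Samples requiring extrapolation are flagged.
#'
#' @param object a fitted [fit_gene_model()] model.
#' @param tf_matrix TF [expression_matrix()] holding the test samples.
#' @param test_samples sample ids to predict.
#' @param gene_matrix optional gene [expression_matrix()]; when supplied,
#'   observed values, R-squared and MSPE are included in the result.
#' @param clamp clamp predictors to the training range.
#' @param ... unused.
#' @return A list of class `"PredictionResult"`: `sample_ids`, `y_hat`,
#'   `y_obs` (or NULL), `r_squared`, `mspe`, `extrapolated`.
#' @export
predict.crm_gam <- function(object, tf_matrix, test_samples,
                            gene_matrix = NULL, clamp = FALSE, ...) {
  if (!length(test_samples)) stop("empty test set")
  if (object$linear_fallback) {
    X <- cbind(1, t(tf_matrix$values[object$predictors, test_samples,
                                     drop = FALSE]))
    y_hat <- drop(X %*% object$coef)
    extrapolated <- rep(FALSE, length(test_samples))
  } else if (!length(object$predictors)) {
    y_hat <- rep(object$beta0, length(test_samples))
    extrapolated <- rep(FALSE, length(test_samples))
  } else {
    pd <- predict_design(object$basis, object$predictors, tf_matrix,
                         test_samples, object$interactions, clamp = clamp)
    y_hat <- drop(pd$X %*% object$coef)
    extrapolated <- pd$extrapolated
  }
  names(y_hat) <- test_samples
  y_obs <- NULL; r2 <- NULL; err <- NULL
  if (!is.null(gene_matrix)) {
    y_obs <- gene_matrix$values[object$gene_id, test_samples]
    r2 <- if (length(test_samples) >= 2) r_squared(y_hat, y_obs) else NA_real_
    err <- mspe(y_hat, y_obs)
  }
  structure(list(sample_ids = test_samples, y_hat = y_hat, y_obs = y_obs,
                 r_squared = r2, mspe = err, extrapolated = extrapolated),
            class = "PredictionResult")
}

#' Test whether splines fit better than a linear model
#'
#' Compares ordinary least squares on the predictors against the same model
#' with fixed-df (unpenalized) cubic-regression-spline terms of dimension
#' `k_test` per predictor, by a classical nested F-test on residual sums of
#' squares.  The tested spline block is deliberately *not* penalized: with
#' GCV-selected smooths the effective degrees of freedom adapt to the noise
#' and an edf-based F-test is measurably liberal (and increasingly so with
#' more predictors), whereas the fixed-df comparison is exact under the
#' Gaussian null.  Both models are fitted on replicate-averaged (cell-type
#' mean) expression: replicates share their cell-type-level variation, and
#' counting them as independent observations would inflate the test
#' (pseudo-replication).
#'
#' @inheritParams fit_gene_model
#' @param k_test basis dimension per predictor in the spline alternative
#'   (default 5, i.e. 3 nonlinear df per predictor).
#' @return A list: `p_value`, `f_stat`, `df_nonlinear`, `df_linear`,
#'   `nonlinear` (flag at p < 0.01).
#' @export
nonlinearity_test <- function(spec, tf_matrix, gene_matrix,
                              training_samples = NULL, basis_cap = 8,
                              k_test = 5) {
  if (!is.null(training_samples)) {
    keep <- unique(unname(tf_matrix$replicate_map[training_samples]))
    tf_matrix <- subset_expression(tf_matrix,
                                   samples = samples_of(tf_matrix, keep))
    gene_matrix <- subset_expression(gene_matrix,
                                     samples = samples_of(gene_matrix, keep))
  }
  tf_matrix <- collapse_replicates(tf_matrix)
  gene_matrix <- collapse_replicates(gene_matrix)
  n <- ncol(tf_matrix$values)
  preds <- spec_predictors(spec)
  sds <- apply(tf_matrix$values[preds, , drop = FALSE], 1, stats::sd)
  preds <- preds[sds > 1e-10]
  y <- gene_matrix$values[spec$gene_id, ]
  if (!length(preds))
    return(list(p_value = 1, f_stat = 0, df_nonlinear = 0, df_linear = 1,
                nonlinear = FALSE))
  X_lin <- cbind(1, t(tf_matrix$values[preds, , drop = FALSE]))
  k <- min(k_test, basis_dim(n, basis_cap))
  blocks <- lapply(preds, function(tf) {
    x <- tf_matrix$values[tf, ]
    if (k < 3 || length(unique(x)) <= k) return(cbind(x))
    mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k, fx = TRUE),
                    data = data.frame(x = x), absorb.cons = TRUE)[[1]]$X
  })
  X_spl <- cbind(1, do.call(cbind, blocks))
  lf <- stats::lm.fit(X_lin, y)
  sf <- stats::lm.fit(X_spl, y)
  df_lin <- sum(!is.na(lf$coefficients))
  df_spl <- sum(!is.na(sf$coefficients))
  rss_lin <- sum(lf$residuals^2)
  rss_spl <- sum(sf$residuals^2)
  df1 <- df_spl - df_lin
  if (df1 < 1 || n - df_spl < 1 || rss_spl <= 0)
    return(list(p_value = 1, f_stat = 0, df_nonlinear = max(df1, 0),
                df_linear = df_lin, nonlinear = FALSE))
  f_stat <- ((rss_lin - rss_spl) / df1) / (rss_spl / (n - df_spl))
  p <- if (f_stat <= 0) 1 else
    stats::pf(f_stat, df1, n - df_spl, lower.tail = FALSE)
  list(p_value = p, f_stat = f_stat, df_nonlinear = df1,
       df_linear = df_lin, nonlinear = p < 0.01)
}

#' Test TF-TF interaction terms one pair at a time
#'
#' For each TF pair in the spec, compares the additive model against the same
#' model plus a tensor-product interaction surface for that pair with an
#' F-test on residual sums of squares.  Two choices keep the test calibrated
#' and powered at 38 cell types: the added tensor block is *unpenalized*
#' with exactly `(k_int - 1)^2` fixed degrees of freedom (an adaptively
#' penalized block chases noise and inflates the test), and the main-effect
#' smoothing parameters are held at their additive-fit values in the
#' augmented fit (classical nested F conditional on the nuisance
#' smoothing).  The default `k_int = 3` (4 df) spans every bilinear
#' surface — a multiplicative TF pair is rank-1 bilinear — and leaves
#' 4-predictor CRMs testable on 38 cell types, where a 4x4 block would not
#' fit.  Like [nonlinearity_test()], the comparison is made on
#' replicate-averaged expression.  Pairs whose block would leave fewer
#' residual degrees of freedom than `min_resid_df` are skipped with a
#' message.
#'
#' @inheritParams fit_gene_model
#' @param pairs optional 2-column matrix of TF pairs; default all pairs.
#' @param k_int marginal basis dimension of the tested tensor block
#'   (default 3).
#' @param min_resid_df minimum residual degrees of freedom (default 5).
#' @param basis,ti_cache optional precomputed bases on the collapsed panel
#'   (performance knobs used by [run_null_battery()]).
#' @return A data frame with columns `tf_a`, `tf_b`, `p_value`, `edf_int`,
#'   `significant` (p < 0.01); zero rows for single-predictor specs.
#' @export
interaction_test <- function(spec, tf_matrix, gene_matrix,
                             training_samples = NULL, pairs = NULL,
                             basis_cap = 8, k_int = 3, min_resid_df = 5,
                             basis = NULL, ti_cache = NULL) {
  if (!is.null(training_samples)) {
    keep <- unique(unname(tf_matrix$replicate_map[training_samples]))
    tf_matrix <- subset_expression(tf_matrix,
                                   samples = samples_of(tf_matrix, keep))
    gene_matrix <- subset_expression(gene_matrix,
                                     samples = samples_of(gene_matrix, keep))
    basis <- NULL; ti_cache <- NULL
  }
  tf_matrix <- collapse_replicates(tf_matrix)
  gene_matrix <- collapse_replicates(gene_matrix)
  preds <- spec_predictors(spec)
  empty <- data.frame(tf_a = character(), tf_b = character(),
                      p_value = numeric(), edf_int = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (length(preds) < 2) return(empty)
  if (is.null(pairs)) pairs <- t(utils::combn(sort(preds), 2))
  if (is.null(basis)) basis <- make_tf_basis(tf_matrix, preds, basis_cap)
  n <- ncol(tf_matrix$values)
  y <- gene_matrix$values[spec$gene_id, ]
  sds <- apply(tf_matrix$values[preds, , drop = FALSE], 1, stats::sd)
  preds <- preds[sds > 1e-10]
  if (length(preds) < 2) return(empty)
  design <- assemble_design(basis, preds, seq_len(n))
  base <- fit_penalized(y, design)
  P0 <- penalty_total(design, base$sp)
  df_t <- (k_int - 1)^2
  out <- empty
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
    if (!a %in% preds || !b %in% preds) next
    if (n - (ncol(design$X) + df_t) < min_resid_df) {
      message("pair ", a, ":", b, " skipped: insufficient samples ",
              "for the bivariate basis")
      next
    }
    key <- paste(a, b, sep = "|")
    ib <- if (!is.null(ti_cache) && !is.null(ti_cache[[key]]))
      ti_cache[[key]]
    else make_interaction_basis(tf_matrix, a, b, k_int = k_int, fx = TRUE)
    if (!is.null(ti_cache)) ti_cache[[key]] <- ib
    Xf <- cbind(design$X, ib$X)
    Pf <- matrix(0, ncol(Xf), ncol(Xf))
    Pf[seq_len(ncol(design$X)), seq_len(ncol(design$X))] <- P0
    A <- crossprod(Xf) + Pf
    beta <- tryCatch(solve(A, crossprod(Xf, y)), error = function(e) NULL)
    if (is.null(beta)) {
      message("pair ", a, ":", b, " skipped: singular augmented design")
      next
    }
    rss1 <- sum((y - drop(Xf %*% beta))^2)
    edf1 <- sum(diag(solve(A, crossprod(Xf))))
    f_stat <- ((base$rss - rss1) / df_t) / (rss1 / (n - edf1))
    p <- if (n - edf1 < 1 || f_stat <= 0 || rss1 <= 0) 1 else
      stats::pf(f_stat, df_t, n - edf1, lower.tail = FALSE)
    out <- rbind(out, data.frame(tf_a = a, tf_b = b, p_value = p,
                                 edf_int = df_t, significant = p < 0.01,
                                 stringsAsFactors = FALSE))
  }
  out
}
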