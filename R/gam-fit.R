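# Penalized-spline fitting machinery.
#
# Built directly on mgcv's constructor-level API (smoothCon / magic /
# PredictMat) instead of the gam() wrapper: the null-model battery refits the
# same additive structure tens of thousands of times and the wrapper's
# formula handling dominates runtime.  magic() performs the same GCV
# smoothness selection as gam(method = "GCV.Cp") and reproduces its
# coefficients on identical bases.

# Basis dimension per smooth term: capped so a 38-cell-type panel stays
# identifiable; below 3 the term degrades to a plain linear term.
basis_dim <- function(n_samples, cap = 8) min(cap, n_samples %/% 3L)

# Build cubic-regression-spline bases for a set of TFs over the full sample
# panel.  Knot placement depends only on predictor values (never on the
# response), so bases can be shared across genes, CV folds and null
# replicates without information leakage.
make_tf_basis <- function(tf_matrix, tfs = features(tf_matrix), basis_cap = 8) {
  n <- ncol(tf_matrix$values)
  k <- basis_dim(n, basis_cap)
  out <- lapply(tfs, function(tf) {
    x <- tf_matrix$values[tf, ]
    if (k < 3 || length(unique(x)) <= k)
      return(list(tf = tf, linear = TRUE, x = x, range = range(x)))
    sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k),
                          data = data.frame(x = x),
                          absorb.cons = TRUE)[[1]]
    list(tf = tf, linear = FALSE, sm = sm, X = sm$X, S = sm$S[[1]],
         x = x, range = range(x))
  })
  names(out) <- tfs
  out
}

# Tensor-product interaction basis (main effects excluded) for a TF pair.
# fx = TRUE gives an unpenalized block with exactly (k_int - 1)^2 df, which
# the interaction test needs for a calibrated fixed-df F comparison.
make_interaction_basis <- function(tf_matrix, tf_a, tf_b, k_int = 4,
                                   fx = FALSE) {
  x <- tf_matrix$values[tf_a, ]
  z <- tf_matrix$values[tf_b, ]
  sm <- mgcv::smoothCon(mgcv::ti(x, z, bs = c("cr", "cr"),
                                 k = c(k_int, k_int), fx = fx),
                        data = data.frame(x = x, z = z),
                        absorb.cons = TRUE)[[1]]
  list(tf_a = tf_a, tf_b = tf_b, sm = sm, X = sm$X,
       S = if (fx) list() else sm$S)
}

# Assemble the design for given TF terms and (optional) interaction terms on
# a row subset; returns X, penalty list and term index blocks.
assemble_design <- function(basis, tfs, rows, inter = list()) {
  X <- matrix(1, length(rows), 1)
  S <- list(); off <- integer(); blocks <- list(intercept = 1L)
  for (tf in tfs) {
    b <- basis[[tf]]
    if (b$linear) {
      X <- cbind(X, b$x[rows])
      blocks[[tf]] <- ncol(X)
    } else {
      idx <- ncol(X) + seq_len(ncol(b$X))
      X <- cbind(X, b$X[rows, , drop = FALSE])
      S[[length(S) + 1L]] <- b$S
      off <- c(off, idx[1])
      blocks[[tf]] <- idx
    }
  }
  for (ib in inter) {
    idx <- ncol(X) + seq_len(ncol(ib$X))
    X <- cbind(X, ib$X[rows, , drop = FALSE])
    for (Sj in ib$S) {
      S[[length(S) + 1L]] <- Sj
      off <- c(off, idx[1])
    }
    blocks[[paste(ib$tf_a, ib$tf_b, sep = ":")]] <- idx
  }
  list(X = X, S = S, off = off, blocks = blocks)
}

# Penalized least squares with GCV smoothness selection; falls back to plain
# least squares when there is nothing to penalize.  Returns coefficients,
# fitted values, RSS and effective degrees of freedom (total and per column).
# gamma = 1.4 inflates the per-df cost in the GCV score, the standard remedy
# for GCV's tendency to undersmooth at modest sample sizes.
fit_penalized <- function(y, design, gamma = 1.4) {
  X <- design$X
  n <- length(y)
  if (!length(design$S)) {
    qr_fit <- stats::lm.fit(X, y)
    coef <- qr_fit$coefficients
    coef[is.na(coef)] <- 0
    fitted <- drop(X %*% coef)
    edf_col <- rep(1, ncol(X))  # unpenalized: one df per estimable column
    edf_col[is.na(qr_fit$coefficients)] <- 0
    return(list(coef = coef, fitted = fitted,
                rss = sum((y - fitted)^2),
                edf = sum(edf_col), edf_col = edf_col, sp = numeric()))
  }
  b <- mgcv::magic(y, X, sp = rep(-1, length(design$S)),
                   S = design$S, off = design$off, gcv = TRUE,
                   gamma = gamma)
  fitted <- drop(X %*% b$b)
  XtX <- crossprod(X)
  # (X'X + S_lambda)^{-1} = rV rV'; per-coefficient edf is
  # diag((X'X + S_lambda)^{-1} X'X).
  M <- t(b$rV) %*% XtX
  edf_col <- rowSums(b$rV * t(M))
  list(coef = b$b, fitted = fitted, rss = sum((y - fitted)^2),
       edf = sum(edf_col), edf_col = edf_col, sp = b$sp)
}

# Prediction design matrix rows for new samples, mirroring assemble_design.
predict_design <- function(basis, tfs, tf_matrix, samples, inter = list(),
                           clamp = FALSE) {
  X <- matrix(1, length(samples), 1)
  extrapolated <- rep(FALSE, length(samples))
  for (tf in tfs) {
    b <- basis[[tf]]
    x <- tf_matrix$values[tf, samples]
    outside <- x < b$range[1] | x > b$range[2]
    extrapolated <- extrapolated | outside
    if (clamp) x <- pmin(pmax(x, b$range[1]), b$range[2])
    if (b$linear) {
      X <- cbind(X, x)
    } else {
      X <- cbind(X, mgcv::PredictMat(b$sm, data.frame(x = x)))
    }
  }
  for (ib in inter) {
    x <- tf_matrix$values[ib$tf_a, samples]
    z <- tf_matrix$values[ib$tf_b, samples]
    X <- cbind(X, mgcv::PredictMat(ib$sm, data.frame(x = x, z = z)))
  }
  list(X = X, extrapolated = extrapolated)
}

# Total penalty matrix at given smoothing parameters (magic's ordering).
penalty_total <- function(design, sp) {
  p <- ncol(design$X)
  P <- matrix(0, p, p)
  for (j in seq_along(design$S)) {
    idx <- design$off[j] + seq_len(ncol(design$S[[j]])) - 1L
    P[idx, idx] <- P[idx, idx] + sp[j] * design$S[[j]]
  }
  P
}

# Penalized least-squares coefficients at fixed smoothing parameters; adds a
# small ridge on (near-)singular systems.
pls_coef <- function(X, y, P) {
  A <- crossprod(X) + P
  b <- crossprod(X, y)
  tryCatch(solve(A, b), error = function(e)
    solve(A + diag(1e-8 * max(diag(A)), ncol(A)), b))
}
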