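test_that("specs are built per CRM-gene link with sorted predictors", {
  crms <- data.frame(crm_id = c("c1", "c2"), chrom = "chr1",
                     start = c(0L, 500L), end = c(100L, 600L),
                     center = c(50L, 550L), n_sites = 2L, n_tfs = 2L,
                     tfs = c("TF02,TF01", "TF01,TF99"),
                     stringsAsFactors = FALSE)
  links <- data.frame(crm_id = c("c1", "c1", "c2"),
                      gene_id = c("g1", "g2", "g2"),
                      distance = c(0L, 10L, -5L), stringsAsFactors = FALSE)
  tf <- tiny_panel(1, n_tf = 3)
  rownames(tf$values) <- c("TF01", "TF02", "TF03")
  expect_warning(specs <- build_model_specs(links, crms, tf), "dropped")
  expect_equal(nrow(specs), 2)  # c2 contains TF99 with no expression row
  expect_equal(unique(specs$predictors), "TF01,TF02")
  # gene with two CRMs would get two specs when both are modelable
  crms$tfs[2] <- "TF03,TF01"
  specs2 <- build_model_specs(links, crms, tf)
  expect_equal(nrow(specs2), 3)
  expect_equal(sum(specs2$gene_id == "g2"), 2)
})

test_that("a noiseless single-predictor signal is recovered exactly", {
  tf <- tiny_panel(2, n_tf = 2, n_ct = 12)
  genes <- gene_panel_from(tf, "gLin",
                           list(function(x) 2 * x["TF01", ]), noise = 0)
  m <- fit_gene_model(spec_for("gLin", "TF01"), tf, genes)
  r2 <- r_squared(m$fitted, m$y)
  expect_gte(r2, 0.999)
  # intercept is 0 for mean-centered data, smooth terms centered
  expect_lt(abs(m$beta0), 1e-8)
  expect_lt(abs(mean(m$fitted)), 1e-8)
})

test_that("a smooth nonlinear response is learned from 40 samples", {
  tf <- tiny_panel(3, n_tf = 2, n_ct = 20)
  genes <- gene_panel_from(tf, "gSin",
                           list(function(x) sin(pi * x["TF01", ])),
                           noise = 0.1, seed = 30)
  cv <- kfold_cv(spec_for("gSin", "TF01"), tf, genes, k = 5, seed = 9)
  expect_gte(cv$mean_r2, 0.8)
})

test_that("constant predictors are dropped with a warning", {
  tf <- tiny_panel(4, n_tf = 2, n_ct = 8)
  tf$values["TF02", ] <- 0
  genes <- gene_panel_from(tf, "g1", list(function(x) x["TF01", ]),
                           noise = 0)
  expect_warning(
    m <- fit_gene_model(spec_for("g1", c("TF01", "TF02")), tf, genes),
    "constant")
  expect_equal(m$predictors, "TF01")
  expect_gte(r_squared(m$fitted, m$y), 0.999)
})

test_that("spline fits agree with least squares on linear truth", {
  # independent observations (replicate-collapsed panel) so GCV sees the
  # true residual df; on linear truth the smooths then collapse to lines
  set.seed(55)
  sigma <- 0.3
  n <- 38
  ids <- sprintf("ct%02d", 1:n)
  rmap <- setNames(ids, ids)
  X <- rbind(TF01 = rnorm(n), TF02 = rnorm(n))
  colnames(X) <- ids
  tf <- mean_center(expression_matrix(X, rmap))
  y <- X["TF01", ] - 0.5 * X["TF02", ] + rnorm(n, 0, sigma)
  genes <- mean_center(expression_matrix(
    matrix(y, 1, dimnames = list("g1", ids)), rmap))
  m <- fit_gene_model(spec_for("g1", c("TF01", "TF02")), tf, genes)
  Xd <- cbind(1, t(tf$values))
  ols <- stats::lm.fit(Xd, genes$values["g1", ])
  expect_lt(max(abs(m$fitted - drop(Xd %*% ols$coefficients))), 0.05 * sigma)
})

test_that("prediction on training data with noiseless truth has ~0 MSPE", {
  tf <- tiny_panel(6, n_tf = 1, n_ct = 10)
  genes <- gene_panel_from(tf, "g1", list(function(x) 3 * x["TF01", ]),
                           noise = 0)
  sp <- spec_for("g1", "TF01")
  m <- fit_gene_model(sp, tf, genes)
  pr <- predict(m, tf, samples(tf), genes)
  expect_lt(pr$mspe, 1e-4)
  expect_error(predict(m, tf, character(0)), "empty test set")
})

test_that("extrapolation beyond the training range is flagged", {
  tf <- tiny_panel(7, n_tf = 1, n_ct = 10)
  genes <- gene_panel_from(tf, "g1", list(function(x) x["TF01", ]),
                           noise = 0)
  sp <- spec_for("g1", "TF01")
  train <- samples(tf)[1:16]
  m <- fit_gene_model(sp, tf, genes, training_samples = train)
  test <- setdiff(samples(tf), train)
  tf$values["TF01", test[1]] <- max(tf$values["TF01", train]) + 5
  pr <- predict(m, tf, test, genes)
  expect_true(pr$extrapolated[1])
  prc <- predict(m, tf, test, genes, clamp = TRUE)
  # clamped prediction equals the boundary prediction
  bnd <- max(tf$values["TF01", train])
  tf2 <- tf; tf2$values["TF01", test[1]] <- bnd
  expect_equal(unname(prc$y_hat[1]),
               unname(predict(m, tf2, test[1:2], genes)$y_hat[1]))
})

test_that("cross-validated accuracy degrades monotonically with noise", {
  tf <- tiny_panel(8, n_tf = 2, n_ct = 15)
  mean_r2_at <- function(sigma, n_genes = 40) {
    r2 <- vapply(seq_len(n_genes), function(i) {
      g <- gene_panel_from(tf, "g",
                           list(function(x) x["TF01", ] + x["TF02", ]^2 / 2),
                           noise = sigma, seed = 1000 * sigma + i)
      kfold_cv(spec_for("g", c("TF01", "TF02")), tf, g, k = 5,
               seed = 5)$mean_r2
    }, 0)
    mean(r2)
  }
  r2s <- vapply(c(0, 0.5, 1, 2), mean_r2_at, 0)
  expect_true(all(diff(r2s) < 0))
})

test_that("the nonlinearity test flags curvature and spares linearity", {
  tf <- tiny_panel(9, n_tf = 2, n_ct = 19)
  quad <- gene_panel_from(tf, "gQ",
                          list(function(x) x["TF01", ]^2), noise = 0.1,
                          seed = 5)
  nt <- nonlinearity_test(spec_for("gQ", c("TF01", "TF02")), tf, quad)
  expect_lt(nt$p_value, 0.01)
  expect_true(nt$nonlinear)
  # clean linear signal: usually not flagged (full type-I study elsewhere)
  lin <- gene_panel_from(tf, "gL", list(function(x) x["TF01", ]),
                         noise = 0.3, seed = 6)
  nl <- nonlinearity_test(spec_for("gL", c("TF01", "TF02")), tf, lin)
  expect_gte(nl$p_value, 0.01)
})

test_that("interaction testing needs two predictors and finds products", {
  tf <- tiny_panel(10, n_tf = 3, n_ct = 38)
  expect_equal(nrow(interaction_test(spec_for("g", "TF01"), tf,
                                     tiny_panel(10, 1, 38))), 0)
  prod_g <- gene_panel_from(
    tf, "gP", list(function(x) x["TF01", ] * x["TF02", ]),
    noise = 0.2, seed = 8)
  it <- interaction_test(spec_for("gP", c("TF01", "TF02")), tf, prod_g)
  expect_equal(nrow(it), 1)
  expect_lt(it$p_value, 0.01)
  add_g <- gene_panel_from(
    tf, "gA", list(function(x) x["TF01", ] + tanh(x["TF02", ])),
    noise = 0.2, seed = 9)
  it2 <- interaction_test(spec_for("gA", c("TF01", "TF02")), tf, add_g)
  expect_gte(it2$p_value, 0.01)
})

test_that("r_squared and mspe follow their definitions", {
  expect_equal(mspe(c(1, 2), c(1, 2)), 0)
  expect_equal(mspe(c(2, 3), c(1, 2)), 1)
  expect_equal(mspe(c(0, 0), c(1, 3)), 5)
  expect_error(mspe(numeric(0), numeric(0)), "empty")
  expect_equal(r_squared(c(1, 2, 4), c(2, 4, 8)), 1)
  expect_error(r_squared(1, 1), "2 points")
  expect_equal(r_squared(rep(1, 3), c(1, 2, 3)), 0)
})
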