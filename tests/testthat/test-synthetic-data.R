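test_that("genome simulation is deterministic and respects its config", {
  cfg <- simulation_config(seed = 7, n_genes = 40)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$annotation), 40)
  expect_true(all(diff(sort(s1$annotation$tss[s1$annotation$chrom ==
                                                "chr1"])) >=
                    cfg$min_tss_spacing %/% 2))
  # regulated genes have planted sites within 1kb of their TSS in line A
  gt <- s1$ground_truth
  for (i in which(gt$genes$regulated)) {
    g <- gt$genes[i, ]
    sites <- gt$planted_sites[gt$planted_sites$gene_id == g$gene_id, ]
    expect_setequal(sort(unique(sites$tf)),
                    strsplit(g$regulators, ",")[[1]])
    expect_true(all(abs(sites$pos - g$tss) <= 1000))
  }
  # motif table flags every true (regulator, gene) pair
  truth_pairs <- unlist(lapply(which(gt$genes$regulated), function(i)
    paste(strsplit(gt$genes$regulators[i], ",")[[1]],
          gt$genes$gene_id[i])))
  expect_true(all(truth_pairs %in% paste(gt$motif$tf, gt$motif$gene_id)))
  expect_error(simulate_genome(simulation_config(seed = 1, n_genes = 5000)),
               "too small")
})

test_that("zero enrichment plants no CRMs", {
  cfg <- simulation_config(seed = 8, n_genes = 30, enrichment_factor = 0)
  s <- simulate_genome(cfg)
  expect_equal(nrow(s$ground_truth$planted_sites), 0)
  expect_false(any(s$ground_truth$genes$regulated))
})

test_that("CRM detection recovers planted modules from default tracks", {
  cfg <- simulation_config(seed = 9, n_genes = 80)
  s <- simulate_genome(cfg)
  crms <- detect_crms(s$peaks)
  gt <- s$ground_truth
  planted <- split(gt$planted_sites, gt$planted_sites$gene_id)
  hits <- vapply(planted, function(ps) {
    cand <- crms[crms$chrom == ps$chrom[1] &
                   crms$start <= max(ps$pos) & crms$end >= min(ps$pos), ,
                 drop = FALSE]
    any(vapply(tf_sets(cand), function(ts)
      all(unique(ps$tf) %in% ts), TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("binding perturbation hits the requested dissimilarity", {
  cfg <- simulation_config(seed = 10, n_genes = 100)
  s <- simulate_genome(cfg)
  p0 <- perturb_binding(s, 0, seed = 1)
  expect_true(all(p0$realized$realized == 0))
  p1 <- perturb_binding(s, 1, seed = 1)
  expect_true(all(p1$realized$realized == 1))
  p5 <- perturb_binding(s, 0.5, seed = 1)
  expect_gte(mean(p5$realized$realized), 0.4)
  expect_lte(mean(p5$realized$realized), 0.6)
  # monotone in the target
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t)
    mean(perturb_binding(s, t, seed = 2)$realized$realized), 0)
  expect_true(all(diff(means) > 0))
})

test_that("expression simulation matches its declared generative model", {
  cfg <- simulation_config(seed = 11, n_genes = 40, noise_sigma = 0,
                           response_library = "linear",
                           fraction_interacting = 0)
  s <- simulate_genome(cfg)
  e <- simulate_expression(cfg, s$ground_truth)
  gt <- s$ground_truth$genes
  # noiseless linear responses: gene cell-type values are exact linear
  # combinations of the regulators' cell-type values
  for (g in head(gt$gene_id[gt$regulated], 5)) {
    reg <- strsplit(gt$regulators[gt$gene_id == g], ",")[[1]]
    fit <- stats::lm.fit(cbind(1, t(e$tf_cell_values[reg, , drop = FALSE])),
                         e$gene_cell_values[g, ])
    expect_lt(max(abs(fit$residuals)), 1e-9)
  }
  # replicates correlate strongly at replicate noise 0.1 and signal SD ~1
  cfg2 <- simulation_config(seed = 12, n_genes = 40)
  s2 <- simulate_genome(cfg2)
  e2 <- simulate_expression(cfg2, s2$ground_truth)
  r1 <- samples(e2$gene_matrix)[c(TRUE, FALSE)]
  r2 <- samples(e2$gene_matrix)[c(FALSE, TRUE)]
  cors <- vapply(seq_len(nrow(e2$gene_matrix$values)), function(i)
    cor(e2$gene_matrix$values[i, r1], e2$gene_matrix$values[i, r2]), 0)
  expect_gt(mean(cors), 0.9)
})

test_that("with no regulated genes expression is independent of the TFs", {
  cfg <- simulation_config(seed = 13, n_genes = 120,
                           fraction_regulated = 0)
  s <- simulate_genome(cfg)
  e <- simulate_expression(cfg, s$ground_truth)
  cors <- abs(cor(t(e$gene_cell_values), t(e$tf_cell_values)))
  # max |cor| over 120 x 14 pairs at n = 38 consistent with the null
  expect_lt(max(cors), 0.75)
  expect_lt(mean(cors), 0.2)
})

test_that("fixture bundles round-trip through the readers", {
  cfg <- simulation_config(seed = 14, n_genes = 20)
  dir <- withr::local_tempdir()
  paths <- make_fixture_bundle(cfg, file.path(dir, "b"))
  expect_true(all(file.exists(paths)))
  ann <- read_annotation(paths["annotation"])
  expect_equal(nrow(ann), 20)
  tfm <- read_expression(paths["tf_expression"], paths["replicate_map"])
  expect_equal(dim(tfm), c(14L, 76L))
  pk <- read_peaks(paths[["peaks_A_TF01"]], "TF01")
  expect_gt(nrow(pk), 0)
  # refusing to overwrite without force
  expect_error(make_fixture_bundle(cfg, file.path(dir, "b")), "force")
  # same seed -> identical manifests
  p2 <- make_fixture_bundle(cfg, file.path(dir, "c"))
  expect_identical(readLines(paths["truth_genes"]),
                   readLines(p2["truth_genes"]))
  expect_identical(readLines(paths[["peaks_B_TF01"]]),
                   readLines(p2[["peaks_B_TF01"]]))
  # manifest regulator sets match the planted site TF sets
  genes <- utils::read.table(paths["truth_genes"], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  sites <- utils::read.table(paths["truth_sites"], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  for (g in genes$gene_id[genes$regulated]) {
    expect_equal(sort(strsplit(genes$regulators[genes$gene_id == g],
                               ",")[[1]]),
                 sort(unique(sites$tf[sites$gene_id == g])))
  }
})
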