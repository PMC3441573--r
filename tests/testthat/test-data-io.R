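test_that("read_peaks parses BED-like files and validates coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t900\t1000", "chr2\t5\t50"), f)
  p <- read_peaks(f, "GATA2")
  expect_equal(nrow(p), 3)
  expect_equal(p$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(p$start, c(100L, 900L, 5L))
  expect_equal(p$end, c(200L, 1000L, 50L))
  expect_true(all(p$tf == "GATA2"))

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_peaks(empty, "X")), 0)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_peaks(bad, "X"), "line 2.*start >= end")
  writeLines("chr1\tfoo\t200", bad)
  expect_error(read_peaks(bad, "X"), "line 1.*non-integer")
})

test_that("peaks survive a write/read round trip", {
  p <- data.frame(chrom = c("chr1", "chr2"), start = c(10L, 30L),
                  end = c(20L, 45L), tf = "NFE2", score = c(1.5, 2),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_peaks(p, f)
  expect_equal(read_peaks(f, "NFE2"), p)
})

test_that("read_expression attaches the replicate map and rejects bad input", {
  m <- withr::local_tempfile(); rm <- withr::local_tempfile()
  writeLines(c("feature_id\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4", "gB\t4\t3\t2\t1"), m)
  writeLines(c("sample_id\tcell_type", "s1\tct1", "s2\tct1",
               "s3\tct2", "s4\tct2"), rm)
  em <- read_expression(m, rm)
  expect_equal(dim(em), c(2L, 4L))
  expect_equal(unname(em$replicate_map["s3"]), "ct2")

  writeLines("feature_id\ts1\ts2", m)
  expect_error(read_expression(m, rm), "no features")

  writeLines(c("feature_id\ts1\ts5", "gA\t1\t2"), m)
  expect_error(read_expression(m, rm), "s5")

  writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), m)
  expect_error(read_expression(m, rm), "duplicate")
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- expression_matrix(m, setNames(c("a", "b"), c("s1", "s2")))
  qn <- quantile_normalize(em)
  expect_equal(unname(qn$values),
               matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
  # idempotence
  expect_equal(quantile_normalize(qn)$values, qn$values)
  # single column unchanged; identical columns unchanged
  one <- expression_matrix(m[, 1, drop = FALSE],
                           setNames("a", "s1"))
  expect_equal(quantile_normalize(one)$values, one$values)
  same <- expression_matrix(cbind(s1 = c(g1 = 2, g2 = 7),
                                  s2 = c(g1 = 2, g2 = 7)),
                            setNames(c("a", "b"), c("s1", "s2")))
  expect_equal(quantile_normalize(same)$values, same$values)
  # all columns share one sorted multiset after normalization
  set.seed(1)
  big <- expression_matrix(
    matrix(rnorm(50), 10, 5,
           dimnames = list(paste0("g", 1:10), paste0("s", 1:5))),
    setNames(rep("ct", 5), paste0("s", 1:5)))
  qb <- quantile_normalize(big)$values
  for (j in 2:5) expect_equal(unname(sort(qb[, j])), unname(sort(qb[, 1])))
})

test_that("probe selection keeps the most variable probe per gene", {
  m <- rbind(p1 = c(0, 0.5, 1, 1.5), p2 = c(0, 1, 2, 3),
             p3 = c(5, 5, 5, 6))
  colnames(m) <- paste0("s", 1:4)
  em <- expression_matrix(m, setNames(rep("ct", 4), colnames(m)))
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("gA", "gA", "gB"))
  sel <- select_probe_per_gene(em, pm)
  expect_equal(features(sel), c("gA", "gB"))
  expect_equal(unname(sel$values["gA", ]), unname(m["p2", ]))  # var 1.67 > 0.42
  # exact tie -> lexicographically smallest probe id
  m2 <- rbind(pB = c(0, 1), pA = c(10, 11))
  colnames(m2) <- c("s1", "s2")
  em2 <- expression_matrix(m2, setNames(rep("ct", 2), colnames(m2)))
  pm2 <- data.frame(probe_id = c("pB", "pA"), gene_id = "gX")
  expect_equal(unname(select_probe_per_gene(em2, pm2)$values["gX", ]),
               unname(m2["pA", ]))
  # gene with no probe present -> warning, omitted
  pm3 <- rbind(pm2, data.frame(probe_id = "pZ", gene_id = "gGone"))
  expect_warning(sel3 <- select_probe_per_gene(em2, pm3), "gGone")
  expect_equal(features(sel3), "gX")
})

test_that("mean centering zeroes every feature row and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1))
  colnames(m) <- paste0("s", 1:3)
  em <- expression_matrix(m, setNames(rep("ct", 3), colnames(m)))
  cc <- mean_center(em)
  expect_equal(unname(cc$values["a", ]), c(-1, 0, 1))
  expect_equal(unname(cc$values["b", ]), c(0, 0, 0))
  expect_equal(unname(cc$values["c", ]), c(-1, 0, 1))
  expect_equal(mean_center(cc)$values, cc$values)
})
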