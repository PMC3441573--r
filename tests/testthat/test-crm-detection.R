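test_that("binding sites sit at floored peak centers", {
  p <- data.frame(chrom = "chr1", start = c(100L, 100L), end = c(200L, 201L),
                  tf = "A", score = NA_real_)
  s <- peaks_to_sites(p)
  expect_equal(s$pos, c(150L, 150L))
  expect_equal(nrow(peaks_to_sites(p[0, ])), 0)
})

test_that("site chaining follows the 500bp single-linkage rule", {
  s <- data.frame(tf = c("A", "B", "C"), chrom = "chr1",
                  pos = c(100L, 550L, 1200L), stringsAsFactors = FALSE)
  g <- group_sites(s)
  expect_equal(as.vector(table(g$group)), c(2L, 1L))
  # gap of exactly 500 still chains
  s2 <- data.frame(tf = c("A", "B"), chrom = "chr1", pos = c(0L, 500L))
  expect_equal(length(unique(group_sites(s2)$group)), 1L)
  s3 <- data.frame(tf = c("A", "B"), chrom = "chr1", pos = c(0L, 501L))
  expect_equal(length(unique(group_sites(s3)$group)), 2L)
  # different chromosomes never chain
  s4 <- data.frame(tf = c("A", "B"), chrom = c("chr1", "chr2"),
                   pos = c(0L, 10L))
  expect_equal(length(unique(group_sites(s4)$group)), 2L)
  # partition property: union of groups is the input, groups disjoint
  s5 <- random_sites(7, n_sites = 40)
  g5 <- group_sites(s5)
  expect_equal(nrow(g5), nrow(s5))
  expect_setequal(paste(g5$chrom, g5$pos, g5$tf),
                  paste(s5$chrom, s5$pos, s5$tf))
})

test_that("CRM calling needs two distinct TFs and records spans", {
  one_tf <- data.frame(tf = c("A", "A"), chrom = "chr1",
                       pos = c(100L, 300L), stringsAsFactors = FALSE)
  expect_equal(nrow(call_crms(group_sites(one_tf))), 0)
  two <- data.frame(tf = c("A", "B"), chrom = "chr1", pos = c(100L, 550L),
                    stringsAsFactors = FALSE)
  crm <- call_crms(group_sites(two))
  expect_equal(crm$tfs, "A,B")
  expect_equal(c(crm$start, crm$end, crm$center), c(100L, 550L, 325L))
  # duplicate TF sites retained as sites, counted once in the set
  dup <- data.frame(tf = c("A", "A", "B"), chrom = "chr1",
                    pos = c(100L, 200L, 300L), stringsAsFactors = FALSE)
  crm2 <- call_crms(group_sites(dup))
  expect_equal(crm2$n_sites, 3L)
  expect_equal(crm2$n_tfs, 2L)
})

test_that("CRM detection matches the brute-force single-linkage oracle", {
  for (seed in 1:25) {
    sites <- random_sites(seed, n_sites = sample(10:50, 1))
    got <- crms_as_canonical(call_crms(group_sites(sites)))
    want <- brute_force_crms(sites)
    expect_equal(got, unname(want), info = paste("seed", seed))
  }
})

test_that("promoter mapping uses an inclusive 1kb window with strand sign", {
  crms <- data.frame(crm_id = c("c1", "c2", "c3"), chrom = "chr1",
                     start = c(5000L, 8000L, 20000L),
                     end = c(5100L, 8100L, 20100L),
                     center = c(5050L, 8050L, 20050L),
                     n_sites = 2L, n_tfs = 2L, tfs = "A,B",
                     stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    tss = c(5050L, 9050L, 21550L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  links <- map_crms_to_genes(crms, ann, window = 1000)
  # g1: distance 0; g2: center exactly 1000 upstream, minus strand flips sign
  expect_equal(nrow(links), 2)
  expect_equal(links$distance[links$gene_id == "g1"], 0L)
  expect_equal(links$distance[links$gene_id == "g2"], 1000L)
  # 1500bp away is not linked
  expect_false("g3" %in% links$gene_id)
})

test_that("planted TF combinations beat the permutation null", {
  set.seed(11)
  # 20 CRMs with the planted pair, 100 background CRMs with random labels
  mk <- function(i, tfs) data.frame(tf = tfs, chrom = "chr1",
                                    pos = as.integer(i * 5000 + c(0, 100)),
                                    stringsAsFactors = FALSE)
  planted <- do.call(rbind, lapply(1:20, mk, tfs = c("A", "B")))
  bg <- do.call(rbind, lapply(21:120, function(i)
    mk(i, sample(LETTERS[1:8], 2))))
  crms <- call_crms(group_sites(rbind(planted, bg)))
  stats <- combination_significance(crms, B = 500, seed = 3)
  expect_lte(stats$p_value[stats$tfs == "A,B"], 0.005)
  # minimum attainable p is 1/(B+1)
  expect_gte(min(stats$p_value), 1 / 501)
  # p in (0, 1]
  expect_true(all(stats$p_value > 0 & stats$p_value <= 1))
})

test_that("unbreakable label configurations give p = 1", {
  # a single CRM: any permutation of its two labels reproduces the same
  # tf_set, so the null count always equals the observed count
  crms <- call_crms(group_sites(data.frame(
    tf = c("A", "B"), chrom = "chr1", pos = c(0L, 100L),
    stringsAsFactors = FALSE)))
  stats <- combination_significance(crms, B = 50, seed = 1)
  expect_equal(stats$p_value, 1)
  expect_error(combination_significance(crms, B = 0, seed = 1), "B")
})

test_that("permutation p-values are calibrated under exchangeability", {
  # fully random label assignments: the observed count of any fixed
  # combination is itself a draw from the permutation null, so its p-value
  # is (conservatively, given discreteness) uniform.  A combination not
  # observed at all has count 0 and hence p = 1.
  set.seed(42)
  pvals <- replicate(150, {
    sites <- data.frame(
      tf = sample(LETTERS[1:4], 30, replace = TRUE), chrom = "chr1",
      pos = as.integer(seq(0, by = 5000, length.out = 15)[
        rep(1:15, each = 2)] + c(0, 100)))
    crms <- call_crms(group_sites(sites))
    st <- combination_significance(crms, B = 100, seed = sample(1e6, 1))
    if ("A,B" %in% st$tfs) st$p_value[st$tfs == "A,B"] else 1
  })
  expect_lte(mean(pvals < 0.05), 0.09)
  expect_gte(mean(pvals), 0.4)
})
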