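test_that("Hamming and Jaccard distances follow their definitions", {
  expect_equal(unname(crm_distance("A,B,C", "A,B,C")), c(0, 0))
  expect_equal(unname(crm_distance("A,B,C", "A,B,D")), c(2, 0.5))
  expect_equal(unname(crm_distance("A,B", "C,D")), c(4, 1))
  expect_error(crm_distance(character(0), character(0)), "empty")
})

test_that("jaccard equals hamming over union size on random set pairs", {
  set.seed(14)
  univ <- LETTERS[1:10]
  for (i in 1:300) {
    a <- sample(univ, sample(1:6, 1))
    b <- sample(univ, sample(1:6, 1))
    d <- crm_distance(a, b)
    expect_equal(d["jaccard"],
                 d["hamming"] / length(union(a, b)), ignore_attr = TRUE)
  }
})

test_that("Jaccard distance satisfies the triangle inequality", {
  set.seed(15)
  univ <- LETTERS[1:8]
  for (i in 1:300) {
    a <- sample(univ, sample(1:5, 1))
    b <- sample(univ, sample(1:5, 1))
    cc <- sample(univ, sample(1:5, 1))
    dab <- crm_distance(a, b)["jaccard"]
    dbc <- crm_distance(b, cc)["jaccard"]
    dac <- crm_distance(a, cc)["jaccard"]
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

mk_crms <- function(starts, ends, tfs, chrom = "chr1", prefix = "c") {
  df <- data.frame(
    crm_id = paste0(prefix, seq_along(starts)), chrom = chrom,
    start = as.integer(starts), end = as.integer(ends),
    center = as.integer((starts + ends) %/% 2),
    n_sites = 2L, n_tfs = lengths(strsplit(tfs, ",")), tfs = tfs,
    stringsAsFactors = FALSE)
  sites <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    tf <- strsplit(df$tfs[i], ",")[[1]]
    data.frame(crm_id = df$crm_id[i], tf = tf, chrom = df$chrom[i],
               pos = as.integer(seq(df$start[i], max(df$end[i], df$start[i] + 1),
                                    length.out = length(tf))),
               stringsAsFactors = FALSE)
  }))
  attr(df, "sites") <- sites
  df
}

test_that("reciprocal overlap pairing uses a strict 50% rule", {
  a <- mk_crms(0, 100, "A,B")
  b_edge <- mk_crms(50, 150, "A,C", prefix = "d")     # exactly 50% each
  expect_equal(nrow(find_overlapping_crms(a, b_edge)), 0)
  b_in <- mk_crms(20, 120, "A,C", prefix = "d")       # 80% each
  pairs <- find_overlapping_crms(a, b_in)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$frac_a, 0.8)
  expect_equal(pairs$hamming, 2)
  expect_equal(pairs$jaccard, 2 / 3)
  ident <- find_overlapping_crms(a, mk_crms(0, 100, "A,B", prefix = "d"))
  expect_equal(c(ident$frac_a, ident$frac_b, ident$jaccard), c(1, 1, 0))
})

test_that("overlap pairing is symmetric and resolves multi-hits", {
  a <- mk_crms(c(0, 300), c(200, 500), c("A,B", "B,C"))
  b <- mk_crms(c(10, 320), c(190, 480), c("A,C", "C,D"), prefix = "d")
  ab <- find_overlapping_crms(a, b)
  ba <- find_overlapping_crms(b, a)
  expect_setequal(paste(ab$crm_a, ab$crm_b), paste(ba$crm_b, ba$crm_a))
  expect_equal(ab$frac_a[order(ab$crm_a)], ba$frac_b[order(ba$crm_b)])
  # one a-CRM overlapping two b-CRMs pairs with the larger reciprocal overlap
  a2 <- mk_crms(0, 100, "A,B")
  b2 <- mk_crms(c(10, 40), c(110, 140), c("A,C", "B,D"), prefix = "d")
  p2 <- find_overlapping_crms(a2, b2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$crm_b, "d1")
})

test_that("permutation null of pair dissimilarity matches the hypergeometric law", {
  # both lines: two 2-site CRMs over the same 4 distinct labels; after a
  # global label permutation each CRM's set is a uniform 2-subset, so for a
  # fixed pair |A_perm ∩ B_perm| ~ Hypergeometric(4, 2, 2) independently on
  # both sides and Hamming = 4 - 2|intersection|
  a <- mk_crms(c(0, 1000), c(100, 1100), c("A,B", "C,D"))
  b <- mk_crms(c(10, 1010), c(110, 1110), c("A,B", "C,D"), prefix = "d")
  pairs <- find_overlapping_crms(a, b)
  expect_equal(nrow(pairs), 2)
  B <- 4000
  nd <- random_crm_dissimilarity(a, b, pairs, B = B, seed = 6)
  counts <- attr(nd, "null_counts")
  # distribution of one pair's hamming: sum over pairs / (2 * B)
  phat <- colSums(counts) / (2 * B)
  # intersection k in {0,1,2} with hypergeometric probs (1,4,1)/6;
  # hamming h = 4 - 2k -> P(0)=1/6, P(2)=4/6, P(4)=1/6
  want <- c(`0` = 1, `2` = 4, `4` = 1) / 6
  got <- setNames(phat, nd$hamming)[c("0", "2", "4")]
  expect_lt(max(abs(got - want)), 0.03)
  # parity: with shared 2-TF universes distances are always even
  expect_true(all(nd$hamming %% 2 == 0))
  # reproducibility with a fixed seed
  nd2 <- random_crm_dissimilarity(a, b, pairs, B = 100, seed = 6)
  nd3 <- random_crm_dissimilarity(a, b, pairs, B = 100, seed = 6)
  expect_identical(nd2, nd3)
  expect_warning(random_crm_dissimilarity(a, b, pairs, B = 10, seed = 1),
                 "band")
})

test_that("identical TF sets give MSPE ratios of 1; empty bins are omitted", {
  tf <- tiny_panel(21, n_tf = 4, n_ct = 12)
  g <- gene_panel_from(tf, "g0001",
                       list(function(x) x["TF01", ] + x["TF02", ]),
                       noise = 0.3, seed = 3)
  crms_a <- mk_crms(0, 400, "TF01,TF02")
  crms_b <- mk_crms(10, 410, "TF01,TF02", prefix = "d")
  links_a <- data.frame(crm_id = "c1", gene_id = "g0001", distance = 0L,
                        stringsAsFactors = FALSE)
  pairs <- find_overlapping_crms(crms_a, crms_b)
  dv <- dissimilarity_vs_error(pairs, crms_a, crms_b, links_a, tf, g,
                               target_cell_type = "ct01")
  expect_equal(dv$per_pair$ratio, 1)
  expect_equal(dv$bins$jaccard_bin, "0")
  expect_equal(dv$bins$median_ratio, 1)
})

test_that("DE-gene TF enrichment reproduces a hand-counted fixture", {
  # 30 classified genes: 10 over-expressed; TF X bound only in line B at 6
  # of them and at 6 unchanged genes: rate 12/30, expected 10 * 0.4 = 4
  genes <- sprintf("g%02d", 1:30)
  de <- setNames(rep("unchanged", 30), genes)
  de[1:10] <- "over_expressed"; de[11:15] <- "under_expressed"
  bound_b <- c(genes[1:6], genes[16:21])
  links_b <- data.frame(crm_id = paste0("b", seq_along(bound_b)),
                        gene_id = bound_b, distance = 0L,
                        stringsAsFactors = FALSE)
  crms_b <- mk_crms(seq(0, by = 1000, length.out = 12),
                    seq(100, by = 1000, length.out = 12),
                    rep("X,Y", 12), prefix = "b")
  # line A: X binds nowhere; Y binds the same genes (so Y is never specific)
  links_a <- data.frame(crm_id = paste0("a", seq_along(bound_b)),
                        gene_id = bound_b, distance = 0L,
                        stringsAsFactors = FALSE)
  crms_a <- mk_crms(seq(0, by = 1000, length.out = 12),
                    seq(100, by = 1000, length.out = 12),
                    rep("Y", 12), prefix = "a")
  crms_a$n_tfs <- 1L
  enr <- de_gene_tf_enrichment(links_a, links_b, crms_a, crms_b, de)
  row <- enr[enr$tf == "X" & enr$gene_class == "over_expressed" &
               enr$side == "only_B", ]
  expect_equal(row$observed, 6)
  expect_equal(row$expected, 4)
  expect_equal(row$ratio, 1.5)
  # Y is bound identically in both lines: no record
  expect_false("Y" %in% enr$tf)
  expect_error(de_gene_tf_enrichment(links_a, links_b, crms_a, crms_b,
                                     setNames(rep("unchanged", 3),
                                              genes[1:3])),
               "differentially expressed")
})

test_that("TF co-occurrence clustering matches brute-force average linkage", {
  # 4 TFs with hand-built co-occurrence: P,Q always together; R sometimes
  # with P,Q; S alone
  tfs <- c("P,Q", "P,Q,R", "P,Q", "R,S", "S,P")
  crms_a <- mk_crms(seq(0, by = 1000, length.out = 5),
                    seq(100, by = 1000, length.out = 5), tfs)
  crms_b <- crms_a[0, ]
  lk <- cluster_tf_cooccurrence(crms_a, crms_b, crms_a$crm_id)
  # P,Q co-occur in CRMs {1,2,3,5} and {1,2,3}: jaccard sim 3/4
  expect_equal(lk$dist["P", "Q"], 1 - 3 / 4)
  expect_equal(unname(diag(lk$dist)), rep(0, 4))
  expect_equal(lk$dist, t(lk$dist))
  # brute-force average linkage on the same matrix
  hc <- stats::hclust(stats::as.dist(lk$dist), method = "average")
  expect_equal(lk$hclust$merge, hc$merge)
  expect_equal(lk$hclust$height, hc$height)
  # two TFs always co-occurring merge first
  first <- sort(lk$hclust$labels[-lk$hclust$merge[1, ]])
  expect_equal(first, c("P", "Q"))
  # newick round trip
  f <- withr::local_tempfile()
  write_newick(lk, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, lk$tfs)
})

test_that("DE classification uses replicate-mean log differences", {
  tf <- tiny_panel(22, n_tf = 2, n_ct = 4)
  m <- matrix(0, 2, ncol(tf$values),
              dimnames = list(c("gUp", "gFlat"), samples(tf)))
  m["gUp", samples_of(tf, "ct02")] <- 2
  gm <- expression_matrix(m, tf$replicate_map)
  de <- classify_de(gm, "ct01", "ct02", threshold = 1)
  expect_equal(unname(de["gUp"]), "over_expressed")
  expect_equal(unname(de["gFlat"]), "unchanged")
})
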