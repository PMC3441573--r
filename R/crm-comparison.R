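#' Hamming and Jaccard dissimilarity between two TF sets
#'
#' Hamming distance: the number of TFs present in exactly one of the two
#' sets.  Jaccard distance: Hamming divided by the size of the union, i.e.
#' the proportion of TFs that differ.
#'
#' @param tfs_a,tfs_b character vectors of TF ids (or single comma-joined
#'   strings as stored in a CRM table).
#' @return A named numeric vector `c(hamming = ..., jaccard = ...)`.
#' @export
crm_distance <- function(tfs_a, tfs_b) {
  a <- unique(unlist(strsplit(as.character(tfs_a), ",", fixed = TRUE)))
  b <- unique(unlist(strsplit(as.character(tfs_b), ",", fixed = TRUE)))
  u <- union(a, b)
  if (!length(u)) stop("both TF sets are empty")
  h <- length(setdiff(a, b)) + length(setdiff(b, a))
  c(hamming = h, jaccard = h / length(u))
}

span_len <- function(crms) pmax(crms$end - crms$start, 1L)

#' Find reciprocally overlapping CRMs between two cell lines
#'
#' Two CRMs form a candidate pair when each span overlaps the other by
#' strictly more than `min_frac` of its own length (zero-length spans are
#' widened to 1 bp).  A CRM overlapping several partners is paired with the
#' one of larger reciprocal overlap (larger minimum fraction); ties go to the
#' partner with the smaller start coordinate.  Each pair carries the Hamming
#' and Jaccard dissimilarity of the TF sets.
#'
#' @param crms_a,crms_b CRM tables from [call_crms()] (same assembly).
#' @param min_frac reciprocal overlap threshold (default 0.5, strict).
#' @return A data frame with columns `crm_a`, `crm_b`, `frac_a`, `frac_b`,
#'   `hamming`, `jaccard`.
#' @export
find_overlapping_crms <- function(crms_a, crms_b, min_frac = 0.5) {
  empty <- data.frame(crm_a = character(), crm_b = character(),
                      frac_a = numeric(), frac_b = numeric(),
                      hamming = numeric(), jaccard = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(crms_a) || !nrow(crms_b)) return(empty)
  if (any(crms_a$end == crms_a$start) || any(crms_b$end == crms_b$start))
    message("zero-length CRM span(s) widened to 1 bp")
  cand <- list()
  for (ch in intersect(unique(crms_a$chrom), unique(crms_b$chrom))) {
    ca <- crms_a[crms_a$chrom == ch, , drop = FALSE]
    cb <- crms_b[crms_b$chrom == ch, , drop = FALSE]
    end_a <- pmax(ca$end, ca$start + 1L)
    end_b <- pmax(cb$end, cb$start + 1L)
    ov <- outer(end_a, end_b, pmin) - outer(ca$start, cb$start, pmax)
    hit <- which(ov > 0, arr.ind = TRUE)
    if (!nrow(hit)) next
    fa <- ov[hit] / span_len(ca)[hit[, 1]]
    fb <- ov[hit] / span_len(cb)[hit[, 2]]
    keep <- fa > min_frac & fb > min_frac
    if (!any(keep)) next
    cand[[ch]] <- data.frame(
      ia = ca$crm_id[hit[keep, 1]], ib = cb$crm_id[hit[keep, 2]],
      frac_a = fa[keep], frac_b = fb[keep],
      score = pmin(fa[keep], fb[keep]),
      start_a = ca$start[hit[keep, 1]], start_b = cb$start[hit[keep, 2]],
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start_a, cand$start_b), , drop = FALSE]
  used_a <- character(); used_b <- character(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$ia[i] %in% used_a || cand$ib[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$ia[i]); used_b <- c(used_b, cand$ib[i])
  }
  cand <- cand[keep, , drop = FALSE]
  ta <- crms_a$tfs[match(cand$ia, crms_a$crm_id)]
  tb <- crms_b$tfs[match(cand$ib, crms_b$crm_id)]
  d <- t(mapply(crm_distance, ta, tb))
  out <- data.frame(crm_a = cand$ia, crm_b = cand$ib,
                    frac_a = cand$frac_a, frac_b = cand$frac_b,
                    hamming = d[, "hamming"], jaccard = d[, "jaccard"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$crm_a), , drop = FALSE]
}

#' Null distribution of CRM dissimilarity under TF-label permutation
#'
#' Permutes TF labels across all CRM member sites genome-wide within each
#' cell line (preserving per-CRM site counts and per-TF totals), recomputes
#' the Hamming distance for every overlapping pair, and summarizes the
#' distribution of distances: for each distance value, the mean count of
#' pairs at that distance over permutations with a 2.5/97.5 percentile band.
#'
#' @param crms_a,crms_b CRM tables with `"sites"` attributes.
#' @param pairs overlapping pairs from [find_overlapping_crms()].
#' @param B number of permutations.
#' @param seed integer seed (required).
#' @return A data frame with columns `hamming`, `mean_count`, `q025`, `q975`,
#'   `observed_count`; the B x distances count matrix is attached as
#'   attribute `"null_counts"`.
#' @export
random_crm_dissimilarity <- function(crms_a, crms_b, pairs, B, seed) {
  if (missing(seed)) stop("'seed' is required for resampling")
  if (B < 40) warning("B < 40: percentile band unreliable")
  if (!nrow(pairs)) stop("no overlapping pairs supplied")
  sa <- attr(crms_a, "sites"); sb <- attr(crms_b, "sites")
  if (is.null(sa) || is.null(sb)) stop("CRM tables must carry member sites")
  ia <- split(seq_len(nrow(sa)), sa$crm_id)
  ib <- split(seq_len(nrow(sb)), sb$crm_id)
  max_h <- length(unique(c(sa$tf, sb$tf))) * 2
  counts <- matrix(0L, B, max_h + 1)
  set.seed(seed)
  for (b in seq_len(B)) {
    la <- sample(sa$tf); lb <- sample(sb$tf)
    h <- vapply(seq_len(nrow(pairs)), function(i) {
      ta <- unique(la[ia[[pairs$crm_a[i]]]])
      tb <- unique(lb[ib[[pairs$crm_b[i]]]])
      length(setdiff(ta, tb)) + length(setdiff(tb, ta))
    }, 0L)
    tab <- tabulate(h + 1L, nbins = max_h + 1)
    counts[b, ] <- tab
  }
  obs <- tabulate(pairs$hamming + 1L, nbins = max_h + 1)
  nz <- which(colSums(counts) > 0 | obs > 0)
  out <- data.frame(
    hamming = nz - 1L,
    mean_count = colMeans(counts)[nz],
    q025 = apply(counts, 2, stats::quantile, 0.025)[nz],
    q975 = apply(counts, 2, stats::quantile, 0.975)[nz],
    observed_count = obs[nz])
  rownames(out) <- NULL
  attr(out, "null_counts") <- counts[, nz, drop = FALSE]
  out
}

#' Cross-cell-line prediction error versus CRM dissimilarity
#'
#' For each overlapping CRM pair linked to a gene, two models are trained on
#' all cell types except the target one: an A-model using cell line A's TF
#' set and a B-model using cell line B's TF set.  Both predict the target
#' cell type; the MSPE ratio (B-model / A-model) is reported per pair and
#' aggregated over Jaccard-dissimilarity bins.
#'
#' @param pairs overlapping pairs from [find_overlapping_crms()].
#' @param crms_a,crms_b CRM tables.
#' @param links_a CRM-gene links for cell line A.
#' @param tf_matrix,gene_matrix mean-centered [expression_matrix()] objects.
#' @param target_cell_type cell type whose expression both models predict.
#' @param basis_cap cap on the per-term basis dimension.
#' @return A list with `per_pair` (gene, jaccard, mspe_a, mspe_b, ratio) and
#'   `bins` (jaccard bin, n, median ratio); empty bins are omitted.  Pairs
#'   whose gene lacks expression data are skipped.
#' @export
dissimilarity_vs_error <- function(pairs, crms_a, crms_b, links_a,
                                   tf_matrix, gene_matrix, target_cell_type,
                                   basis_cap = 8) {
  test <- samples_of(gene_matrix, target_cell_type)
  if (!length(test)) stop("unknown target cell type: ", target_cell_type)
  train <- setdiff(samples(gene_matrix), test)
  basis <- make_tf_basis(tf_matrix, basis_cap = basis_cap)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    genes <- links_a$gene_id[links_a$crm_id == pairs$crm_a[i]]
    genes <- intersect(genes, features(gene_matrix))
    for (g in genes) {
      ta <- crms_a$tfs[crms_a$crm_id == pairs$crm_a[i]]
      tb <- crms_b$tfs[crms_b$crm_id == pairs$crm_b[i]]
      sa <- list(gene_id = g, crm_id = pairs$crm_a[i], predictors = ta)
      sb <- list(gene_id = g, crm_id = pairs$crm_b[i], predictors = tb)
      fit_pred <- function(s) {
        m <- fit_gene_model(s, tf_matrix, gene_matrix, train,
                            basis_cap = basis_cap, basis = basis)
        stats::predict(m, tf_matrix, test, gene_matrix)$mspe
      }
      ea <- tryCatch(fit_pred(sa), error = function(e) NA_real_)
      eb <- tryCatch(fit_pred(sb), error = function(e) NA_real_)
      if (is.na(ea) || is.na(eb) || ea <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, crm_a = pairs$crm_a[i], crm_b = pairs$crm_b[i],
        jaccard = pairs$jaccard[i], mspe_a = ea, mspe_b = eb,
        ratio = eb / ea, stringsAsFactors = FALSE)
    }
  }
  per_pair <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), crm_a = character(),
               crm_b = character(), jaccard = numeric(), mspe_a = numeric(),
               mspe_b = numeric(), ratio = numeric(), stringsAsFactors = FALSE)
  rownames(per_pair) <- NULL
  breaks <- c(-Inf, 0, 0.3, 0.5, 0.8, 1)
  labels <- c("0", "(0,0.3]", "(0.3,0.5]", "(0.5,0.8]", "(0.8,1]")
  bin <- cut(per_pair$jaccard, breaks, labels = labels)
  bins <- do.call(rbind, lapply(levels(bin), function(lv) {
    r <- per_pair$ratio[bin == lv]
    if (!length(r)) return(NULL)
    data.frame(jaccard_bin = lv, n = length(r),
               median_ratio = stats::median(r), stringsAsFactors = FALSE)
  }))
  list(per_pair = per_pair, bins = bins)
}

#' Classify genes as differentially expressed between two cell types
#'
#' Uses the absolute difference of replicate-mean log expression with a
#' configurable threshold (default 1, i.e. two-fold on a log2 scale).
#'
#' @param gene_matrix a gene [expression_matrix()] containing both cell
#'   types.
#' @param cell_a,cell_b cell-type labels; the sign convention is B vs A
#'   (`over_expressed` = higher in B).
#' @param threshold minimum absolute mean log difference.
#' @return A named character vector over genes with values
#'   `"under_expressed"`, `"over_expressed"` or `"unchanged"`.
#' @export
classify_de <- function(gene_matrix, cell_a, cell_b, threshold = 1) {
  a <- samples_of(gene_matrix, cell_a); b <- samples_of(gene_matrix, cell_b)
  if (!length(a) || !length(b)) stop("unknown cell type")
  d <- rowMeans(gene_matrix$values[, b, drop = FALSE]) -
    rowMeans(gene_matrix$values[, a, drop = FALSE])
  cls <- ifelse(d >= threshold, "over_expressed",
                ifelse(d <= -threshold, "under_expressed", "unchanged"))
  stats::setNames(cls, features(gene_matrix))
}

gene_tf_table <- function(links, crms) {
  idx <- match(links$crm_id, crms$crm_id)
  sets <- tf_sets(crms)[idx]
  df <- data.frame(gene_id = rep(links$gene_id, lengths(sets)),
                   tf = unlist(sets), stringsAsFactors = FALSE)
  unique(df)
}

#' TF enrichment at differentially expressed genes
#'
#' For each TF and DE class, counts genes in the class whose promoter CRM
#' contains the TF in exactly one cell line, and compares with the expected
#' count given the genome-wide rate of such cell-line-specific binding among
#' all classified genes.
#'
#' @param links_a,links_b CRM-gene links per cell line.
#' @param crms_a,crms_b CRM tables per cell line.
#' @param de_classes named classification from [classify_de()].
#' @return A data frame with columns `tf`, `gene_class`, `side` (`"only_A"`
#'   or `"only_B"`), `observed`, `expected`, `ratio`.  TFs with no
#'   cell-line-specific binding anywhere are omitted.
#' @export
de_gene_tf_enrichment <- function(links_a, links_b, crms_a, crms_b,
                                  de_classes) {
  de_classes <- de_classes[!is.na(de_classes)]
  if (!length(de_classes)) stop("no classified genes")
  classes <- c("under_expressed", "over_expressed")
  if (!any(de_classes %in% classes)) stop("no differentially expressed genes")
  for (cl in classes)
    if (!sum(de_classes == cl)) stop("empty DE class: ", cl)
  universe <- names(de_classes)
  ga <- gene_tf_table(links_a, crms_a)
  gb <- gene_tf_table(links_b, crms_b)
  tfs <- sort(unique(c(ga$tf, gb$tf)))
  key <- function(df) paste(df$gene_id, df$tf)
  only_a <- ga[!(key(ga) %in% key(gb)) & ga$gene_id %in% universe, ]
  only_b <- gb[!(key(gb) %in% key(ga)) & gb$gene_id %in% universe, ]
  rows <- list()
  for (tf in tfs) {
    for (side in c("only_A", "only_B")) {
      spec_genes <- if (side == "only_A") only_a$gene_id[only_a$tf == tf]
        else only_b$gene_id[only_b$tf == tf]
      if (!length(spec_genes)) next
      rate <- length(spec_genes) / length(universe)
      for (cl in classes) {
        class_genes <- names(de_classes)[de_classes == cl]
        observed <- sum(class_genes %in% spec_genes)
        expected <- length(class_genes) * rate
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, gene_class = cl, side = side, observed = observed,
          expected = expected, ratio = observed / expected,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster TFs by co-occurrence in CRMs at DE-gene promoters
#'
#' Pools the CRMs of both cell lines at differentially expressed genes'
#' promoters; each TF is represented by the set of pooled CRMs containing
#' it, pairwise distance is 1 minus the Jaccard similarity of those sets,
#' and TFs are merged by average-linkage hierarchical clustering.
#'
#' @param crms_a,crms_b CRM tables per cell line.
#' @param de_gene_links CRM-gene links restricted to DE genes (both lines
#'   concatenated), or a character vector of CRM ids.
#' @return A list of class `"TFLinkage"`: `tfs`, `dist` (symmetric matrix,
#'   zero diagonal), `hclust`.
#' @export
cluster_tf_cooccurrence <- function(crms_a, crms_b, de_gene_links) {
  ids <- if (is.character(de_gene_links)) de_gene_links else
    de_gene_links$crm_id
  line_pool <- function(crms, prefix) {
    if (!nrow(crms))
      return(data.frame(uid = character(), tfs = character(),
                        keep = logical(), stringsAsFactors = FALSE))
    data.frame(uid = paste0(prefix, crms$crm_id), tfs = crms$tfs,
               keep = crms$crm_id %in% ids, stringsAsFactors = FALSE)
  }
  pool <- rbind(line_pool(crms_a, "A|"), line_pool(crms_b, "B|"))
  pool <- pool[pool$keep, , drop = FALSE]
  if (!nrow(pool)) stop("no CRMs at DE-gene promoters")
  sets <- strsplit(pool$tfs, ",", fixed = TRUE)
  tfs <- sort(unique(unlist(sets)))
  member <- lapply(tfs, function(tf)
    pool$uid[vapply(sets, function(s) tf %in% s, TRUE)])
  names(member) <- tfs
  present <- lengths(member) > 0
  if (any(!present))
    message("TF(s) in zero CRMs excluded: ",
            paste(tfs[!present], collapse = ", "))
  tfs <- tfs[present]; member <- member[present]
  if (length(tfs) < 2) stop("need at least 2 TFs to cluster")
  D <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) for (j in seq_along(tfs)) if (i < j) {
    inter <- length(intersect(member[[i]], member[[j]]))
    uni <- length(union(member[[i]], member[[j]]))
    D[i, j] <- D[j, i] <- 1 - inter / uni
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(tfs = tfs, dist = D, hclust = hc), class = "TFLinkage")
}

#' Write a TF linkage tree in Newick format
#'
#' @param linkage a [cluster_tf_cooccurrence()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(linkage, path) {
  ape::write.tree(ape::as.phylo(linkage$hclust), file = path)
  invisible(path)
}
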