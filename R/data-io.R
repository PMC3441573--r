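#' Read TF ChIP-Seq peaks from a BED-like file
#'
#' Reads a tab-separated BED-like file (3+ columns: chrom, start, end) of
#' called peaks for one transcription factor.  Coordinates are kept 0-based
#' half-open throughout the package (BED convention).
#'
#' @param path path to a tab-separated file; lines starting with `#`, `track`
#'   or `browser` are ignored.
#' @param tf_label TF identifier attached to every peak.
#' @param log2 unused for peaks; present for interface symmetry.
#' @return A data frame with columns `chrom`, `start`, `end`, `tf` and `score`
#'   (NA when the file has no score column).  An empty file yields a
#'   zero-row data frame.
#' @export
read_peaks <- function(path, tf_label, log2 = FALSE) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (!nzchar(tf_label)) stop("'tf_label' must be non-empty")
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_peaks())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": non-integer coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", idx[bad[1]], ": start >= end")
  if (any(!nzchar(chrom)))
    stop("line ", idx[which(!nzchar(chrom))[1]], ": empty chromosome name")
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  data.frame(chrom = chrom, start = start, end = end,
             tf = tf_label, score = score, stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             tf = character(), score = numeric(), stringsAsFactors = FALSE)
}

#' Write peaks as BED
#'
#' @param peaks a peak data frame as returned by [read_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$tf,
                   ifelse(is.na(peaks$score), 0, peaks$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (TSS) table
#'
#' Expects a BED-like tab-separated file: chrom, tss, tss+1, gene_id and
#' optionally score and strand in columns 5-6 (BED column order).  When the
#' strand column is absent, `+` is assumed.
#'
#' @param path path to the annotation file.
#' @return A data frame with columns `gene_id`, `chrom`, `tss` (0-based bp)
#'   and `strand`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:6), fill = TRUE)
  if (ncol(df) < 4 || !nrow(df)) stop("annotation needs >= 4 columns")
  tss <- suppressWarnings(as.integer(df$V2))
  if (anyNA(tss) || any(tss < 0)) stop("invalid TSS coordinate")
  strand <- if (all(df$V6 %in% c("+", "-"))) df$V6 else "+"
  out <- data.frame(gene_id = as.character(df$V4), chrom = df$V1,
                    tss = tss, strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene ids in annotation")
  out
}

#' Write a gene annotation table
#' @param annotation data frame from [read_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(annotation$chrom, annotation$tss, annotation$tss + 1L,
                   annotation$gene_id, 0L, annotation$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its replicate map
#'
#' The matrix file is tab-separated with feature ids in the first column and a
#' header of sample ids.  The replicate map is a two-column tab-separated file
#' (sample_id, cell_type) with a header.  Input is assumed log-scale; set
#' `log2 = TRUE` to apply `log2(x + 1)` to raw intensities.
#'
#' @param path matrix TSV path.
#' @param replicate_map_path replicate map TSV path.
#' @param log2 apply `log2(x + 1)` on load.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, replicate_map_path, log2 = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no features in expression matrix: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  if (log2) m <- log2(m + 1)
  rm <- read_replicate_map(replicate_map_path)
  expression_matrix(m, rm)
}

#' @rdname read_expression
#' @export
read_replicate_map <- function(replicate_map_path) {
  if (!file.exists(replicate_map_path))
    stop("replicate map not found: ", replicate_map_path)
  df <- utils::read.table(replicate_map_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("replicate map needs 2 columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write an expression matrix and its replicate map
#' @param em an [expression_matrix()].
#' @param path matrix TSV path.
#' @param replicate_map_path optional replicate map TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, replicate_map_path = NULL) {
  df <- data.frame(feature_id = features(em), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(replicate_map_path)) {
    rm <- data.frame(sample_id = names(em$replicate_map),
                     cell_type = unname(em$replicate_map))
    utils::write.table(rm, replicate_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the same distribution: the value at
#' each rank becomes the mean across columns of the values at that rank.
#' Ties within a column receive the mean of the rank-means they span
#' (average-tie rule), so the operation is deterministic and idempotent.
#'
#' @param em an [expression_matrix()].
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(em) {
  if (ncol(em$values) < 1) stop("need at least one sample column")
  v <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(v) <- dimnames(em$values)
  expression_matrix(v, em$replicate_map)
}

#' Collapse probes to genes, keeping the most variable probe
#'
#' When several probes map to one gene, the probe whose expression profile has
#' the largest sample variance (n-1 denominator) is kept; exact ties are
#' broken toward the lexicographically smallest probe id.  Genes with no probe
#' present in the matrix are omitted with a warning.
#'
#' @param em an [expression_matrix()] whose features are probe ids.
#' @param probe_map data frame with columns `probe_id` and `gene_id`
#'   (many probes to one gene allowed; each probe maps to exactly one gene).
#' @return An [expression_matrix()] with one row per gene.
#' @export
select_probe_per_gene <- function(em, probe_map) {
  if (anyDuplicated(probe_map$probe_id))
    stop("a probe maps to more than one gene")
  present <- probe_map[probe_map$probe_id %in% features(em), , drop = FALSE]
  lost <- setdiff(unique(probe_map$gene_id), unique(present$gene_id))
  if (length(lost))
    warning("genes with no probe present omitted: ",
            paste(lost, collapse = ", "))
  if (!nrow(present)) stop("no probes from the map are present in the matrix")
  vars <- apply(em$values[present$probe_id, , drop = FALSE], 1, stats::var)
  ord <- order(present$gene_id, -vars, present$probe_id)
  present <- present[ord, , drop = FALSE]
  chosen <- present[!duplicated(present$gene_id), , drop = FALSE]
  v <- em$values[chosen$probe_id, , drop = FALSE]
  rownames(v) <- chosen$gene_id
  expression_matrix(v, em$replicate_map)
}

#' Mean-center every feature row
#'
#' Subtracts each feature's mean across samples, so that models describe
#' expression variation around the gene's mean rather than absolute level.
#'
#' @param em an [expression_matrix()].
#' @return A centered [expression_matrix()]; every row has mean 0.
#' @export
mean_center <- function(em) {
  v <- em$values - rowMeans(em$values)
  expression_matrix(v, em$replicate_map)
}
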