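#' Convert peaks to binding-site centers
#'
#' A TF's binding site is taken to be the center of its ChIP-Seq peak,
#' `floor((start + end) / 2)` in 0-based coordinates.
#'
#' @param peaks a peak data frame from [read_peaks()] (rows from several TFs
#'   may be concatenated).
#' @return A data frame with columns `tf`, `chrom`, `pos`.
#' @export
peaks_to_sites <- function(peaks) {
  data.frame(tf = as.character(peaks$tf),
             chrom = as.character(peaks$chrom),
             pos = as.integer((peaks$start + peaks$end) %/% 2L),
             stringsAsFactors = FALSE)
}

#' Chain binding sites into co-localization groups
#'
#' Sites on each chromosome are sorted by position and chained by
#' single-linkage: a new group starts whenever the gap to the previous site
#' exceeds `max_gap` (a gap of exactly `max_gap` still chains).  Groups are
#' therefore maximal runs of sites with consecutive gaps <= `max_gap`.
#'
#' @param sites data frame from [peaks_to_sites()], one cell line.
#' @param max_gap maximum chaining distance in bp (default 500).
#' @return The input rows, sorted by (chrom, pos), with an integer `group`
#'   column; the groups partition the input.
#' @export
group_sites <- function(sites, max_gap = 500) {
  if (!nrow(sites)) {
    sites$group <- integer()
    return(sites)
  }
  ord <- order(sites$chrom, sites$pos, sites$tf)
  s <- sites[ord, , drop = FALSE]
  new_chrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(0L, diff(s$pos))
  s$group <- cumsum(new_chrom | gap > max_gap)
  rownames(s) <- NULL
  s
}

#' Call cis-regulatory modules from site groups
#'
#' A group becomes a CRM when it contains binding sites of two or more
#' distinct TFs.  Repeated sites of one TF are retained as sites but count
#' once in the TF set.  The CRM center is the midpoint of the span
#' (`floor((min pos + max pos) / 2)`), and the id is `chrom:start-end`.
#'
#' @param grouped_sites output of [group_sites()].
#' @return A data frame with one row per CRM: `crm_id`, `chrom`, `start`,
#'   `end` (span over member site positions), `center`, `n_sites`, `n_tfs`,
#'   `tfs` (comma-joined sorted distinct TFs).  The member sites, with their
#'   `crm_id`, are attached as attribute `"sites"`.
#' @export
call_crms <- function(grouped_sites) {
  s <- grouped_sites
  if (!nrow(s)) {
    out <- data.frame(crm_id = character(), chrom = character(),
                      start = integer(), end = integer(), center = integer(),
                      n_sites = integer(), n_tfs = integer(), tfs = character(),
                      stringsAsFactors = FALSE)
    attr(out, "sites") <- data.frame(crm_id = character(), tf = character(),
                                     chrom = character(), pos = integer(),
                                     stringsAsFactors = FALSE)
    return(out)
  }
  g <- split(seq_len(nrow(s)), s$group)
  rows <- lapply(g, function(i) {
    tfs <- sort(unique(s$tf[i]))
    if (length(tfs) < 2) return(NULL)
    lo <- min(s$pos[i]); hi <- max(s$pos[i])
    data.frame(crm_id = sprintf("%s:%d-%d", s$chrom[i[1]], lo, hi),
               chrom = s$chrom[i[1]], start = lo, end = hi,
               center = (lo + hi) %/% 2L,
               n_sites = length(i), n_tfs = length(tfs),
               tfs = paste(tfs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) return(call_crms(s[0, , drop = FALSE]))
  rownames(out) <- NULL
  member <- do.call(rbind, lapply(which(keep), function(j) {
    i <- g[[j]]
    data.frame(crm_id = sprintf("%s:%d-%d", s$chrom[i[1]],
                                min(s$pos[i]), max(s$pos[i])),
               tf = s$tf[i], chrom = s$chrom[i], pos = s$pos[i],
               stringsAsFactors = FALSE)
  }))
  rownames(member) <- NULL
  attr(out, "sites") <- member
  out
}

#' Detect CRMs from a list of per-TF peak sets
#'
#' Convenience wrapper: concatenates peaks, converts to site centers, chains
#' within `max_gap` and calls CRMs.
#'
#' @param peak_list list of peak data frames (one per TF, or arbitrary split).
#' @param max_gap chaining distance in bp.
#' @return See [call_crms()].
#' @export
detect_crms <- function(peak_list, max_gap = 500) {
  peaks <- do.call(rbind, peak_list)
  call_crms(group_sites(peaks_to_sites(peaks), max_gap = max_gap))
}

#' Split a CRM table's comma-joined TF sets
#' @param crms a CRM data frame.
#' @return A list of character vectors, one TF set per CRM.
#' @export
tf_sets <- function(crms) strsplit(crms$tfs, ",", fixed = TRUE)

#' Map CRMs to genes by promoter proximity
#'
#' A CRM is linked to a gene when its center lies within `window` bp of the
#' gene's TSS (inclusive).  The reported distance is strand-oriented:
#' positive values lie downstream of the TSS.
#'
#' @param crms CRM table from [call_crms()].
#' @param annotation gene annotation from [read_annotation()].
#' @param window promoter half-width in bp (default 1000).
#' @return A data frame with columns `crm_id`, `gene_id`, `distance`.
#' @export
map_crms_to_genes <- function(crms, annotation, window = 1000) {
  out <- list()
  for (ch in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    cr <- crms[crms$chrom == ch, , drop = FALSE]
    if (!nrow(ann) || !nrow(cr)) next
    d <- outer(cr$center, ann$tss, `-`)
    hit <- which(abs(d) <= window, arr.ind = TRUE)
    if (!nrow(hit)) next
    sgn <- ifelse(ann$strand[hit[, 2]] == "-", -1L, 1L)
    out[[ch]] <- data.frame(
      crm_id = cr$crm_id[hit[, 1]],
      gene_id = ann$gene_id[hit[, 2]],
      distance = sgn * d[hit],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(crm_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$crm_id), , drop = FALSE]
}

#' Significance of TF combinations by label permutation
#'
#' Tests whether each observed distinct TF combination occurs among CRMs more
#' often than expected when TF identity is unrelated to position.  Null CRMs
#' are built by permuting the TF labels across all CRM member sites
#' genome-wide without replacement, which preserves each CRM's site count and
#' each TF's total site count; relabeled groups that collapse below two
#' distinct TFs are dropped, mirroring the CRM definition.
#'
#' @param crms CRM table from [call_crms()] (must carry the `"sites"`
#'   attribute).
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the permutations (required).
#' @param per_crm if `TRUE`, labels are resampled independently for each CRM
#'   from the global site-label pool instead of one genome-wide permutation.
#' @return A data frame with one row per observed distinct TF set: `tfs`,
#'   `observed_count`, `null_mean`, `p_value` where
#'   `p = (1 + #\{null count >= observed\}) / (1 + B)`.  Per-permutation
#'   counts are attached as attribute `"null_counts"` (sets x B matrix).
#' @export
combination_significance <- function(crms, B = 1000, seed, per_crm = FALSE) {
  if (B < 1) stop("'B' must be >= 1")
  if (missing(seed)) stop("'seed' is required for resampling")
  sites <- attr(crms, "sites")
  if (is.null(sites) || !nrow(sites))
    stop("CRM table carries no member sites")
  obs <- table(crms$tfs)
  keys <- names(obs)
  crm_of <- match(sites$crm_id, crms$crm_id)
  labels <- sites$tf
  null_counts <- matrix(0L, length(keys), B,
                        dimnames = list(keys, NULL))
  set.seed(seed)
  for (b in seq_len(B)) {
    if (per_crm) {
      lab <- character(length(labels))
      for (i in split(seq_along(labels), crm_of))
        lab[i] <- sample(labels, length(i))
    } else {
      lab <- sample(labels)
    }
    combos <- vapply(split(lab, crm_of), function(x) {
      u <- sort(unique(x))
      if (length(u) < 2) NA_character_ else paste(u, collapse = ",")
    }, "")
    tab <- table(combos[!is.na(combos)])
    hit <- intersect(keys, names(tab))
    null_counts[hit, b] <- as.integer(tab[hit])
  }
  p <- (1 + rowSums(null_counts >= as.integer(obs))) / (1 + B)
  out <- data.frame(tfs = keys,
                    observed_count = as.integer(obs),
                    null_mean = rowMeans(null_counts),
                    p_value = as.numeric(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$p_value, -out$observed_count), , drop = FALSE]
  attr(out, "null_counts") <- null_counts
  out
}

#' Write a CRM table as BED
#'
#' Columns: chrom, span start, span end + 1 (half-open), crm_id, number of
#' TFs, TF set comma-joined.
#'
#' @param crms CRM table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crms <- function(crms, path) {
  df <- data.frame(crms$chrom, crms$start, crms$end + 1L, crms$crm_id,
                   crms$n_tfs, crms$tfs)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
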