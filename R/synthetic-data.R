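#' Configuration for the synthetic regulatory study
#'
#' Defines the conditions the generator emulates: a panel of TF ChIP-Seq
#' tracks with binding clustered near TSSs, two cell lines with controlled
#' binding differences, and an expression panel of hematopoietic-style cell
#' types with two biological replicates each.  Defaults mirror the assayed
#' study design this package targets: 14 TFs, 38 cell types x 2 replicates,
#' and gene expression generated as smooth (possibly nonlinear, possibly
#' interacting) functions of bound-TF expression plus Gaussian noise of
#' standard deviation `noise_sigma` on a unit-variance signal.
#'
#' @param seed integer seed driving all randomness (required).
#' @param n_chromosomes,chrom_length genome shape (default 2 x 2 Mb).
#' @param n_tfs number of TFs in the panel (default 14).
#' @param n_genes number of annotated genes (default 200).
#' @param n_cell_types,n_replicates expression panel shape (default 38 x 2).
#' @param background_rate background peak rate per bp per TF (default 2e-5).
#' @param enrichment_factor probability that a gene's promoter receives a
#'   planted CRM (default 1; 0 disables planting).
#' @param crm_size_probs probabilities for 2, 3 or 4 distinct TFs per
#'   planted CRM.
#' @param response_library response shapes drawn per regulator:
#'   `linear`, `saturating`, `sinusoidal`, `ushaped`.
#' @param fraction_interacting fraction of regulated multi-TF genes that
#'   additionally carry a multiplicative TF-TF interaction term.
#' @param noise_sigma SD of Gaussian noise added to the unit-variance signal.
#' @param fraction_regulated fraction of planted genes whose expression is
#'   actually driven by the planted TFs; the rest carry non-functional
#'   binding.
#' @param target_jaccard default Jaccard dissimilarity for cell line B.
#' @param min_tss_spacing minimum distance between TSSs in bp.
#' @param crm_width bp window within which a planted CRM's sites scatter.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 2, chrom_length = 2e6,
                              n_tfs = 14, n_genes = 200,
                              n_cell_types = 38, n_replicates = 2,
                              background_rate = 2e-5,
                              enrichment_factor = 1,
                              crm_size_probs = c(0.5, 0.3, 0.2),
                              response_library = c("linear", "saturating",
                                                   "sinusoidal", "ushaped"),
                              fraction_interacting = 0.15,
                              noise_sigma = 0.5,
                              fraction_regulated = 0.5,
                              target_jaccard = 0.25,
                              min_tss_spacing = 5000,
                              crm_width = 400) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n_chromosomes >= 1, chrom_length >= 1, n_tfs >= 1, n_genes >= 1,
            n_cell_types >= 1, n_replicates >= 1, noise_sigma >= 0,
            fraction_regulated >= 0, fraction_regulated <= 1,
            enrichment_factor >= 0, enrichment_factor <= 1,
            target_jaccard >= 0, target_jaccard <= 1)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_tfs = n_tfs,
                 n_genes = n_genes, n_cell_types = n_cell_types,
                 n_replicates = n_replicates,
                 background_rate = background_rate,
                 enrichment_factor = enrichment_factor,
                 crm_size_probs = crm_size_probs / sum(crm_size_probs),
                 response_library = response_library,
                 fraction_interacting = fraction_interacting,
                 noise_sigma = noise_sigma,
                 fraction_regulated = fraction_regulated,
                 target_jaccard = target_jaccard,
                 min_tss_spacing = min_tss_spacing,
                 crm_width = crm_width),
            class = "SimulationConfig")
}

tf_names <- function(n) sprintf("TF%02d", seq_len(n))
gene_names <- function(n) sprintf("g%04d", seq_len(n))

# Replicate-level measurement noise SD; fixed so the replicate-averaging
# code path is exercised identically in every simulation.
REPLICATE_SD <- 0.1

response_fun <- function(id) {
  switch(id,
         linear = function(x) x,
         saturating = function(x) tanh(1.5 * x),
         sinusoidal = function(x) sin(pi * x),
         ushaped = function(x) x^2,
         stop("unknown response: ", id))
}

#' Simulate a genome: annotation, line-A peak tracks and ground truth
#'
#' TSSs are placed on a minimum-spacing grid; each gene's promoter receives
#' a planted CRM with probability `enrichment_factor` (2-4 distinct TFs whose
#' sites scatter within `crm_width` bp of an anchor inside the promoter);
#' background peaks for every TF are scattered genome-wide at
#' `background_rate`.  Peak widths are even numbers in 200-400 bp so the
#' peak center recovers the planted site exactly.  A subset of planted genes
#' (`fraction_regulated`) is marked regulated: their expression will be
#' generated from the planted TFs.  The motif table flags every true
#' (regulator, gene) pair as enriched plus random pairs at rate 0.3.
#'
#' @param config a [simulation_config()].
#' @return A list: `annotation` (as [read_annotation()]), `peaks` (named
#'   list of per-TF peak data frames, cell line A), `ground_truth` (list of
#'   class `"GroundTruth"` with elements `genes`, `planted_sites`,
#'   `background_peaks`, `motif`, `expressed`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  tfs <- tf_names(config$n_tfs)
  margin <- 2000
  slots_per_chrom <- (config$chrom_length - 2 * margin) %/%
    config$min_tss_spacing
  if (slots_per_chrom * config$n_chromosomes < config$n_genes)
    stop("genome too small for ", config$n_genes, " genes at ",
         config$min_tss_spacing, " bp spacing")
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), config$n_genes))
  ann <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
    ng <- sum(chrom_of == ci)
    if (!ng) return(NULL)
    slots <- sort(sample(slots_per_chrom, ng))
    data.frame(chrom = sprintf("chr%d", ci),
               tss = as.integer(margin + (slots - 1) * config$min_tss_spacing +
                                  sample(0:(config$min_tss_spacing %/% 4),
                                         ng, replace = TRUE)),
               strand = sample(c("+", "-"), ng, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ann <- data.frame(gene_id = gene_names(config$n_genes),
                    chrom = ann$chrom, tss = ann$tss, strand = ann$strand,
                    stringsAsFactors = FALSE)
  planted <- stats::runif(config$n_genes) < config$enrichment_factor
  regulated <- planted & stats::runif(config$n_genes) <
    config$fraction_regulated
  sizes <- 1 + sample(length(config$crm_size_probs), config$n_genes,
                      replace = TRUE, prob = config$crm_size_probs)
  genes <- data.frame(ann, planted = planted, regulated = regulated,
                      regulators = "", responses = "", interaction = "",
                      stringsAsFactors = FALSE)
  site_rows <- list()
  for (i in which(planted)) {
    m <- min(sizes[i], config$n_tfs)
    reg <- sort(sample(tfs, m))
    anchor <- ann$tss[i] + sample(-600:600, 1)
    pos <- anchor + sort(sample(seq(-config$crm_width / 2,
                                    config$crm_width / 2), m))
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      gene_id = ann$gene_id[i], tf = reg, chrom = ann$chrom[i],
      pos = as.integer(pmax(pos, 1)), stringsAsFactors = FALSE)
    genes$regulators[i] <- paste(reg, collapse = ",")
    resp <- sample(config$response_library, m, replace = TRUE)
    genes$responses[i] <- paste(resp, collapse = ",")
    if (regulated[i] && m >= 2 &&
        stats::runif(1) < config$fraction_interacting) {
      pair <- sort(sample(reg, 2))
      genes$interaction[i] <- paste(pair, collapse = "*")
    }
  }
  planted_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(), tf = character(), chrom = character(),
               pos = integer(), stringsAsFactors = FALSE)
  background <- do.call(rbind, lapply(tfs, function(tf) {
    do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
      n_bg <- stats::rpois(1, config$background_rate * config$chrom_length)
      if (!n_bg) return(NULL)
      data.frame(tf = tf, chrom = sprintf("chr%d", ci),
                 pos = sample.int(config$chrom_length - 1000, n_bg) + 500,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(background))
    background <- data.frame(tf = character(), chrom = character(),
                             pos = integer(), stringsAsFactors = FALSE)
  # motif table: true regulators always enriched, plus random pairs
  motif <- expand.grid(tf = tfs, gene_id = ann$gene_id,
                       stringsAsFactors = FALSE)
  truth_key <- unlist(lapply(which(regulated), function(i)
    paste(strsplit(genes$regulators[i], ",")[[1]], genes$gene_id[i])))
  enriched <- paste(motif$tf, motif$gene_id) %in% truth_key |
    stats::runif(nrow(motif)) < 0.3
  motif <- motif[enriched, , drop = FALSE]
  rownames(motif) <- NULL
  gt <- structure(list(genes = genes, planted_sites = planted_sites,
                       background_peaks = background,
                       motif = motif,
                       expressed = stats::setNames(rep(TRUE, length(tfs)),
                                                   tfs)),
                  class = "GroundTruth")
  list(annotation = ann, peaks = sites_to_peaks(rbind(
    planted_sites[, c("tf", "chrom", "pos")], background), config$seed),
    ground_truth = gt)
}

# Wrap site centers into peaks with even widths in [200, 400] bp so that
# floor((start + end) / 2) returns the site exactly; deterministic given the
# RNG state offset.
sites_to_peaks <- function(sites, seed) {
  set.seed(seed + 7919L)
  w <- 2L * sample(100:200, nrow(sites), replace = TRUE)
  start <- pmax(sites$pos - w %/% 2L, 0L)
  df <- data.frame(chrom = sites$chrom, start = as.integer(start),
                   end = as.integer(start + w), tf = sites$tf,
                   score = NA_real_, stringsAsFactors = FALSE)
  split(df, df$tf)
}

#' Perturb cell line A's planted binding toward a target Jaccard distance
#'
#' For each planted CRM, chooses the number of removed (`r`) and added (`a`)
#' TFs whose resulting Jaccard distance `(r + a) / (m + a)` is closest to the
#' target, keeping at least 2 TFs; ties prefer fewer changes.  Added TFs
#' reuse the genomic positions vacated by removals where possible, so CRM
#' spans stay aligned between the lines.  Background peaks are shared.
#'
#' @param sim output of [simulate_genome()].
#' @param target_jaccard value in \[0, 1\], or a named per-gene vector.
#' @param seed integer seed (required).
#' @return A list: `peaks` (per-TF peak list for cell line B), `realized`
#'   (data frame gene_id, target, realized jaccard, tfs_b).
#' @export
perturb_binding <- function(sim, target_jaccard, seed) {
  if (missing(seed)) stop("'seed' is required")
  gt <- sim$ground_truth
  set.seed(seed)
  all_tfs <- names(gt$expressed)
  per_gene <- split(gt$planted_sites, gt$planted_sites$gene_id)
  rows <- list(); b_sites <- list()
  for (g in names(per_gene)) {
    s <- per_gene[[g]]
    tfs_a <- sort(unique(s$tf))
    m <- length(tfs_a)
    tgt <- if (length(target_jaccard) > 1) target_jaccard[[g]] else
      target_jaccard
    grid <- expand.grid(r = 0:m, a = 0:(length(all_tfs) - m))
    grid <- grid[m - grid$r + grid$a >= 2 & grid$r <= m, ]
    grid$j <- (grid$r + grid$a) / (m + grid$a)
    grid <- grid[order(abs(grid$j - tgt), grid$r + grid$a, grid$r), ]
    r <- grid$r[1]; a <- grid$a[1]
    removed <- if (r) sample(tfs_a, r) else character()
    added <- if (a) sample(setdiff(all_tfs, tfs_a), a) else character()
    keep <- s[!(s$tf %in% removed), , drop = FALSE]
    freed <- s$pos[s$tf %in% removed]
    new_pos <- c(freed, sample(seq(min(s$pos), max(s$pos)),
                               max(0, a - length(freed)), replace = TRUE))
    add_rows <- if (a) data.frame(
      gene_id = g, tf = added, chrom = s$chrom[1],
      pos = as.integer(new_pos[seq_len(a)]), stringsAsFactors = FALSE)
      else NULL
    b <- rbind(keep, add_rows)
    b_sites[[g]] <- b
    tfs_b <- sort(unique(b$tf))
    rows[[g]] <- data.frame(
      gene_id = g, target = tgt,
      realized = unname(crm_distance(tfs_a, tfs_b)["jaccard"]),
      tfs_b = paste(tfs_b, collapse = ","), stringsAsFactors = FALSE)
  }
  planted_b <- do.call(rbind, b_sites)
  realized <- do.call(rbind, rows)
  rownames(realized) <- NULL
  if (any(abs(realized$realized - realized$target) > 0.2))
    message(sum(abs(realized$realized - realized$target) > 0.2),
            " CRM(s) could not reach the target dissimilarity exactly; ",
            "closest achievable used")
  peaks <- sites_to_peaks(rbind(planted_b[, c("tf", "chrom", "pos")],
                                gt$background_peaks), seed)
  list(peaks = peaks, realized = realized)
}

#' Simulate the TF and gene expression panels
#'
#' TF expression per cell type is standard normal; replicates add
#' N(0, 0.1) measurement noise.  Regulated genes are smooth functions of
#' their regulators' cell-type values (response shapes from the ground
#' truth, plus a product term for interacting genes), standardized to unit
#' variance before N(0, `noise_sigma`) biological noise is added;
#' unregulated genes are independent standard normal.  All outputs are
#' mean-centered.
#'
#' @param config a [simulation_config()].
#' @param ground_truth from [simulate_genome()].
#' @param seed seed for the expression draw (default `config$seed + 1`).
#' @return A list: `tf_matrix` and `gene_matrix`, both mean-centered
#'   [expression_matrix()] objects with replicate maps attached, plus
#'   `tf_cell_values` (the noise-free TF x cell-type matrix) and
#'   `gene_cell_values` (the pre-replicate gene x cell-type matrix).
#' @export
simulate_expression <- function(config, ground_truth,
                                seed = config$seed + 1L) {
  set.seed(seed)
  tfs <- tf_names(config$n_tfs)
  cts <- sprintf("ct%02d", seq_len(config$n_cell_types))
  reps <- sprintf("r%d", seq_len(config$n_replicates))
  sample_ids <- as.vector(t(outer(cts, reps, paste, sep = "_")))
  rep_map <- stats::setNames(rep(cts, each = config$n_replicates),
                             sample_ids)
  x_ct <- matrix(stats::rnorm(config$n_tfs * config$n_cell_types),
                 config$n_tfs, config$n_cell_types,
                 dimnames = list(tfs, cts))
  tf_vals <- x_ct[, rep_map[sample_ids], drop = FALSE] +
    matrix(stats::rnorm(config$n_tfs * length(sample_ids), 0, REPLICATE_SD),
           config$n_tfs, length(sample_ids))
  colnames(tf_vals) <- sample_ids
  genes <- ground_truth$genes
  y_ct <- matrix(NA_real_, nrow(genes), config$n_cell_types,
                 dimnames = list(genes$gene_id, cts))
  for (i in seq_len(nrow(genes))) {
    if (genes$regulated[i]) {
      reg <- strsplit(genes$regulators[i], ",")[[1]]
      resp <- strsplit(genes$responses[i], ",")[[1]]
      sig <- rep(0, config$n_cell_types)
      for (j in seq_along(reg))
        sig <- sig + response_fun(resp[j])(x_ct[reg[j], ])
      if (nzchar(genes$interaction[i])) {
        pair <- strsplit(genes$interaction[i], "*", fixed = TRUE)[[1]]
        sig <- sig + x_ct[pair[1], ] * x_ct[pair[2], ]
      }
      s <- stats::sd(sig)
      if (s > 1e-12) sig <- (sig - mean(sig)) / s
      y_ct[i, ] <- sig + stats::rnorm(config$n_cell_types, 0,
                                      config$noise_sigma)
    } else {
      y_ct[i, ] <- stats::rnorm(config$n_cell_types)
    }
  }
  gene_vals <- y_ct[, rep_map[sample_ids], drop = FALSE] +
    matrix(stats::rnorm(nrow(genes) * length(sample_ids), 0, REPLICATE_SD),
           nrow(genes), length(sample_ids))
  colnames(gene_vals) <- sample_ids
  list(tf_matrix = mean_center(expression_matrix(tf_vals, rep_map)),
       gene_matrix = mean_center(expression_matrix(gene_vals, rep_map)),
       tf_cell_values = x_ct, gene_cell_values = y_ct)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Runs [simulate_genome()], [perturb_binding()] and [simulate_expression()]
#' and writes every file the analysis pipeline reads: per-TF peak BEDs for
#' both cell lines, the annotation BED, expression and replicate-map TSVs,
#' the motif-enrichment table, and a ground-truth manifest.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return Named character vector of written paths, invisibly.
#' @export
make_fixture_bundle <- function(config, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory not empty (use force = TRUE): ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  pb <- perturb_binding(sim, config$target_jaccard,
                        seed = config$seed + 2L)
  expr <- simulate_expression(config, sim$ground_truth)
  paths <- c()
  for (tf in names(sim$peaks)) {
    p <- file.path(outdir, sprintf("peaks_A_%s.bed", tf))
    write_peaks(sim$peaks[[tf]], p); paths[paste0("peaks_A_", tf)] <- p
  }
  for (tf in names(pb$peaks)) {
    p <- file.path(outdir, sprintf("peaks_B_%s.bed", tf))
    write_peaks(pb$peaks[[tf]], p); paths[paste0("peaks_B_", tf)] <- p
  }
  paths["annotation"] <- file.path(outdir, "annotation.bed")
  write_annotation(sim$annotation, paths["annotation"])
  paths["tf_expression"] <- file.path(outdir, "tf_expression.tsv")
  paths["replicate_map"] <- file.path(outdir, "replicate_map.tsv")
  write_expression(expr$tf_matrix, paths["tf_expression"],
                   paths["replicate_map"])
  paths["gene_expression"] <- file.path(outdir, "gene_expression.tsv")
  write_expression(expr$gene_matrix, paths["gene_expression"])
  paths["motif"] <- file.path(outdir, "motif_table.tsv")
  utils::write.table(sim$ground_truth$motif, paths["motif"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["expressed"] <- file.path(outdir, "expressed_tfs.tsv")
  utils::write.table(
    data.frame(tf = names(sim$ground_truth$expressed),
               expressed = sim$ground_truth$expressed),
    paths["expressed"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_genes"] <- file.path(outdir, "truth_genes.tsv")
  utils::write.table(sim$ground_truth$genes, paths["truth_genes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_sites"] <- file.path(outdir, "truth_sites.tsv")
  utils::write.table(sim$ground_truth$planted_sites, paths["truth_sites"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["realized_jaccard"] <- file.path(outdir, "realized_jaccard.tsv")
  utils::write.table(pb$realized, paths["realized_jaccard"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
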