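# Genome-wide analyses on trained trajectories: genomic cross-correlation
# matrices, enhancer-proximity synchrony, dynamic-buffering classification,
# and RBP target enrichment.

annotation_granges <- function(annotation) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(annotation)),
            all(annotation$start < annotation$end))
  GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(start = annotation$start + 1L,  # 0-based half-open in
                              end = annotation$end),
    gene_id = annotation$gene_id
  )
}

#' Genome-ordered lag-0 cross-correlation matrix
#'
#' For the genes of a genomic region, ordered by start position, the
#' symmetric matrix of pairwise lag-0 cross-correlations between their
#' trajectories (any trajectory type: transcription rate, spliced mRNA,
#' ...). Genes with constant trajectories get flagged-missing (NA) rows and
#' columns; the diagonal is exactly 1 for non-constant genes.
#'
#' @param trajectories Numeric matrix, genes in rows (row names = gene IDs),
#'   time points in columns.
#' @param annotation `data.frame` with `gene_id`, `chromosome`, `start`,
#'   `end` (0-based half-open coordinates).
#' @param region Optional list/vector `(chrom, start, end)` restricting the
#'   genes; `NULL` uses all annotated genes.
#' @return Symmetric matrix with genes ordered by start position.
#' @export
cc_matrix <- function(trajectories, annotation, region = NULL) {
  ann <- annotation[annotation$gene_id %in% rownames(trajectories), ]
  if (!is.null(region)) {
    ann <- ann[ann$chromosome == region[[1]] &
                 ann$start >= as.numeric(region[[2]]) &
                 ann$end <= as.numeric(region[[3]]), ]
  }
  if (nrow(ann) < 2) stop("cc_matrix: fewer than 2 annotated genes in region")
  ann <- ann[order(ann$start), ]
  m <- trajectories[ann$gene_id, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' Enhancer-proximity synchrony analysis
#'
#' Tests whether genes near active enhancers show more synchronized
#' trajectories. Active enhancers are eRNA loci with
#' `log(total TPM + 1) > activity_threshold` (natural log). Each gene is
#' assigned the distance to its nearest active enhancer (0 on overlap),
#' binned at `bin_width`; its synchrony score is the average lag-0
#' cross-correlation with the other genes of its bin. One-sided
#' Mann-Whitney U tests (alternative: nearer bin greater) compare the
#' requested bin pairs, with Benjamini-Hochberg adjustment across pairs.
#'
#' @param trajectories Genes x time matrix (row names = gene IDs).
#' @param annotation Gene annotation `data.frame` (`gene_id`, `chromosome`,
#'   `start`, `end`, 0-based half-open).
#' @param enhancers `data.frame` with `chromosome`, `start`, `end`,
#'   `total_tpm`.
#' @param bin_width Distance bin width in bp (default 50 kb).
#' @param activity_threshold Threshold on `log(total_tpm + 1)`
#'   (default 4.0).
#' @param test_pairs List of length-2 integer vectors of bin indices
#'   (0-based bins) to test; default: bin 0 against every other populated
#'   bin.
#' @return List with `gene_stats` (`gene_id`, `distance`, `bin`,
#'   `avg_cc`), `bin_summary` (per-bin n and mean avg_cc) and `tests`
#'   (`bin_a`, `bin_b`, `p`, `p_adj`).
#' @export
enhancer_proximity_synchrony <- function(trajectories, annotation, enhancers,
                                         bin_width = 50000,
                                         activity_threshold = 4.0,
                                         test_pairs = NULL) {
  stopifnot(all(c("chromosome", "start", "end", "total_tpm") %in% names(enhancers)))
  active <- enhancers[log(enhancers$total_tpm + 1) > activity_threshold, ]
  if (nrow(active) == 0) {
    stop("enhancer_proximity_synchrony: no enhancer passes the activity threshold")
  }
  ann <- annotation[annotation$gene_id %in% rownames(trajectories), ]
  gr_genes <- annotation_granges(ann)
  gr_enh <- GenomicRanges::GRanges(
    seqnames = active$chromosome,
    ranges = IRanges::IRanges(start = active$start + 1L, end = active$end)
  )
  hit <- GenomicRanges::distanceToNearest(gr_genes, gr_enh)
  dist <- rep(NA_real_, length(gr_genes))
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  gene_stats <- data.frame(gene_id = ann$gene_id, distance = dist,
                           bin = floor(dist / bin_width),
                           stringsAsFactors = FALSE)
  gene_stats <- gene_stats[!is.na(gene_stats$distance), ]

  # average lag-0 cross-correlation with the other genes of the same bin
  gene_stats$avg_cc <- NA_real_
  for (b in unique(gene_stats$bin)) {
    ids <- gene_stats$gene_id[gene_stats$bin == b]
    if (length(ids) < 2) next
    m <- trajectories[ids, , drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(m)))
    diag(cc) <- NA_real_
    gene_stats$avg_cc[match(ids, gene_stats$gene_id)] <-
      rowMeans(cc, na.rm = TRUE)
  }

  bins <- sort(unique(gene_stats$bin))
  bin_summary <- do.call(rbind, lapply(bins, function(b) {
    v <- gene_stats$avg_cc[gene_stats$bin == b]
    data.frame(bin = b, n = sum(gene_stats$bin == b),
               mean_avg_cc = mean(v, na.rm = TRUE))
  }))

  if (is.null(test_pairs)) {
    eligible <- bins[vapply(bins, function(b)
      sum(!is.na(gene_stats$avg_cc[gene_stats$bin == b])) >= 2, logical(1))]
    test_pairs <- lapply(setdiff(eligible, 0), function(b) c(0, b))
  }
  tests <- NULL
  if (length(test_pairs) > 0) {
    tests <- do.call(rbind, lapply(test_pairs, function(pr) {
      a <- gene_stats$avg_cc[gene_stats$bin == pr[[1]]]
      b <- gene_stats$avg_cc[gene_stats$bin == pr[[2]]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        return(data.frame(bin_a = pr[[1]], bin_b = pr[[2]], p = NA_real_))
      }
      p <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE)$p.value
      data.frame(bin_a = pr[[1]], bin_b = pr[[2]], p = p)
    }))
    tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  }
  list(gene_stats = gene_stats, bin_summary = bin_summary, tests = tests)
}

#' Classify a gene as dynamically buffered
#'
#' A gene is dynamically buffered when its spliced mRNA dynamics are more
#' stable than its unspliced dynamics (SD of the log2 fold-change relative
#' to t = 0, over the dense grid, strictly smaller — optionally by a ratio
#' threshold) while its transcription and degradation rate trajectories are
#' strongly coupled (maximum cross-correlation above `cc_threshold` within a
#' `max_lag_minutes` window). The buffering direction is the sign of the
#' extremum of the log2 fold-change of the transcription rate within the
#' first 60 minutes.
#'
#' @param model A `trained_gene_model` (or any object with a dense
#'   `mean_trajectory` holding `time`, `U_fit`, `S_fit`, `alpha`, `gamma`).
#' @param cc_threshold Coupling threshold (default 0.75).
#' @param max_lag_minutes Lag window for the coupling (default 60).
#' @param sd_ratio Require `sd_spliced < sd_ratio * sd_unspliced`
#'   (default 1, i.e. strictly smaller).
#' @param direction_window_minutes Window for the direction call
#'   (default 60).
#' @return One-row `data.frame`: `gene_id`, `sd_spliced`, `sd_unspliced`,
#'   `cc_alpha_gamma`, `cc_lag`, `buffered`, `direction` (`"up"`/`"down"`),
#'   `max_log2fc_alpha`.
#' @export
classify_buffered <- function(model, cc_threshold = 0.75,
                              max_lag_minutes = 60, sd_ratio = 1,
                              direction_window_minutes = 60) {
  tr <- model$mean_trajectory
  step <- tr$time[[2]] - tr$time[[1]]
  if (any(tr$S_fit <= 0) || any(tr$U_fit <= 0)) {
    stop("classify_buffered: fitted abundances must be positive to take log2 fold-changes")
  }
  dyn_s <- log2(tr$S_fit / tr$S_fit[[1]])
  dyn_u <- log2(tr$U_fit / tr$U_fit[[1]])
  sd_s <- stats::sd(dyn_s)
  sd_u <- stats::sd(dyn_u)
  cc <- max_lagged_crosscorr(tr$alpha, tr$gamma, max_lag_minutes, step)
  in_window <- tr$time > 0 & tr$time <= direction_window_minutes
  lfc_a <- log2(tr$alpha[in_window] / tr$alpha[[1]])
  ext <- lfc_a[which.max(abs(lfc_a))]
  buffered <- !is.na(cc$best_cc) && sd_s < sd_ratio * sd_u &&
    cc$best_cc > cc_threshold
  data.frame(gene_id = model$gene_id,
             sd_spliced = sd_s, sd_unspliced = sd_u,
             cc_alpha_gamma = cc$best_cc, cc_lag = cc$best_lag,
             buffered = buffered,
             direction = if (ext >= 0) "up" else "down",
             max_log2fc_alpha = ext,
             stringsAsFactors = FALSE)
}

#' Condition-specific buffered gene sets
#'
#' @param calls_a,calls_b `data.frame`s of [classify_buffered()] rows for
#'   two conditions over the same gene universe.
#' @return List with `a_specific` and `b_specific` gene ID vectors
#'   (buffered in one condition and not the other).
#' @export
condition_specific_sets <- function(calls_a, calls_b) {
  if (!setequal(calls_a$gene_id, calls_b$gene_id)) {
    stop("condition_specific_sets: the two call sets cover different gene universes")
  }
  buf_a <- calls_a$gene_id[calls_a$buffered]
  buf_b <- calls_b$gene_id[calls_b$buffered]
  list(a_specific = setdiff(buf_a, buf_b),
       b_specific = setdiff(buf_b, buf_a))
}

#' RBP target enrichment in a gene group
#'
#' For each expressed RNA-binding protein, a two-sided Fisher exact test on
#' the 2x2 table (gene in group x gene is RBP target) over the gene
#' universe, with Benjamini-Hochberg adjustment across all tested RBPs.
#' The reported odds ratio is the sample (cross-product) odds ratio.
#'
#' @param gene_group Character vector of genes (subset of `universe`).
#' @param universe Character vector: all genes considered.
#' @param rbp_targets Named list mapping RBP ID to a character vector of
#'   target genes, or a two-column `data.frame` (`rbp_id`,
#'   `target_gene_id`).
#' @param expressed_rbps Optional character vector restricting the tested
#'   RBPs (default: all RBPs in the mapping).
#' @return `data.frame` ranked by decreasing odds ratio: `rbp`, `a`, `b`,
#'   `c`, `d` (table cells), `odds_ratio`, `p`, `p_adj`, `significant`
#'   (adjusted p < 0.05).
#' @export
rbp_enrichment <- function(gene_group, universe, rbp_targets,
                           expressed_rbps = NULL) {
  if (length(gene_group) == 0) stop("rbp_enrichment: empty gene group")
  if (!all(gene_group %in% universe)) {
    stop("rbp_enrichment: gene_group must be a subset of universe")
  }
  if (is.data.frame(rbp_targets)) {
    rbp_targets <- split(rbp_targets[[2]], rbp_targets[[1]])
  }
  if (length(rbp_targets) == 0) stop("rbp_enrichment: empty RBP mapping")
  rbps <- names(rbp_targets)
  if (!is.null(expressed_rbps)) rbps <- intersect(rbps, expressed_rbps)
  in_group <- universe %in% gene_group
  rows <- lapply(rbps, function(r) {
    is_target <- universe %in% rbp_targets[[r]]
    a <- sum(in_group & is_target)
    b <- sum(in_group & !is_target)
    c_ <- sum(!in_group & is_target)
    d <- sum(!in_group & !is_target)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    data.frame(rbp = r, a = a, b = b, c = c_, d = d,
               odds_ratio = (a * d) / (b * c_),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < 0.05
  out[order(-out$odds_ratio), ]
}
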