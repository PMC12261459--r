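# Plain-text writers/readers: per-gene observation TSVs, ground-truth
# kinetics, trained trajectories with a JSON sidecar.

#' Write a simulated dataset to a directory of TSV files
#'
#' One `<gene_id>.tsv` per gene (columns `time_min`, `replicate`,
#' `unspliced`, `spliced`), one `<gene_id>.truth.tsv` per gene (`time_min`,
#' `alpha`, `beta`, `gamma` on the dense grid) and a `manifest.json`
#' recording the scenario settings and seed.
#'
#' @param genes List of `simulated_gene` objects from [simulate_scenario()].
#' @param dir Output directory (created if missing).
#' @param manifest Named list stored as `manifest.json` (seed, scenario
#'   settings, ...).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(genes, dir, manifest = list(),
                                    force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("write_simulated_dataset: ", dir,
         " exists and is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genes) {
    obs <- g$observations
    long <- do.call(rbind, lapply(seq_len(obs$n_replicates), function(r) {
      data.frame(time_min = obs$times, replicate = r,
                 unspliced = obs$U_obs[, r], spliced = obs$S_obs[, r])
    }))
    utils::write.table(long, file.path(dir, paste0(g$gene_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(time_min = g$truth_grid$time, alpha = g$truth_grid$alpha,
                 beta = g$truth_grid$beta, gamma = g$truth_grid$gamma),
      file.path(dir, paste0(g$gene_id, ".truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a per-gene observation TSV
#'
#' @param path TSV with columns `time_min`, `replicate`, `unspliced`,
#'   `spliced`.
#' @param gene_id Gene label (default: file name without extension).
#' @return A [gene_time_series()].
#' @export
read_gene_series <- function(path, gene_id = NULL) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_min", "replicate", "unspliced", "spliced") %in% names(df)))
  if (is.null(gene_id)) gene_id <- sub("\\.tsv$", "", basename(path))
  times <- sort(unique(df$time_min))
  reps <- sort(unique(df$replicate))
  U <- matrix(NA_real_, length(times), length(reps))
  S <- matrix(NA_real_, length(times), length(reps))
  idx <- cbind(match(df$time_min, times), match(df$replicate, reps))
  U[idx] <- df$unspliced
  S[idx] <- df$spliced
  gene_time_series(gene_id, times, U, S)
}

#' Write a trained gene model as TSV + JSON sidecar
#'
#' @param model A `trained_gene_model`.
#' @param dir Output directory.
#' @param per_restart Also write per-restart trajectory columns.
#' @return Paths of the written files, invisibly.
#' @export
write_gene_result <- function(model, dir, per_restart = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- model$mean_trajectory
  names(tr)[names(tr) == "time"] <- "time_min"
  if (per_restart) {
    for (k in seq_along(model$ensemble)) {
      for (cn in c("alpha", "beta", "gamma")) {
        tr[[paste0(cn, "_restart", k)]] <- model$ensemble[[k]][[cn]]
      }
    }
  }
  tsv <- file.path(dir, paste0(model$gene_id, ".fit.tsv"))
  utils::write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- file.path(dir, paste0(model$gene_id, ".fit.json"))
  ok <- !vapply(model$fits, function(f) isTRUE(f$failed), logical(1))
  jsonlite::write_json(list(
    gene_id = model$gene_id,
    restart_seeds = model$restart_seeds,
    n_failed = model$n_failed,
    converged = vapply(model$fits[ok], function(f) isTRUE(f$converged), logical(1)),
    final_total_loss = vapply(model$fits[ok],
                              function(f) f$final_loss$total, numeric(1)),
    lambda_final = lapply(model$fits[ok], function(f) as.list(f$model$lambda))
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, side))
}

#' Read count matrices and a sample sheet from TSV files
#'
#' @param intronic_path,exonic_path TSVs whose first column is the gene ID
#'   and remaining columns are samples.
#' @param sample_sheet_path TSV with columns `sample_id`, `time_min`,
#'   `replicate`.
#' @return A [count_table()].
#' @export
read_count_tables <- function(intronic_path, exonic_path, sample_sheet_path) {
  rd <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  count_table(rd(intronic_path), rd(exonic_path),
              utils::read.delim(sample_sheet_path))
}
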