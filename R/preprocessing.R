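# From intronic/exonic read-count tables to normalized per-gene time series:
# CPM by library size, then per-gene max normalization per channel.

#' Assemble a count table object
#'
#' @param intronic,exonic Genes x samples matrices (or data frames) of
#'   non-negative counts with gene IDs as row names and identical dimnames.
#' @param sample_sheet `data.frame` with columns `sample_id`, `time_min`,
#'   `replicate`, covering every column of the count matrices; times must
#'   include 0.
#' @param library_size Optional named per-sample library sizes; defaults to
#'   the column sums of `exonic + intronic`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(intronic, exonic, sample_sheet, library_size = NULL) {
  intronic <- as.matrix(intronic)
  exonic <- as.matrix(exonic)
  stopifnot(identical(dim(intronic), dim(exonic)),
            identical(colnames(intronic), colnames(exonic)),
            identical(rownames(intronic), rownames(exonic)),
            all(c("sample_id", "time_min", "replicate") %in% names(sample_sheet)))
  if (any(intronic < 0) || any(exonic < 0)) {
    stop("count_table: counts must be non-negative")
  }
  missing_cols <- setdiff(colnames(intronic), sample_sheet$sample_id)
  if (length(missing_cols) > 0) {
    stop("count_table: sample sheet does not cover samples: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!0 %in% sample_sheet$time_min) {
    stop("count_table: sample sheet must include time 0")
  }
  if (is.null(library_size)) {
    library_size <- colSums(intronic) + colSums(exonic)
  }
  if (any(library_size <= 0)) stop("count_table: library sizes must be > 0")
  if (!is.null(names(library_size))) {
    library_size <- library_size[colnames(intronic)]
    if (anyNA(library_size)) stop("count_table: library_size names do not cover all samples")
  } else if (length(library_size) != ncol(intronic)) {
    stop("count_table: library_size must be named or match the sample count")
  }
  structure(list(intronic = intronic, exonic = exonic,
                 sample_sheet = sample_sheet,
                 library_size = library_size),
            class = "count_table")
}

#' Counts-per-million normalization
#'
#' `cpm = count / library_size * 1e6` per cell, using each sample's library
#' size.
#'
#' @param counts A [count_table()].
#' @return The same object with `intronic` and `exonic` replaced by CPM
#'   matrices (class `cpm_table`).
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  ls <- counts$library_size
  counts$intronic <- sweep(counts$intronic, 2, ls, "/") * 1e6
  counts$exonic <- sweep(counts$exonic, 2, ls, "/") * 1e6
  class(counts) <- c("cpm_table", "count_table")
  counts
}

#' Per-gene max normalization of CPM levels
#'
#' Divides each gene's intronic and exonic CPM levels by their respective
#' per-gene maxima taken over all samples (all time points and replicates),
#' so the normalized values are dimensionless and capped at 1. Genes whose
#' maximum is zero in either channel carry no usable signal and are dropped
#' (reported via the `dropped` attribute and a message).
#'
#' @param cpm A `cpm_table` from [cpm_normalize()].
#' @return An object of class `normalized_series`: list with `unspliced`,
#'   `spliced` (normalized matrices), `scale_U`, `scale_S` (the per-gene
#'   maxima divided out), `sample_sheet`, and attribute `dropped`.
#' @export
max_normalize <- function(cpm) {
  stopifnot(inherits(cpm, "cpm_table"))
  max_u <- apply(cpm$intronic, 1, max)
  max_s <- apply(cpm$exonic, 1, max)
  keep <- max_u > 0 & max_s > 0
  if (!all(keep)) {
    message("max_normalize: dropping ", sum(!keep),
            " gene(s) with zero signal in at least one channel")
  }
  out <- structure(list(
    unspliced = cpm$intronic[keep, , drop = FALSE] / max_u[keep],
    spliced = cpm$exonic[keep, , drop = FALSE] / max_s[keep],
    scale_U = max_u[keep],
    scale_S = max_s[keep],
    sample_sheet = cpm$sample_sheet
  ), class = "normalized_series")
  attr(out, "dropped") <- rownames(cpm$intronic)[!keep]
  out
}

#' Assemble per-gene time series from normalized data
#'
#' Reshapes the sample-wise normalized values into one [gene_time_series()]
#' per retained gene, carrying the per-gene normalization scales so that
#' downstream training keeps rate units consistent. Missing time-replicate
#' cells are allowed (ragged real-data designs) and handled by the
#' replicate-averaging convention of the loss.
#'
#' @param norm A `normalized_series` from [max_normalize()].
#' @return Named list of [gene_time_series()] objects.
#' @export
assemble_series <- function(norm) {
  stopifnot(inherits(norm, "normalized_series"))
  sheet <- norm$sample_sheet
  sheet <- sheet[match(colnames(norm$unspliced), sheet$sample_id), ]
  times <- sort(unique(sheet$time_min))
  reps <- sort(unique(sheet$replicate))
  genes <- rownames(norm$unspliced)
  out <- lapply(seq_along(genes), function(i) {
    U <- matrix(NA_real_, length(times), length(reps))
    S <- matrix(NA_real_, length(times), length(reps))
    ti <- match(sheet$time_min, times)
    ri <- match(sheet$replicate, reps)
    U[cbind(ti, ri)] <- norm$unspliced[i, ]
    S[cbind(ti, ri)] <- norm$spliced[i, ]
    gene_time_series(genes[[i]], times, U, S,
                     scale = c(U = unname(norm$scale_U[[i]]),
                               S = unname(norm$scale_S[[i]])))
  })
  names(out) <- genes
  out
}
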