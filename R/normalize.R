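# Normalization and replicate QC for the 12-sample log2 matrix.

#' Quantile-normalize a matrix of expression values
#'
#' Forces every column to share the same distribution: each value is
#' replaced by the mean, across columns, of the values at its rank; tied
#' values within a column receive the mean of their tied rank-means.
#' Delegates to [limma::normalizeQuantiles()] with tie handling on, the
#' standard implementation for single-channel arrays.
#'
#' @param values numeric probe x sample matrix (any scale; normalization is
#'   rank-based).
#' @return Matrix of the same shape and dimnames with identical column
#'   distributions. A single-column input is returned unchanged with a
#'   warning.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become (2.5, 3.5, 4.5)
quantile_normalize <- function(values) {
  stop_if_not_matrix(values)
  if (anyNA(values)) stop("`values` must not contain missing values",
                          call. = FALSE)
  if (ncol(values) < 2L) {
    warning("single-column input: quantile normalization is a no-op")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Center each probe on its across-sample median
#'
#' The GeneSpring "baseline to median of all samples" step: subtracts from
#' every probe row its median over samples, so each row has median zero.
#' Applied on log2-scale values; idempotent.
#'
#' @param values numeric probe x sample matrix of log2 intensities.
#' @return Matrix of the same shape with per-row median 0.
#' @export
baseline_to_median <- function(values) {
  stop_if_not_matrix(values)
  values - apply(values, 1, median)
}

#' Replicate correlation QC
#'
#' Pearson correlation for every pair of samples plus a complete-linkage
#' tree on 1 - r distance, mirroring the replicate check done by
#' hierarchical clustering of arrays. Replicate pairs (same time point)
#' whose correlation falls below `threshold` are flagged; a zero-variance
#' sample yields an undefined correlation and is reported as a failure.
#'
#' @param values normalized probe x sample log2 matrix.
#' @param design sample design table (see [expression_dataset()]).
#' @param threshold QC threshold on replicate Pearson r (default 0.99).
#' @return list with `correlations` (sample x sample matrix), `tree`
#'   (an [stats::hclust] object, complete linkage on 1 - r) and
#'   `replicate_qc` (data.frame: time_point, sample_1, sample_2, r, pass).
#' @export
replicate_correlation <- function(values, design, threshold = 0.99) {
  stop_if_not_matrix(values)
  check_design(design, colnames(values))
  degenerate <- apply(values, 2, sd) == 0
  if (any(degenerate))
    warning("zero-variance sample(s): ",
            paste(colnames(values)[degenerate], collapse = ", "),
            "; correlations involving them are undefined")
  cors <- suppressWarnings(cor(values))
  d <- as.dist(1 - ifelse(is.na(cors), 2, cors))  # undefined pairs pushed out
  tree <- hclust(d, method = "complete")

  qc <- do.call(rbind, lapply(unique(design$time_point), function(tp) {
    ids <- design$sample_id[design$time_point == tp]
    ids <- ids[ids %in% colnames(values)]
    if (length(ids) < 2) return(NULL)
    pairs <- combn(ids, 2)
    data.frame(time_point = tp,
               sample_1 = pairs[1, ], sample_2 = pairs[2, ],
               r = cors[cbind(pairs[1, ], pairs[2, ])],
               stringsAsFactors = FALSE)
  }))
  qc$pass <- !is.na(qc$r) & qc$r >= threshold
  list(correlations = cors, tree = tree, replicate_qc = qc)
}
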