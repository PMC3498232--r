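# Flag filtering, fold changes, differential / heat-responsive calls.

#' Filter probes by detection flags
#'
#' Keeps probes called Present (`P`) in at least `min_present` of the 12
#' samples. For datasets with a different sample count the threshold
#' rescales to `ceiling(n_samples / 2)` with a warning.
#'
#' @param dataset an [expression_dataset()].
#' @param min_present minimum number of P flags (default 6 of 12).
#' @return Character vector of retained probe IDs; the number retained is
#'   reported as a message.
#' @export
flag_filter <- function(dataset, min_present = 6L) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  ns <- ncol(dataset$flags)
  if (ns != 12L) {
    min_present <- ceiling(ns / 2)
    warning("dataset has ", ns, " samples; P-flag threshold rescaled to ",
            min_present)
  }
  keep <- rowSums(dataset$flags == "P") >= min_present
  message(sum(keep), " of ", length(keep), " probes pass the flag filter")
  rownames(dataset$flags)[keep]
}

#' Per-time-point log2 fold changes versus control
#'
#' For every probe and treatment time point, the mean of the replicate
#' log2 values minus the mean of the CK (control) replicate log2 values —
#' the difference-of-means convention on log2 data, equivalent to the log
#' of the ratio of geometric means.
#'
#' @param dataset an [expression_dataset()] holding normalized log2 values
#'   (typically flag-filtered first with [flag_filter()] /
#'   [subset_probes()]).
#' @return `FoldChangeTable`: a numeric probe x 5 matrix with columns
#'   `20min, 60min, 2h, 4h, 8h`.
#' @export
fold_changes <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  values <- dataset$values
  design <- dataset$design
  tp_mean <- function(tp) {
    cols <- design$sample_id[design$time_point == tp]
    cols <- cols[cols %in% colnames(values)]
    sub <- values[, cols, drop = FALSE]
    if (anyNA(sub))
      warning("missing replicate values at ", tp,
              "; using available replicates")
    rowMeans(sub, na.rm = TRUE)
  }
  ck <- tp_mean("CK")
  fc <- vapply(TREATMENT_TIMES, function(tp) tp_mean(tp) - ck,
               numeric(nrow(values)))
  if (is.null(dim(fc))) fc <- matrix(fc, nrow = 1L)
  dimnames(fc) <- list(rownames(values), TREATMENT_TIMES)
  class(fc) <- c("FoldChangeTable", class(fc))
  fc
}

#' Call differentially expressed probes per time point
#'
#' A probe is up-regulated at a time point when its log2 fold change
#' strictly exceeds `log2(fold)`, and down-regulated when it is strictly
#' below `-log2(fold)` ("more than `fold`-fold change" vs control).
#'
#' @param fct a [fold_changes()] table.
#' @param fold linear fold-change threshold, must be > 1 (default 3).
#' @return `DifferentialCalls`: list with `up` and `down` (each a list of
#'   probe-ID vectors named by time point) and `fold`.
#' @export
differential_probes <- function(fct, fold = 3) {
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  lfc <- log2(fold)
  probes <- rownames(fct)
  up <- lapply(TREATMENT_TIMES, function(tp) probes[fct[, tp] > lfc])
  down <- lapply(TREATMENT_TIMES, function(tp) probes[fct[, tp] < -lfc])
  names(up) <- names(down) <- TREATMENT_TIMES
  structure(list(up = up, down = down, fold = fold),
            class = "DifferentialCalls")
}

#' @export
print.DifferentialCalls <- function(x, ...) {
  cat("DifferentialCalls (>", x$fold, "-fold vs CK)\n", sep = "")
  for (tp in TREATMENT_TIMES)
    cat(sprintf("  %-6s up %5d  down %5d\n", tp,
                length(x$up[[tp]]), length(x$down[[tp]])))
  invisible(x)
}

# probes differential (either direction) at a given time point
differential_at <- function(calls, tp) union(calls$up[[tp]], calls$down[[tp]])

#' Probes differential at every time point
#'
#' The Venn-diagram intersection: probes with a differential call (up or
#' down, direction free to vary) at all five treatment time points.
#'
#' @param calls a [differential_probes()] result.
#' @param probe_gene optional probe -> gene map for the gene-level set.
#' @return list with `probes` and (when a map is supplied) `genes`.
#' @export
intersect_all_timepoints <- function(calls, probe_gene = NULL) {
  stopifnot(inherits(calls, "DifferentialCalls"))
  probes <- Reduce(intersect,
                   lapply(TREATMENT_TIMES, differential_at, calls = calls))
  probes <- sort(probes)
  out <- list(probes = probes)
  if (!is.null(probe_gene))
    out$genes <- map_probes_to_genes(probes, probe_gene)
  out
}

#' Heat-responsive probe and gene set
#'
#' Heat-responsive (HR) probes show a more-than-threshold fold change
#' (either direction; the direction may differ between time points) in at
#' least `min_timepoints` of the five treatment time points.
#'
#' @param calls a [differential_probes()] result.
#' @param probe_gene optional probe -> gene map.
#' @param min_timepoints minimum qualifying time points (default 2).
#' @return `HRSet`: list with `probes`, `genes` (NULL without a map),
#'   `n_timepoints` (named count of qualifying time points per HR probe)
#'   and `min_timepoints`.
#' @export
heat_responsive <- function(calls, probe_gene = NULL, min_timepoints = 2L) {
  stopifnot(inherits(calls, "DifferentialCalls"))
  if (min_timepoints > length(TREATMENT_TIMES))
    stop("`min_timepoints` cannot exceed ", length(TREATMENT_TIMES),
         call. = FALSE)
  hits <- table(unlist(lapply(TREATMENT_TIMES, differential_at,
                              calls = calls)))
  probes <- sort(names(hits)[hits >= min_timepoints])
  genes <- if (!is.null(probe_gene)) map_probes_to_genes(probes, probe_gene)
  structure(list(probes = probes, genes = genes,
                 n_timepoints = setNames(as.integer(hits[probes]), probes),
                 min_timepoints = min_timepoints),
            class = "HRSet")
}

#' @export
print.HRSet <- function(x, ...) {
  cat("HRSet: ", length(x$probes), " probes",
      if (!is.null(x$genes)) paste0(" (", length(x$genes), " genes)"),
      " differential in >= ", x$min_timepoints, " time points\n", sep = "")
  invisible(x)
}

#' Collapse a probe set to its gene set
#'
#' A gene is included as soon as any one of its probes is in the input
#' set (the any-probe rule). Probes with no annotation are dropped and
#' counted in a warning.
#'
#' @param probes character vector of probe IDs.
#' @param probe_gene named character vector, probe -> gene ID.
#' @return Sorted character vector of gene IDs.
#' @export
map_probes_to_genes <- function(probes, probe_gene) {
  mapped <- probe_gene[probes]
  n_missing <- sum(is.na(mapped))
  if (n_missing > 0)
    warning(n_missing, " probe(s) lack a gene annotation and were dropped")
  sort(unique(mapped[!is.na(mapped)]))
}
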