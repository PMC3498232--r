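# ExpressionDataset container: log2 intensities + P/A/M flags + design.

#' Construct an ExpressionDataset
#'
#' Bundles a probe x sample matrix of log2 intensities with its detection
#' flags (Present / Absent / Marginal), the sample design (time point and
#' replicate) and an optional probe-to-gene annotation. Missing flags are
#' treated conservatively as `A`.
#'
#' @param values numeric probe x sample matrix of log2 intensities, with
#'   probe rownames and sample colnames.
#' @param flags character matrix of the same shape, cells in `P`, `A`, `M`.
#' @param design data.frame with columns `sample_id`, `time_point`
#'   (in `CK, 20min, 60min, 2h, 4h, 8h`) and `replicate`.
#' @param probe_gene named character vector mapping probe -> gene ID;
#'   probes absent from the map are treated as unannotated.
#' @return An object of class `ExpressionDataset`: a list with the four
#'   components above.
#' @export
expression_dataset <- function(values, flags = NULL, design = standard_design(),
                               probe_gene = NULL) {
  stop_if_not_matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe_%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- design$sample_id[seq_len(ncol(values))]
  check_design(design, colnames(values))
  if (is.null(flags)) {
    flags <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!identical(dim(flags), dim(values)))
    stop("`values` and `flags` must have identical shape", call. = FALSE)
  flags[is.na(flags)] <- "A"
  if (!all(flags %in% c("P", "A", "M")))
    stop("flags must be one of P, A, M", call. = FALSE)
  dimnames(flags) <- dimnames(values)
  tab <- table(design$time_point[design$sample_id %in% colnames(values)])
  if (!all(TIME_POINTS %in% names(tab)))
    stop("design must cover all six time points", call. = FALSE)
  structure(list(values = values, flags = flags, design = design,
                 probe_gene = probe_gene),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  cat("  time points:", paste(unique(x$design$time_point), collapse = ", "),
      "\n")
  cat("  P-flag fraction:", round(mean(x$flags == "P"), 3), "\n")
  if (!is.null(x$probe_gene))
    cat("  annotated probes:",
        sum(rownames(x$values) %in% names(x$probe_gene)), "\n")
  invisible(x)
}

#' Subset an ExpressionDataset to a set of probes
#'
#' @param dataset an [expression_dataset()].
#' @param probes character vector of probe IDs to keep.
#' @return A new `ExpressionDataset` restricted to `probes`.
#' @export
subset_probes <- function(dataset, probes) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  missing <- setdiff(probes, rownames(dataset$values))
  if (length(missing))
    stop(length(missing), " probes not present in dataset", call. = FALSE)
  expression_dataset(dataset$values[probes, , drop = FALSE],
                     dataset$flags[probes, , drop = FALSE],
                     dataset$design, dataset$probe_gene)
}
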