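# 2^(-ddCt) relative quantification and array concordance.

#' Simulate a qPCR plate from known log2 fold changes
#'
#' Builds CT records for a set of target genes plus the reference gene
#' under the six conditions, such that the noiseless 2^(-ddCt) relative
#' quantity of each gene equals `2^true_log2fc`: the target CT in a
#' condition is the gene's basal CT minus its true log2 fold change (one
#' PCR cycle per doubling), while the reference CT is constant across
#' conditions. Gaussian noise with `noise_sd` is added per technical
#' replicate.
#'
#' @param genes character vector of target gene IDs.
#' @param true_log2fc numeric matrix genes x conditions (columns from
#'   `TREATMENT_TIMES`; the CK column, if present, is ignored and treated
#'   as 0).
#' @param ref_ct reference-gene CT (default 16).
#' @param base_ct basal target CT at CK (default 24).
#' @param noise_sd CT noise standard deviation per well.
#' @param n_bio,n_tech biological / technical replicates (defaults 2, 3).
#' @param reference_gene reference gene ID (default "actin1").
#' @param seed integer RNG seed.
#' @return `QpcrPlate`: data.frame (gene, condition, bio_rep, tech_rep,
#'   ct) with attributes `reference_gene` and `calibrator`.
#' @export
generate_qpcr_plate <- function(genes, true_log2fc, ref_ct = 16,
                                base_ct = 24, noise_sd = 0, n_bio = 2L,
                                n_tech = 3L, reference_gene = "actin1",
                                seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  true_log2fc <- as.matrix(true_log2fc)
  if (is.null(rownames(true_log2fc))) rownames(true_log2fc) <- genes
  if (is.null(colnames(true_log2fc))) {
    if (ncol(true_log2fc) != length(TREATMENT_TIMES))
      stop("`true_log2fc` needs condition colnames or exactly ",
           length(TREATMENT_TIMES), " columns", call. = FALSE)
    colnames(true_log2fc) <- TREATMENT_TIMES
  }
  lfc <- matrix(0, length(genes), length(TIME_POINTS),
                dimnames = list(genes, TIME_POINTS))
  common <- intersect(colnames(true_log2fc), TREATMENT_TIMES)
  lfc[genes, common] <- true_log2fc[genes, common]
  set.seed(seed)
  grid <- expand.grid(gene = c(genes, reference_gene),
                      condition = TIME_POINTS,
                      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  is_ref <- grid$gene == reference_gene
  ct0 <- ifelse(is_ref, ref_ct,
                base_ct - lfc[cbind(match(grid$gene, genes),
                                    match(grid$condition, TIME_POINTS))])
  grid$ct <- ct0 + if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
  structure(grid, reference_gene = reference_gene, calibrator = "CK",
            class = c("QpcrPlate", "data.frame"))
}

#' Relative quantification by the 2^(-ddCt) method
#'
#' Technical replicates are averaged on the CT scale, then per biological
#' replicate dCT = CT(target) - CT(reference) within each condition,
#' ddCT = dCT(condition) - dCT(calibrator), RQ = 2^(-ddCT). RQ is averaged
#' over biological replicates with its standard deviation; by construction
#' RQ of the calibrator condition is 1.
#'
#' @param plate a `QpcrPlate` (or any data.frame with columns gene,
#'   condition, bio_rep, tech_rep, ct).
#' @param reference_gene internal-control gene (default the plate's
#'   attribute, falling back to "actin1").
#' @param calibrator calibrator condition (default "CK").
#' @return `RelativeQuantities` data.frame: gene, condition, delta_ct
#'   (mean over bio reps), delta_delta_ct, rq (mean), rq_sd, log2_rq.
#' @export
delta_delta_ct <- function(plate,
                           reference_gene = attr(plate, "reference_gene"),
                           calibrator = attr(plate, "calibrator")) {
  if (is.null(reference_gene)) reference_gene <- "actin1"
  if (is.null(calibrator)) calibrator <- "CK"
  need <- c("gene", "condition", "bio_rep", "ct")
  stopifnot(all(need %in% names(plate)))
  # average technical replicates on the CT scale
  ct <- aggregate(ct ~ gene + condition + bio_rep, data = plate, FUN = mean)
  ref <- ct[ct$gene == reference_gene, c("condition", "bio_rep", "ct")]
  if (!all(unique(ct$condition) %in% ref$condition))
    stop("reference gene `", reference_gene,
         "` is not measured in every condition", call. = FALSE)
  names(ref)[3] <- "ref_ct"
  ct <- merge(ct[ct$gene != reference_gene, ], ref,
              by = c("condition", "bio_rep"))
  ct$delta_ct <- ct$ct - ct$ref_ct
  cal <- ct[ct$condition == calibrator, c("gene", "bio_rep", "delta_ct")]
  names(cal)[3] <- "cal_delta_ct"
  ct <- merge(ct, cal, by = c("gene", "bio_rep"))
  ct$ddct <- ct$delta_ct - ct$cal_delta_ct
  ct$rq <- 2^(-ct$ddct)
  out <- do.call(rbind, lapply(split(ct, ct[c("gene", "condition")]),
    function(d) data.frame(
      gene = d$gene[1], condition = d$condition[1],
      delta_ct = mean(d$delta_ct), delta_delta_ct = mean(d$ddct),
      rq = mean(d$rq), rq_sd = if (nrow(d) > 1) sd(d$rq) else 0,
      stringsAsFactors = FALSE)))
  out$log2_rq <- log2(out$rq)
  out <- out[order(out$gene, match(out$condition, TIME_POINTS)), ]
  rownames(out) <- NULL
  class(out) <- c("RelativeQuantities", class(out))
  out
}

#' Concordance between qPCR and array fold changes
#'
#' Per gene and treatment time point, compares the qPCR log2 relative
#' quantity with the array log2 fold change: sign agreement per entry,
#' the overall sign-concordance fraction, and the Pearson correlation of
#' the pooled log2FC vectors.
#'
#' @param rq a [delta_delta_ct()] result.
#' @param fct a [fold_changes()] table with gene (or probe) rownames.
#' @param genes genes to compare (default: all shared).
#' @return list with `table` (gene, time_point, log2_rq, log2fc_array,
#'   sign_agree), `sign_concordance` (fraction) and `pearson_r`.
#' @export
concordance <- function(rq, fct, genes = NULL) {
  if (is.null(genes)) genes <- intersect(unique(rq$gene), rownames(fct))
  if (!length(genes)) stop("no overlapping genes", call. = FALSE)
  rq <- rq[rq$gene %in% genes & rq$condition %in% TREATMENT_TIMES, ]
  tab <- data.frame(gene = rq$gene, time_point = rq$condition,
                    log2_rq = rq$log2_rq,
                    log2fc_array = fct[cbind(rq$gene, rq$condition)],
                    stringsAsFactors = FALSE)
  tab$sign_agree <- sign(tab$log2_rq) == sign(tab$log2fc_array)
  list(table = tab,
       sign_concordance = mean(tab$sign_agree),
       pearson_r = cor(tab$log2_rq, tab$log2fc_array))
}
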