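# Synthetic expression data with planted temporal profiles.

#' Configuration for the expression simulator
#'
#' Describes a 12-sample single-channel experiment (CK plus five heat
#' time points, two replicates each) with a block of "planted" probes per
#' temporal archetype and a background of unresponsive probes. Intensities
#' are generated directly on the log2 scale: probe baseline ~
#' N(baseline_mean, baseline_sd), plus the archetype log2 fold change at
#' treatment time points, plus N(0, noise_sd) measurement noise per cell.
#'
#' @param n_probes total number of probes (planted + background).
#' @param n_planted_per_cluster planted probes per archetype profile.
#' @param cluster_profiles numeric matrix, one row per archetype, five
#'   columns of log2FC at (20min, 60min, 2h, 4h, 8h). Default
#'   [default_cluster_archetypes()].
#' @param noise_sd per-cell log2-intensity noise standard deviation.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param flag_absent_rate probability that a cell is flagged `A`
#'   (otherwise `P`).
#' @param genes_per_probe average number of probes per gene used when
#'   building the probe-to-gene map (consecutive probes share a gene).
#' @param seed integer RNG seed.
#' @return An object of class `ExpressionSimConfig`.
#' @export
expression_sim_config <- function(n_probes = 2000,
                                  n_planted_per_cluster = 60,
                                  cluster_profiles = default_cluster_archetypes(),
                                  noise_sd = 0.2,
                                  baseline_mean = 8,
                                  baseline_sd = 2,
                                  flag_absent_rate = 0.1,
                                  genes_per_probe = 1,
                                  seed = 1L) {
  cluster_profiles <- as.matrix(cluster_profiles)
  if (n_probes < 1) stop("`n_probes` must be positive", call. = FALSE)
  if (ncol(cluster_profiles) != 5L)
    stop("each cluster profile must have exactly 5 entries (",
         paste(TREATMENT_TIMES, collapse = ", "), ")", call. = FALSE)
  colnames(cluster_profiles) <- TREATMENT_TIMES
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (flag_absent_rate < 0 || flag_absent_rate >= 1)
    stop("`flag_absent_rate` must be in [0, 1)", call. = FALSE)
  n_planted <- nrow(cluster_profiles) * n_planted_per_cluster
  if (n_planted > n_probes)
    stop("planted probes (", n_planted, ") exceed `n_probes`", call. = FALSE)
  structure(
    list(n_probes = as.integer(n_probes),
         n_planted_per_cluster = as.integer(n_planted_per_cluster),
         cluster_profiles = cluster_profiles,
         noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         flag_absent_rate = flag_absent_rate,
         genes_per_probe = genes_per_probe,
         seed = as.integer(seed)),
    class = "ExpressionSimConfig")
}

#' Standard 12-sample design table
#'
#' @return data.frame with columns sample_id, time_point, replicate in the
#'   canonical order CK-1, CK-2, 20min-1, ..., 8h-2.
#' @export
standard_design <- function() {
  data.frame(
    sample_id = paste(rep(TIME_POINTS, each = 2), rep(1:2, 6), sep = "-"),
    time_point = rep(TIME_POINTS, each = 2),
    replicate = rep(1:2, 6),
    stringsAsFactors = FALSE)
}

#' Simulate an expression dataset with known ground truth
#'
#' Generates a probe x 12-sample log2 intensity matrix, matching P/A
#' detection flags, the standard design table and a probe-to-gene map.
#' The first `nrow(cluster_profiles) * n_planted_per_cluster` probes carry
#' the archetype profiles (in blocks); the remainder are flat background.
#'
#' @param config an [expression_sim_config()].
#' @return list with components `dataset` (an [expression_dataset()]) and
#'   `truth`: `planted_cluster` (named integer, planted probe -> archetype
#'   index), `profiles` (probe x 5 expected log2FC for planted probes) and
#'   `planted_de` (long data.frame probe / time_point / direction / log2fc
#'   for every non-zero planted effect).
#' @export
#' @examples
#' sim <- generate_expression_dataset(expression_sim_config(n_probes = 800,
#'   n_planted_per_cluster = 10, seed = 7))
#' dim(sim$dataset$values)
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "ExpressionSimConfig"))
  set.seed(config$seed)
  design <- standard_design()
  n <- config$n_probes
  k <- nrow(config$cluster_profiles)
  npc <- config$n_planted_per_cluster
  probes <- sprintf("probe_%05d", seq_len(n))

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  values <- matrix(baseline, nrow = n, ncol = 12,
                   dimnames = list(probes, design$sample_id))

  planted_cluster <- integer(0)
  if (npc > 0 && k > 0) {
    planted_cluster <- rep(seq_len(k), each = npc)
    names(planted_cluster) <- probes[seq_along(planted_cluster)]
    for (tp in TREATMENT_TIMES) {
      cols <- design$sample_id[design$time_point == tp]
      fc <- config$cluster_profiles[planted_cluster, tp]
      values[seq_along(planted_cluster), cols] <-
        values[seq_along(planted_cluster), cols] + fc
    }
  }
  if (config$noise_sd > 0)
    values <- values + matrix(rnorm(n * 12, 0, config$noise_sd), n, 12)

  flags <- matrix(ifelse(runif(n * 12) < config$flag_absent_rate, "A", "P"),
                  n, 12, dimnames = dimnames(values))

  # consecutive probes can share a gene (many-to-one probe->gene map)
  gpp <- max(1, round(config$genes_per_probe))
  gene_idx <- ceiling(seq_len(n) / gpp)
  probe_gene <- setNames(sprintf("gene_%05d", gene_idx), probes)

  profiles <- config$cluster_profiles[planted_cluster, , drop = FALSE]
  rownames(profiles) <- names(planted_cluster)
  nz <- which(profiles != 0, arr.ind = TRUE)
  planted_de <- data.frame(
    probe = rownames(profiles)[nz[, 1]],
    time_point = TREATMENT_TIMES[nz[, 2]],
    direction = ifelse(profiles[nz] > 0, "up", "down"),
    log2fc = profiles[nz],
    stringsAsFactors = FALSE)

  list(
    dataset = expression_dataset(values, flags, design, probe_gene),
    truth = list(planted_cluster = planted_cluster,
                 profiles = profiles,
                 planted_de = planted_de))
}

#' Planted differential sets at a fold threshold
#'
#' Derives the per-time-point up/down probe sets implied by the planted
#' profiles, using the same strict |log2FC| > log2(fold) rule as
#' [differential_probes()]; convenient for recovery tests.
#'
#' @param truth the `truth` component of [generate_expression_dataset()].
#' @param fold fold-change threshold (default 3).
#' @return list of lists `up` / `down`, each naming the five treatment
#'   time points.
#' @export
planted_differential_sets <- function(truth, fold = 3) {
  lfc <- log2(fold)
  de <- truth$planted_de
  up <- lapply(TREATMENT_TIMES, function(tp)
    sort(de$probe[de$time_point == tp & de$log2fc > lfc]))
  down <- lapply(TREATMENT_TIMES, function(tp)
    sort(de$probe[de$time_point == tp & de$log2fc < -lfc]))
  names(up) <- names(down) <- TREATMENT_TIMES
  list(up = up, down = down)
}
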