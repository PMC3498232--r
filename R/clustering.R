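# Co-expression clustering and temporal pattern labelling.

# squared Euclidean distance of every row of x to every row of centers
sq_dist_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

# k-means++ seeding: each further center drawn with probability
# proportional to the squared distance to the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  min_d2 <- sq_dist_to_centers(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k)[-1]) {
    if (all(min_d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = min_d2)
    }
    centers[j, ] <- x[idx, ]
    min_d2 <- pmin(min_d2, sq_dist_to_centers(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

# Lloyd iterations; an emptied cluster is re-seeded from the point
# farthest from its assigned centroid
lloyd <- function(x, centers, iter.max) {
  assign_prev <- rep(0L, nrow(x))
  for (it in seq_len(iter.max)) {
    d2 <- sq_dist_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(assign, nrow(centers)) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
      assign[far] <- j
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (j in seq_len(nrow(centers)))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  d2 <- sq_dist_to_centers(x, centers)
  wss <- vapply(seq_len(nrow(centers)), function(j)
    sum(d2[assign == j, j]), numeric(1))
  list(cluster = assign, centers = centers, withinss = wss,
       tot.withinss = sum(wss))
}

#' k-means co-expression clustering
#'
#' Partitions expression profiles into k clusters by Euclidean k-means,
#' the KMC step of the MeV-style workflow: k-means++ seeding, Lloyd
#' iterations (an emptied cluster is re-seeded from the farthest point),
#' several restarts with the best within-cluster sum of squares kept.
#' Deterministic for a given seed. Profiles are typically the 12
#' normalized (median-centered) sample columns; the 5-point log2FC rows
#' can be used instead.
#'
#' @param profiles numeric matrix, one row per probe/gene.
#' @param k number of clusters (default 12).
#' @param seed integer RNG seed.
#' @param nstart k-means++ restarts (default 10).
#' @param iter.max maximum Lloyd iterations per restart.
#' @return `ClusterAssignment`: list with `members` (named integer vector,
#'   row -> cluster in 1..k), `centroids` (k x ncol matrix), `withinss`,
#'   `tot_withinss`, `k`, `seed`, and `pattern_labels` (NULL until
#'   [label_cluster_patterns()] is applied).
#' @export
kmeans_cluster <- function(profiles, k = 12L, seed = 1L, nstart = 10L,
                           iter.max = 100L) {
  stop_if_not_matrix(profiles, "profiles")
  if (k > nrow(profiles))
    stop("`k` cannot exceed the number of rows", call. = FALSE)
  if (k > 1 && nrow(unique(profiles)) == 1L)
    warning("all rows identical: clustering is degenerate for k > 1")
  set.seed(seed)
  fit <- NULL
  for (s in seq_len(nstart)) {
    trial <- lloyd(profiles, kmeanspp_init(profiles, k), iter.max)
    if (is.null(fit) || trial$tot.withinss < fit$tot.withinss) fit <- trial
  }
  dimnames(fit$centers) <- list(seq_len(k), colnames(profiles))
  structure(
    list(members = setNames(fit$cluster, rownames(profiles)),
         centroids = fit$centers,
         withinss = fit$withinss, tot_withinss = fit$tot.withinss,
         k = as.integer(k), seed = as.integer(seed),
         pattern_labels = NULL),
    class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: k =", x$k, ", n =", length(x$members),
      ", total within-SS =", signif(x$tot_withinss, 4), "\n")
  sizes <- tabulate(x$members, x$k)
  for (i in seq_len(x$k))
    cat(sprintf("  #%-2d n=%-5d %s\n", i, sizes[i],
                if (is.null(x$pattern_labels)) "" else x$pattern_labels[i]))
  invisible(x)
}

#' Hierarchical clustering with leaf order
#'
#' Complete-linkage agglomerative clustering (the HCL step) on Euclidean
#' row distance or 1 - Pearson correlation, returning the tree and the
#' leaf order used for heatmap rendering.
#'
#' @param profiles numeric matrix with >= 2 rows.
#' @param linkage linkage method (default "complete").
#' @param distance "euclidean" (rows as points) or "pearson"
#'   (1 - correlation between rows).
#' @return list with `tree` (hclust) and `order` (leaf labels in dendrogram
#'   order).
#' @export
hierarchical_cluster <- function(profiles, linkage = "complete",
                                 distance = c("euclidean", "pearson")) {
  stop_if_not_matrix(profiles, "profiles")
  if (nrow(profiles) < 2) stop("need >= 2 rows", call. = FALSE)
  distance <- match.arg(distance)
  d <- switch(distance,
              euclidean = dist(profiles),
              pearson = as.dist(1 - cor(t(profiles))))
  tree <- hclust(d, method = linkage)
  list(tree = tree, order = rownames(profiles)[tree$order])
}

#' Label a temporal pattern from a centroid log2FC profile
#'
#' Rule-based labelling of a 5-point log2FC centroid (vs CK) using an
#' early window (20min, 60min, 2h) and a late window (4h, 8h):
#' `continuous-up` when all five points are at or above `up_thresh`;
#' `early-up` / `late-up` when only the early / late window mean clears
#' it; mirror rules for down with `-up_thresh`; `early-down-late-up` when
#' the early mean is at or below `-up_thresh` and the late mean at or
#' above `up_thresh`; `mixed` otherwise.
#'
#' @param centroid_log2fc numeric 5-vector of log2FC at
#'   (20min, 60min, 2h, 4h, 8h).
#' @param up_thresh log2FC magnitude a window mean must reach (default 1,
#'   i.e. 2-fold).
#' @return A single pattern label string.
#' @export
#' @examples
#' label_cluster_pattern(c(2, 2, 2, 2, 2))       # continuous-up
#' label_cluster_pattern(c(-2, -1.5, -1.2, 1.5, 2))  # early-down-late-up
label_cluster_pattern <- function(centroid_log2fc, up_thresh = 1.0) {
  stopifnot(length(centroid_log2fc) == 5L, up_thresh > 0)
  v <- as.numeric(centroid_log2fc)
  early <- mean(v[1:3]); late <- mean(v[4:5])
  t <- up_thresh
  if (all(v >= t)) return("continuous-up")
  if (all(v <= -t)) return("continuous-down")
  if (early <= -t && late >= t) return("early-down-late-up")
  if (early >= t && late < t) return("early-up")
  if (late >= t && early < t) return("late-up")
  if (early <= -t && late > -t) return("early-down")
  if (late <= -t && early > -t) return("late-down")
  "mixed"
}

#' Label every cluster of an assignment
#'
#' Converts each centroid to a 5-point log2FC profile (per-time-point
#' replicate means minus the CK mean, when centroids live in the
#' 12-sample space) and applies [label_cluster_pattern()].
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param design the sample design table matching the centroid columns;
#'   ignored when centroids already have the five log2FC columns.
#' @param up_thresh passed to [label_cluster_pattern()].
#' @return The assignment with `pattern_labels` filled in.
#' @export
label_cluster_patterns <- function(assignment, design = standard_design(),
                                   up_thresh = 1.0) {
  stopifnot(inherits(assignment, "ClusterAssignment"))
  cen <- assignment$centroids
  if (ncol(cen) == 5L) {
    lfc <- cen
  } else {
    check_design(design, colnames(cen))
    tp_mean <- function(row, tp)
      mean(row[design$sample_id[design$time_point == tp]])
    lfc <- t(apply(cen, 1, function(row)
      vapply(TREATMENT_TIMES, function(tp) tp_mean(row, tp) - tp_mean(row, "CK"),
             numeric(1))))
  }
  assignment$pattern_labels <- apply(lfc, 1, label_cluster_pattern,
                                     up_thresh = up_thresh)
  assignment
}

#' Annotation-category over-representation per cluster
#'
#' Upper-tail hypergeometric test of each (cluster, category) pair: with
#' `T` genes in the cluster, `t` of them annotated to the category, `k`
#' annotated genes in the universe of `K`, the p-value is P(X >= t) for X
#' hypergeometric(K, k, T). Raw p-values are reported (with an optional
#' Benjamini-Hochberg column) and flagged at `alpha`.
#'
#' @param members named vector or list mapping gene -> cluster index, as in
#'   `ClusterAssignment$members`.
#' @param annotation data.frame with columns `gene` and `category`
#'   (multiple rows per gene allowed).
#' @param universe character vector of all genes tested; must contain every
#'   cluster member.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param bh_correct also report BH-adjusted p-values (default FALSE).
#' @return data.frame with cluster, category, t, T, k, K, p, significant
#'   (and p_bh when requested).
#' @export
category_enrichment <- function(members, annotation, universe,
                                alpha = 0.05, bh_correct = FALSE) {
  stopifnot(all(c("gene", "category") %in% names(annotation)))
  members <- unlist(members)
  if (!all(names(members) %in% universe))
    stop("`universe` must contain every cluster member", call. = FALSE)
  all_cats <- unique(annotation$category)
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  dropped <- setdiff(all_cats, unique(annotation$category))
  if (length(dropped))
    warning("categories with no annotated gene in the universe skipped: ",
            paste(dropped, collapse = ", "))
  K <- length(unique(universe))
  cats <- unique(annotation$category)
  if (!length(cats)) {
    warning("no annotated categories in the universe")
    return(data.frame())
  }
  res <- do.call(rbind, lapply(sort(unique(members)), function(cl) {
    genes <- names(members)[members == cl]
    do.call(rbind, lapply(cats, function(ca) {
      annotated <- unique(annotation$gene[annotation$category == ca])
      t_ <- length(intersect(genes, annotated))
      data.frame(cluster = cl, category = ca,
                 t = t_, T = length(genes),
                 k = length(annotated), K = K,
                 p = hypergeom_tail(t_, length(genes), length(annotated), K),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (bh_correct) res$p_bh <- p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}

#' @importFrom stats p.adjust dist
NULL
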