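# Background database, motif enrichment, windowed co-occurrence, network.

#' Windowed motif co-occurrence per gene
#'
#' Reduces an occurrence table to the unordered pairs of *distinct*
#' motifs that co-occur within `window` bp in each promoter. Distance is
#' measured start-to-start (absolute difference of 1-based leftmost
#' coordinates), strand ignored; a pair is counted at most once per gene
#' no matter how many occurrence pairs qualify.
#'
#' @param occurrences a [scan_motifs()] table.
#' @param window maximum start-to-start distance in bp (default 250,
#'   inclusive).
#' @return data.frame with `gene`, `motif_a`, `motif_b` (`motif_a` <
#'   `motif_b` lexicographically), one row per (gene, pair).
#' @export
cooccurrences <- function(occurrences, window = 250) {
  stopifnot(window >= 0)
  empty <- data.frame(gene = character(0), motif_a = character(0),
                      motif_b = character(0), stringsAsFactors = FALSE)
  if (!nrow(occurrences)) return(empty)
  per_gene <- split(occurrences[c("motif", "start")], occurrences$gene)
  res <- lapply(names(per_gene), function(g) {
    occ <- per_gene[[g]]
    motifs <- sort(unique(occ$motif))
    if (length(motifs) < 2) return(NULL)
    pairs <- combn(motifs, 2)
    hit <- vapply(seq_len(ncol(pairs)), function(j) {
      sa <- occ$start[occ$motif == pairs[1, j]]
      sb <- occ$start[occ$motif == pairs[2, j]]
      min(abs(outer(sa, sb, "-"))) <= window
    }, logical(1))
    if (!any(hit)) return(NULL)
    data.frame(gene = g, motif_a = pairs[1, hit], motif_b = pairs[2, hit],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Build the promoter background database
#'
#' Gene-level motif and motif-pair counts over the whole promoter
#' database, the reference for every enrichment and co-occurrence test:
#' `N` = genes in the database, `n(motif)` = genes containing at least one
#' occurrence, `pair_n(a, b)` = genes in which the unordered pair
#' co-occurs within the window (once-per-gene rule, as in
#' [cooccurrences()]).
#'
#' @param occurrences a [scan_motifs()] table over the full database.
#' @param promoters the promoter set that was scanned (defines `N`,
#'   including genes with no occurrence).
#' @param motifs optional motif library; motifs with zero occurrences then
#'   get explicit `n = 0` entries.
#' @param window co-occurrence window in bp (default 250).
#' @return `BackgroundDB`: list with `N`, `n` (named integer), `pair_n`
#'   (data.frame motif_a, motif_b, count), `window`, `gene_motifs`
#'   (per-gene containment, for cluster lookups) and `gene_pairs`.
#' @export
build_background <- function(occurrences, promoters, motifs = NULL,
                             window = 250) {
  promoters <- as_promoter_set(promoters)
  motif_names <- if (is.null(motifs)) sort(unique(occurrences$motif))
                 else names(validate_motif_library(motifs))
  gene_motifs <- unique(occurrences[c("gene", "motif")])
  n <- table(factor(gene_motifs$motif, levels = motif_names))
  gene_pairs <- cooccurrences(occurrences, window = window)
  pair_n <- if (nrow(gene_pairs)) {
    agg <- aggregate(gene ~ motif_a + motif_b, data = gene_pairs, FUN = length)
    names(agg)[3] <- "count"
    agg
  } else {
    data.frame(motif_a = character(0), motif_b = character(0),
               count = integer(0))
  }
  structure(list(N = length(promoters),
                 n = setNames(as.integer(n), motif_names),
                 pair_n = pair_n, window = window,
                 gene_motifs = gene_motifs, gene_pairs = gene_pairs),
            class = "BackgroundDB")
}

#' @export
print.BackgroundDB <- function(x, ...) {
  cat("BackgroundDB:", x$N, "genes,", length(x$n), "motifs, window",
      x$window, "bp\n")
  print(x$n)
  invisible(x)
}

#' Motif enrichment in a gene cluster
#'
#' For every motif of the background database, counts the cluster genes
#' containing it (`m`, gene-level, once per gene) and tests enrichment
#' against the database background by the upper-tail hypergeometric
#' distribution; also reports the relative-frequency enrichment ratio
#' `(m/M)/(n/N)`. The significance class follows the Cytoscape rendering
#' convention: `diamond` p < 0.001, `triangle` 0.001 <= p < 0.05,
#' `circle` p >= 0.05. Motifs absent from the database (`n = 0`) are
#' skipped.
#'
#' @param cluster_genes character vector of gene IDs forming the cluster;
#'   must be part of the scanned database.
#' @param background a [build_background()] database.
#' @param cluster optional cluster label recorded in the output.
#' @return `EnrichmentResult` data.frame: cluster, motif, m, M, n, N,
#'   ratio, p, class.
#' @export
motif_enrichment <- function(cluster_genes, background, cluster = 1L) {
  stopifnot(inherits(background, "BackgroundDB"))
  cluster_genes <- unique(cluster_genes)
  M <- length(cluster_genes)
  if (M == 0) stop("empty cluster", call. = FALSE)
  gm <- background$gene_motifs
  gm <- gm[gm$gene %in% cluster_genes, , drop = FALSE]
  res <- do.call(rbind, lapply(names(background$n), function(mo) {
    n <- background$n[[mo]]
    if (n == 0) return(NULL)  # enrichment undefined, motif skipped
    m <- sum(gm$motif == mo)
    data.frame(cluster = cluster, motif = mo, m = m, M = M,
               n = n, N = background$N,
               ratio = enrichment_ratio(m, M, n, background$N),
               p = enrichment_pvalue(m, M, n, background$N),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(cluster = integer(0), motif = character(0),
                      m = integer(0), M = integer(0), n = integer(0),
                      N = integer(0), ratio = numeric(0), p = numeric(0))
  res$class <- classify_node(res$p)
  class(res) <- c("EnrichmentResult", class(res))
  rownames(res) <- NULL
  res
}

#' Motif-pair co-occurrence significance in a cluster
#'
#' For every unordered motif pair seen anywhere in the database, counts
#' the cluster genes in which the pair co-occurs within the window (`t`)
#' and tests against the database pair count (`k` of `K` genes) by the
#' upper-tail hypergeometric distribution. Edge class: `solid` p < 0.01,
#' `dash` 0.01 <= p < 0.05, `none` p >= 0.05.
#'
#' @inheritParams motif_enrichment
#' @return `CooccurrenceResult` data.frame: cluster, motif_a, motif_b,
#'   t, T, k, K, p, class.
#' @export
motif_cooccurrence <- function(cluster_genes, background, cluster = 1L) {
  stopifnot(inherits(background, "BackgroundDB"))
  cluster_genes <- unique(cluster_genes)
  T_ <- length(cluster_genes)
  if (T_ == 0) stop("empty cluster", call. = FALSE)
  gp <- background$gene_pairs
  gp_cl <- gp[gp$gene %in% cluster_genes, , drop = FALSE]
  pn <- background$pair_n
  if (!nrow(pn))
    return(structure(
      data.frame(cluster = integer(0), motif_a = character(0),
                 motif_b = character(0), t = integer(0), T = integer(0),
                 k = integer(0), K = integer(0), p = numeric(0),
                 class = character(0)),
      class = c("CooccurrenceResult", "data.frame")))
  res <- do.call(rbind, lapply(seq_len(nrow(pn)), function(i) {
    a <- pn$motif_a[i]; b <- pn$motif_b[i]; k <- pn$count[i]
    t_ <- sum(gp_cl$motif_a == a & gp_cl$motif_b == b)
    data.frame(cluster = cluster, motif_a = a, motif_b = b,
               t = t_, T = T_, k = k, K = background$N,
               p = cooccurrence_pvalue(t_, T_, k, background$N),
               stringsAsFactors = FALSE)
  }))
  res$class <- classify_edge(res$p)
  class(res) <- c("CooccurrenceResult", class(res))
  rownames(res) <- NULL
  res
}

#' Assemble the Cytoscape-style motif network for a cluster
#'
#' One node per motif, with the attributes the rendering maps to node
#' size (`m`, genes containing the motif in the cluster), node color
#' (enrichment ratio) and node shape (significance class: diamond
#' p < 0.001, triangle 0.001 <= p < 0.05, circle otherwise). Edges are the
#' motif pairs with co-occurrence p < 0.05, styled `solid` (p < 0.01) or
#' `dash` (0.01 <= p < 0.05).
#'
#' @param enrichment a [motif_enrichment()] result.
#' @param cooccurrence a [motif_cooccurrence()] result for the same
#'   cluster.
#' @param prune_isolated drop non-significant (circle) nodes that touch no
#'   edge (default FALSE).
#' @return `MotifNetwork`: list with `nodes` (motif, size, color, shape,
#'   p) and `edges` (motif_a, motif_b, p, style).
#' @export
build_network <- function(enrichment, cooccurrence, prune_isolated = FALSE) {
  nodes <- data.frame(motif = enrichment$motif, size = enrichment$m,
                      color = enrichment$ratio, shape = enrichment$class,
                      p = enrichment$p, stringsAsFactors = FALSE)
  keep <- cooccurrence$p < 0.05
  edges <- data.frame(motif_a = cooccurrence$motif_a[keep],
                      motif_b = cooccurrence$motif_b[keep],
                      p = cooccurrence$p[keep],
                      style = cooccurrence$class[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$motif_a %in% nodes$motif &
                 edges$motif_b %in% nodes$motif, , drop = FALSE]
  if (prune_isolated) {
    touched <- unique(c(edges$motif_a, edges$motif_b))
    nodes <- nodes[nodes$shape != "circle" | nodes$motif %in% touched, ,
                   drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "MotifNetwork")
}

#' @export
print.MotifNetwork <- function(x, ...) {
  cat("MotifNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) print(x$nodes)
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
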