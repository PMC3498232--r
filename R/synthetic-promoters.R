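# Synthetic promoter sets with planted cis-elements and element pairs.

#' Configuration for the promoter simulator
#'
#' Describes a promoter database of i.i.d. background sequence (with a
#' configurable GC content) in which motifs are planted: background genes
#' receive each motif independently with `background_freqs`, cluster genes
#' with `motif_plant_freqs`, and `pair_plants` place two motifs at an
#' exact start-to-start distance in a fraction of a cluster's genes.
#' Planted sites never overlap each other (positions are re-drawn on
#' collision); the scanner may of course still find chance matches
#' elsewhere.
#'
#' @param n_background_genes background (non-cluster) genes.
#' @param cluster_sizes integer vector, genes per co-expression cluster.
#' @param promoter_length promoter length in bp (default 3000, the
#'   -3000..-1 region upstream of the ATG).
#' @param gc_content background GC fraction (default 0.43, typical of rice
#'   promoters).
#' @param motifs named IUPAC motif library (default
#'   [default_motif_library()]).
#' @param background_freqs named numeric, motif -> per-gene planting
#'   probability in every gene (background and cluster alike).
#' @param motif_plant_freqs data.frame `cluster`, `motif`, `prob`:
#'   per-gene planting probability within a cluster, overriding the
#'   background rate for that motif. Cluster index 0 targets the
#'   background genes.
#' @param pair_plants data.frame `cluster`, `motif_a`, `motif_b`,
#'   `distance` (start-to-start, bp), `prob`. Cluster index 0 targets the
#'   background genes.
#' @param seed integer RNG seed.
#' @return An object of class `PromoterSimConfig`.
#' @export
promoter_sim_config <- function(n_background_genes = 200,
                                cluster_sizes = 40,
                                promoter_length = 3000,
                                gc_content = 0.43,
                                motifs = default_motif_library(),
                                background_freqs = NULL,
                                motif_plant_freqs = NULL,
                                pair_plants = NULL,
                                seed = 1L) {
  motifs <- validate_motif_library(motifs)
  if (promoter_length < max(nchar(motifs)))
    stop("`promoter_length` must be at least the longest motif",
         call. = FALSE)
  if (gc_content < 0 || gc_content > 1)
    stop("`gc_content` must be in [0, 1]", call. = FALSE)
  full_bg <- setNames(numeric(length(motifs)), names(motifs))
  if (!is.null(background_freqs)) {
    if (!all(names(background_freqs) %in% names(motifs)))
      stop("`background_freqs` names motifs absent from the library",
           call. = FALSE)
    full_bg[names(background_freqs)] <- background_freqs
  }
  background_freqs <- full_bg
  if (is.null(motif_plant_freqs))
    motif_plant_freqs <- data.frame(cluster = integer(0), motif = character(0),
                                    prob = numeric(0))
  if (is.null(pair_plants))
    pair_plants <- data.frame(cluster = integer(0), motif_a = character(0),
                              motif_b = character(0), distance = numeric(0),
                              prob = numeric(0))
  probs <- c(background_freqs, motif_plant_freqs$prob, pair_plants$prob)
  if (any(probs < 0 | probs > 1))
    stop("all planting probabilities must be in [0, 1]", call. = FALSE)
  all_motifs <- c(names(background_freqs), motif_plant_freqs$motif,
                  pair_plants$motif_a, pair_plants$motif_b)
  if (!all(all_motifs %in% names(motifs)))
    stop("planting refers to motifs absent from the library", call. = FALSE)
  if (any(pair_plants$distance < 0))
    stop("planted pair distance must be >= 0", call. = FALSE)
  if (nrow(pair_plants)) {
    len_a <- nchar(motifs[pair_plants$motif_a])
    len_b <- nchar(motifs[pair_plants$motif_b])
    if (any(pair_plants$distance + len_b > promoter_length))
      stop("planted distance + motif length exceeds the promoter length",
           call. = FALSE)
    if (any(pair_plants$distance < len_a))
      stop("planted pair distance smaller than the first motif ",
           "(planted sites would overlap)", call. = FALSE)
  }
  structure(
    list(n_background_genes = as.integer(n_background_genes),
         cluster_sizes = as.integer(cluster_sizes),
         promoter_length = as.integer(promoter_length),
         gc_content = gc_content, motifs = motifs,
         background_freqs = background_freqs,
         motif_plant_freqs = motif_plant_freqs,
         pair_plants = pair_plants, seed = as.integer(seed)),
    class = "PromoterSimConfig")
}

# one concrete instantiation of an IUPAC consensus
IUPAC_CHOICES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(ch) {
    ch_set <- IUPAC_CHOICES[[ch]]
    ch_set[sample.int(length(ch_set), 1L)]
  }, character(1)), collapse = "")
}

# draw a start for a block of `width` bp avoiding `occupied` intervals
draw_start <- function(width, promoter_length, occupied, max_tries = 1000L) {
  hi <- promoter_length - width + 1L
  if (hi < 1L) stop("motif longer than promoter", call. = FALSE)
  for (i in seq_len(max_tries)) {
    s <- sample.int(hi, 1L)
    if (!nrow(occupied) ||
        all(s + width - 1L < occupied$start | s > occupied$end))
      return(s)
  }
  stop("could not place a motif without overlap after ", max_tries,
       " tries", call. = FALSE)
}

#' Simulate a promoter database with planted cis-elements
#'
#' Generates background and cluster promoters per a
#' [promoter_sim_config()] and plants motif instances (and exact-distance
#' motif pairs) into them, recording every planted site as ground truth.
#'
#' @param config a [promoter_sim_config()].
#' @return list with `promoters` (named [Biostrings::DNAStringSet]; all
#'   genes, background first), `motifs` (the library), `cluster_genes`
#'   (list cluster index -> gene IDs) and `truth`: `planted_sites`
#'   (gene, motif, start) and `planted_pairs` (gene, motif_a, motif_b,
#'   distance).
#' @export
generate_promoter_set <- function(config) {
  stopifnot(inherits(config, "PromoterSimConfig"))
  set.seed(config$seed)
  L <- config$promoter_length
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  n_cluster <- sum(config$cluster_sizes)
  n_total <- config$n_background_genes + n_cluster
  genes <- sprintf("gene_%04d", seq_len(n_total))
  cluster_of <- c(rep(0L, config$n_background_genes),
                  rep(seq_along(config$cluster_sizes), config$cluster_sizes))
  cluster_genes <- split(genes[cluster_of > 0L], cluster_of[cluster_of > 0L])

  seqs <- vapply(seq_len(n_total), function(i)
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = ""), character(1))
  names(seqs) <- genes

  sites <- list(); pairs <- list()
  plant <- function(seq, occupied, motif_name, start = NULL) {
    inst <- instantiate_iupac(config$motifs[[motif_name]])
    w <- nchar(inst)
    if (is.null(start)) start <- draw_start(w, L, occupied)
    substr(seq, start, start + w - 1L) <- inst
    list(seq = seq, start = start, width = w)
  }

  for (i in seq_len(n_total)) {
    g <- genes[i]
    occupied <- data.frame(start = integer(0), end = integer(0))
    seq <- seqs[[i]]
    note <- function(start, width)
      occupied <<- rbind(occupied,
                         data.frame(start = start, end = start + width - 1L))

    # exact-distance pair plants (cluster index 0 targets background genes)
    {
      pp <- config$pair_plants[config$pair_plants$cluster == cluster_of[i], ,
                               drop = FALSE]
      for (j in seq_len(nrow(pp))) {
        if (runif(1) >= pp$prob[j]) next
        d <- pp$distance[j]
        wa <- nchar(config$motifs[[pp$motif_a[j]]])
        wb <- nchar(config$motifs[[pp$motif_b[j]]])
        # draw A so that both A and B (at start_A + d) fit and are free
        tries <- 0L
        repeat {
          sa <- sample.int(L - d - wb + 1L, 1L)
          block_free <- !nrow(occupied) ||
            all(sa + d + wb - 1L < occupied$start | sa > occupied$end)
          if (block_free) break
          tries <- tries + 1L
          if (tries >= 1000L)
            stop("could not place a motif pair without overlap",
                 call. = FALSE)
        }
        ra <- plant(seq, occupied, pp$motif_a[j], start = sa)
        seq <- ra$seq; note(ra$start, ra$width)
        rb <- plant(seq, occupied, pp$motif_b[j], start = sa + d)
        seq <- rb$seq; note(rb$start, rb$width)
        sites[[length(sites) + 1L]] <-
          data.frame(gene = g, motif = c(pp$motif_a[j], pp$motif_b[j]),
                     start = c(sa, sa + d), stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene = g, motif_a = pp$motif_a[j],
                     motif_b = pp$motif_b[j], distance = d,
                     stringsAsFactors = FALSE)
      }
    }

    # independent single-motif plants: background rate everywhere plus the
    # cluster-specific rate for cluster genes
    for (mn in names(config$motifs)) {
      prob <- unname(config$background_freqs[mn])
      if (is.na(prob)) prob <- 0
      extra <- config$motif_plant_freqs
      extra <- extra$prob[extra$cluster == cluster_of[i] & extra$motif == mn]
      if (length(extra)) prob <- extra  # cluster-specific rate overrides
      if (prob <= 0 || runif(1) >= prob) next
      r <- plant(seq, occupied, mn)
      seq <- r$seq; note(r$start, r$width)
      sites[[length(sites) + 1L]] <-
        data.frame(gene = g, motif = mn, start = r$start,
                   stringsAsFactors = FALSE)
    }
    seqs[[i]] <- seq
  }

  empty_sites <- data.frame(gene = character(0), motif = character(0),
                            start = integer(0))
  empty_pairs <- data.frame(gene = character(0), motif_a = character(0),
                            motif_b = character(0), distance = numeric(0))
  list(promoters = Biostrings::DNAStringSet(seqs),
       motifs = config$motifs,
       cluster_genes = cluster_genes,
       truth = list(
         planted_sites = if (length(sites)) do.call(rbind, sites)
                         else empty_sites,
         planted_pairs = if (length(pairs)) do.call(rbind, pairs)
                         else empty_pairs))
}
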