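# Plain-text readers and writers for the pipeline's formats.

#' Write / read an expression dataset as TSV + CSV
#'
#' `write_expression_dataset()` writes `expression.tsv` (probe x sample
#' log2 values), `flags.tsv` (same shape, cells P/A/M), `design.csv`
#' (sample_id, time_point, replicate) and, when present,
#' `probe_gene.tsv`; `read_expression_dataset()` reads them back.
#'
#' @param dataset an [expression_dataset()].
#' @param dir output / input directory.
#' @return `write_` returns the directory invisibly; `read_` an
#'   `ExpressionDataset`.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) write.table(
    data.frame(probe = rownames(x), x, check.names = FALSE),
    file.path(dir, file), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(dataset$values, "expression.tsv")
  wt(dataset$flags, "flags.tsv")
  write.csv(dataset$design, file.path(dir, "design.csv"), row.names = FALSE)
  if (!is.null(dataset$probe_gene))
    write.table(data.frame(probe = names(dataset$probe_gene),
                           gene = unname(dataset$probe_gene)),
                file.path(dir, "probe_gene.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(dir) {
  rd <- function(file) {
    d <- read.delim(file.path(dir, file), check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  values <- rd("expression.tsv")
  flags <- rd("flags.tsv")
  design <- read.csv(file.path(dir, "design.csv"))
  pg_path <- file.path(dir, "probe_gene.tsv")
  probe_gene <- NULL
  if (file.exists(pg_path)) {
    pg <- read.delim(pg_path)
    probe_gene <- setNames(pg$gene, pg$probe)
  }
  expression_dataset(values, flags, design, probe_gene)
}

#' Read / write promoter FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; headers are gene IDs.
#'
#' @param path FASTA file path.
#' @param promoters a named [Biostrings::DNAStringSet].
#' @export
read_promoters <- function(path) {
  as_promoter_set(Biostrings::readDNAStringSet(path))
}

#' @rdname read_promoters
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(as_promoter_set(promoters), path)
  invisible(path)
}

#' Read / write a motif library TSV (name <TAB> IUPAC consensus)
#'
#' @param path TSV path. The file has no header.
#' @param motifs named character vector of IUPAC consensi.
#' @export
read_motif_library <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("name", "consensus"))
  validate_motif_library(setNames(d$consensus, d$name))
}

#' @rdname read_motif_library
#' @export
write_motif_library <- function(motifs, path) {
  validate_motif_library(motifs)
  write.table(data.frame(names(motifs), unname(motifs)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a motif network for Cytoscape
#'
#' Writes `<prefix>.sif` (`motifA cooccur motifB`, isolated nodes as bare
#' lines), `<prefix>.nodes.tsv` (motif, size, color, shape, p) and
#' `<prefix>.edges.tsv` (motif_a, motif_b, p, style).
#'
#' @param network a [build_network()] result.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_network_sif <- function(network, prefix) {
  stopifnot(inherits(network, "MotifNetwork"))
  sif <- file.path(paste0(prefix, ".sif"))
  edges <- network$edges
  lines <- character(0)
  if (nrow(edges))
    lines <- paste(edges$motif_a, "cooccur", edges$motif_b, sep = "\t")
  isolated <- setdiff(network$nodes$motif,
                      c(edges$motif_a, edges$motif_b))
  writeLines(c(lines, isolated), sif)
  nf <- paste0(prefix, ".nodes.tsv")
  ef <- paste0(prefix, ".edges.tsv")
  write.table(network$nodes, nf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, nf, ef))
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `truth` component from one of the generators.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
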