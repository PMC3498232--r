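# IUPAC consensus scanning of promoter sequences on both strands.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Validate a motif library
#'
#' Checks every consensus uses only IUPAC nucleotide codes and is at
#' least `min_length` long.
#'
#' @param motifs named character vector, name -> IUPAC consensus.
#' @param min_length minimum consensus length (default 4).
#' @return The library, uppercased, invisibly usable downstream.
#' @export
validate_motif_library <- function(motifs, min_length = 4L) {
  if (is.null(names(motifs)) || any(names(motifs) == ""))
    stop("motifs must be named", call. = FALSE)
  if (anyDuplicated(names(motifs)))
    stop("duplicate motif names", call. = FALSE)
  motifs <- toupper(motifs)
  bad <- vapply(strsplit(motifs, ""),
                function(ch) any(!ch %in% IUPAC_LETTERS), logical(1))
  if (any(bad))
    stop("invalid IUPAC code in motif(s): ",
         paste(names(motifs)[bad], collapse = ", "), call. = FALSE)
  if (any(nchar(motifs) < min_length))
    stop("motif consensus shorter than ", min_length, " nt", call. = FALSE)
  motifs
}

as_promoter_set <- function(promoters) {
  if (is.character(promoters))
    promoters <- tryCatch(
      Biostrings::DNAStringSet(toupper(promoters)),
      error = function(e)
        stop("promoter alphabet restricted to A/C/G/T/N", call. = FALSE))
  if (!methods::is(promoters, "DNAStringSet"))
    stop("`promoters` must be a DNAStringSet or named character vector",
         call. = FALSE)
  if (length(promoters) == 0) return(promoters)
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop("promoters must have unique gene names", call. = FALSE)
  af <- Biostrings::alphabetFrequency(promoters)
  extra <- rowSums(af[, setdiff(colnames(af), c("A", "C", "G", "T", "N")),
                      drop = FALSE])
  if (any(extra > 0))
    stop("promoter alphabet restricted to A/C/G/T/N", call. = FALSE)
  promoters
}

# matches of one degenerate pattern against all promoters; returns
# data.frame(gene, start, width). An N in the *sequence* never matches.
match_one <- function(pattern, promoters, has_n) {
  hits <- Biostrings::vmatchPattern(pattern, promoters, fixed = "subject")
  n_hits <- S4Vectors::elementNROWS(hits)
  if (sum(n_hits) == 0)
    return(data.frame(gene = character(0), start = integer(0),
                      width = integer(0)))
  ul <- unlist(hits)
  out <- data.frame(gene = rep(names(promoters), n_hits),
                    start = BiocGenerics::start(ul),
                    width = BiocGenerics::width(ul),
                    stringsAsFactors = FALSE)
  if (any(has_n[out$gene])) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      if (!has_n[out$gene[i]]) return(TRUE)
      s <- Biostrings::subseq(promoters[[out$gene[i]]], out$start[i],
                              width = out$width[i])
      Biostrings::countPattern("N", s, fixed = TRUE) == 0
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Scan promoters for cis-element occurrences
#'
#' Exhaustive degenerate (IUPAC) consensus matching of every motif at
#' every offset of every promoter, on both strands. A reverse-strand
#' match is reported at the forward-strand coordinate of its leftmost
#' base; `N` in a promoter sequence matches nothing; overlapping matches
#' are all reported.
#'
#' @param promoters a named [Biostrings::DNAStringSet] (or named character
#'   vector) of promoter sequences, conventionally the -3000..-1 region
#'   upstream of the ATG.
#' @param motifs named character vector of IUPAC consensi (validated with
#'   [validate_motif_library()]).
#' @return data.frame of occurrences: `gene`, `motif`, `start` (1-based,
#'   leftmost base, promoter-local), `strand` (`+`/`-`), `width`.
#' @export
#' @examples
#' scan_motifs(c(g1 = "AAAGCCGCCAAA"), c("GCC-box" = "GCCGCC"))
scan_motifs <- function(promoters, motifs) {
  promoters <- as_promoter_set(promoters)
  motifs <- validate_motif_library(motifs)
  has_n <- setNames(
    Biostrings::alphabetFrequency(promoters)[, "N"] > 0, names(promoters))
  res <- lapply(names(motifs), function(mn) {
    pat <- motifs[[mn]]
    fwd <- match_one(pat, promoters, has_n)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pat)))
    if (identical(rc, pat)) {
      # palindromic consensus: minus-strand matches coincide with plus
      rev <- fwd
    } else {
      rev <- match_one(rc, promoters, has_n)
    }
    rbind(
      if (nrow(fwd)) cbind(fwd, motif = mn, strand = "+"),
      if (nrow(rev)) cbind(rev, motif = mn, strand = "-"))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(gene = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      width = integer(0)))
  res <- res[order(res$gene, res$motif, res$start, res$strand),
             c("gene", "motif", "start", "strand", "width")]
  rownames(res) <- NULL
  res
}
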