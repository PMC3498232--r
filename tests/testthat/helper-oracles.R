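# Independent brute-force oracles and small fixture builders.

# Upper-tail hypergeometric by exhaustive enumeration of all M-subsets of
# a population 1..N whose first n items are the "successes".
oracle_hyper_tail <- function(m, M, n, N) {
  if (M == 0) return(as.numeric(m <= 0))
  subsets <- combn(N, M)
  x <- colSums(matrix(subsets <= n, nrow = M))
  mean(x >= m)
}

# tiny expression dataset with hand-set values/flags
tiny_dataset <- function(values, flags = NULL, probe_gene = NULL) {
  design <- standard_design()
  colnames(values) <- design$sample_id
  if (!is.null(flags)) colnames(flags) <- design$sample_id
  expression_dataset(values, flags, design, probe_gene)
}

# occurrence-table builder for co-occurrence unit fixtures
occ_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1]], motif = r[[2]], start = as.integer(r[[3]]),
               strand = if (length(r) > 3) r[[4]] else "+",
               width = 6L, stringsAsFactors = FALSE)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
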