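# IUPAC scanning, background counting, hypergeometric enrichment,
# windowed co-occurrence and the Cytoscape-style network.

test_that("scanning finds direct, reverse-complement and degenerate matches", {
  occ <- scan_motifs(c(g1 = "AAAGCCGCCAAA"), c(gcc = "GCCGCC"))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$start, 4)
  expect_identical(occ$strand, "+")

  # GGCGGC is the reverse complement of GCCGCC
  occ2 <- scan_motifs(c(g1 = "TTTGGCGGCTTT"), c(gcc = "GCCGCC"))
  expect_equal(nrow(occ2), 1)
  expect_identical(occ2$strand, "-")
  expect_equal(occ2$start, 4)  # forward-strand coordinate of leftmost base

  # M = A or C
  occ3 <- scan_motifs(c(a = "TAACGTGT", b = "TCACGTGT"), c(m = "MACGTG"))
  expect_equal(nrow(occ3[occ3$strand == "+", ]), 2)

  # overlapping matches are all reported
  occ4 <- scan_motifs(c(g = "ATATATATAT"), c(at = "ATAT"))
  expect_equal(sum(occ4$strand == "+"), 4)
})

test_that("N in the sequence matches nothing; bad inputs are rejected", {
  expect_equal(nrow(scan_motifs(c(g = "AAGCCNCCAA"), c(x = "GCCNCC"))), 0)
  expect_error(scan_motifs(c(g = "ACGT"), c(x = "GCQGCC")), "IUPAC")
  expect_error(scan_motifs(c(g = "ACGT"), c(x = "GCC")), "shorter")
  expect_error(scan_motifs(c(g = "ACGU"), c(x = "GCCGCC")), "alphabet")
  expect_equal(nrow(scan_motifs(character(0), c(x = "GCCGCC"))), 0)
})

test_that("occurrence counts are invariant under reverse complement", {
  set.seed(11)
  motifs <- default_motif_library()
  for (i in 1:5) {
    s <- random_dna(500)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    n1 <- table(factor(scan_motifs(c(g = s), motifs)$motif,
                       levels = names(motifs)))
    n2 <- table(factor(scan_motifs(c(g = rc), motifs)$motif,
                       levels = names(motifs)))
    expect_equal(as.vector(n1), as.vector(n2))
  }
})

test_that("background counts genes, not occurrences", {
  proms <- c(g1 = "AAGCCGCCAAAGCCGCCAAAGCCGCCTT",  # 3 hits of one motif
             g2 = "AATTTTTTTTTTTTTTTTTTTTTTTTTT",
             g3 = "TTGCCGCCTTTTTTTTTTTTTTTTTTTT")
  lib <- c(gcc = "GCCGCC", ce3 = "ACGCGTGTC")
  bg <- build_background(scan_motifs(proms, lib), proms, lib)
  expect_equal(bg$N, 3)
  expect_equal(unname(bg$n["gcc"]), 2L)   # g1 counts once
  expect_equal(unname(bg$n["ce3"]), 0L)   # absent everywhere
})

test_that("hypergeometric tails match enumeration and phyper", {
  expect_equal(hypergeom_tail(4, 4, 5, 10), 5 / 210, tolerance = 1e-15)
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1)
  set.seed(2)
  for (i in 1:40) {
    N <- sample(2:12, 1); n <- sample(0:N, 1); M <- sample(1:N, 1)
    m <- sample(0:min(n, M), 1)
    p <- hypergeom_tail(m, M, n, N)
    expect_equal(p, oracle_hyper_tail(m, M, n, N), tolerance = 1e-12)
    expect_equal(p, phyper(m - 1, n, N - n, M, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # non-increasing in m
  ps <- vapply(0:8, function(m) hypergeom_tail(m, 8, 10, 20), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_tail(5, 4, 5, 10), "m cannot exceed")
  expect_error(hypergeom_tail(2, 4, 13, 12), "<= N")
})

test_that("enrichment ratio is the relative containment frequency", {
  expect_equal(enrichment_ratio(10, 100, 100, 1000), 1)
  expect_equal(enrichment_ratio(20, 100, 100, 1000), 2)
  expect_equal(enrichment_ratio(0, 100, 100, 1000), 0)
  expect_true(is.na(enrichment_ratio(0, 100, 0, 1000)))
})

test_that("co-occurrence counting: window, once-per-gene, symmetry", {
  # distance 200 <= 250 -> pair present; 300 -> absent
  occ <- occ_table(list("g1", "A", 100), list("g1", "B", 300),
                   list("g2", "A", 100), list("g2", "B", 400))
  pairs <- cooccurrences(occ, window = 250)
  expect_identical(pairs$gene, "g1")
  # boundary: exactly 250 apart counts as co-occurring
  occ_b <- occ_table(list("g", "A", 100), list("g", "B", 350))
  expect_equal(nrow(cooccurrences(occ_b, 250)), 1)
  expect_equal(nrow(cooccurrences(occ_b, 249)), 0)
  # multiple qualifying occurrence pairs still count once per gene
  occ_m <- occ_table(list("g", "A", 100), list("g", "A", 150),
                     list("g", "B", 200), list("g", "B", 240))
  expect_equal(nrow(cooccurrences(occ_m, 250)), 1)
  # self-pairs excluded; order normalized
  occ_s <- occ_table(list("g", "A", 100), list("g", "A", 120))
  expect_equal(nrow(cooccurrences(occ_s, 250)), 0)
  occ_o <- occ_table(list("g", "B", 100), list("g", "A", 120))
  p <- cooccurrences(occ_o, 250)
  expect_identical(c(p$motif_a, p$motif_b), c("A", "B"))
  # strand is ignored for distance
  occ_str <- occ_table(list("g", "A", 100, "-"), list("g", "B", 200, "+"))
  expect_equal(nrow(cooccurrences(occ_str, 250)), 1)
})

test_that("co-occurrence p-value is symmetric and oracle-exact", {
  expect_equal(cooccurrence_pvalue(4, 4, 5, 10), 5 / 210, tolerance = 1e-15)
  expect_equal(cooccurrence_pvalue(0, 4, 5, 10), 1)
  expect_error(cooccurrence_pvalue(1, 4, 0, 10), "inconsistent background")
})

test_that("window enlargement never decreases pair counts", {
  set.seed(4)
  proms <- setNames(replicate(30, random_dna(1500, gc = 0.55)),
                    sprintf("g%02d", 1:30))
  occ <- scan_motifs(proms, default_motif_library())
  n_prev <- -1
  for (w in c(50, 150, 250, 500, 1500)) {
    n_w <- nrow(cooccurrences(occ, w))
    expect_gte(n_w, n_prev)
    n_prev <- n_w
  }
})

test_that("whole-database 'cluster' is unenriched everywhere", {
  set.seed(9)
  proms <- setNames(replicate(60, random_dna(1200, gc = 0.5)),
                    sprintf("g%02d", 1:60))
  lib <- default_motif_library()
  bg <- build_background(scan_motifs(proms, lib), proms, lib)
  en <- motif_enrichment(names(proms), bg)
  expect_true(all(abs(en$ratio - 1) < 1e-12))
  expect_true(all(en$p > 0.4))
  co <- motif_cooccurrence(names(proms), bg)
  expect_true(all(co$class != "solid"))
})

test_that("node and edge significance classes follow the legend thresholds", {
  expect_identical(unname(panicleHeat:::classify_node(
    c(0.0005, 0.001, 0.03, 0.05, 0.2))),
    c("diamond", "triangle", "triangle", "circle", "circle"))
  expect_identical(unname(panicleHeat:::classify_edge(
    c(0.005, 0.01, 0.03, 0.05, 0.2))),
    c("solid", "dash", "dash", "none", "none"))
})

test_that("the network keeps only significant edges and styles them", {
  enr <- data.frame(cluster = 1, motif = c("A", "B", "C"),
                    m = c(10, 8, 1), M = 20, n = c(15, 12, 30), N = 200,
                    ratio = c(5, 4, 0.3), p = c(5e-4, 0.02, 0.9),
                    class = c("diamond", "triangle", "circle"))
  co <- data.frame(cluster = 1,
                   motif_a = c("A", "A", "B"), motif_b = c("B", "C", "C"),
                   t = c(6, 2, 1), T = 20, k = c(8, 10, 12), K = 200,
                   p = c(0.005, 0.03, 0.2),
                   class = c("solid", "dash", "none"))
  net <- build_network(enr, co)
  expect_equal(nrow(net$edges), 2)
  expect_identical(net$edges$style, c("solid", "dash"))
  expect_identical(net$nodes$shape, c("diamond", "triangle", "circle"))
  pruned <- build_network(enr, co[co$motif_a == "A" & co$motif_b == "B", ],
                          prune_isolated = TRUE)
  expect_false("C" %in% pruned$nodes$motif)

  d <- withr::local_tempdir()
  files <- write_network_sif(net, file.path(d, "net"))
  sif <- readLines(file.path(d, "net.sif"))
  expect_true(any(grepl("^A\tcooccur\tB$", sif)))
  expect_true(file.exists(file.path(d, "net.nodes.tsv")))
})

test_that("motif library and promoter FASTA round-trip through files", {
  d <- withr::local_tempdir()
  lib <- default_motif_library()
  write_motif_library(lib, file.path(d, "lib.tsv"))
  expect_identical(read_motif_library(file.path(d, "lib.tsv")), lib)
  set.seed(1)
  proms <- Biostrings::DNAStringSet(
    setNames(replicate(5, random_dna(200)), sprintf("g%d", 1:5)))
  write_promoters(proms, file.path(d, "p.fa"))
  back <- read_promoters(file.path(d, "p.fa"))
  expect_identical(as.character(back), as.character(proms))
})
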