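# Normalization, QC, flag filtering and differential / HR calling.

test_that("quantile normalization matches the hand-computed rank means", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical columns are a fixed point
  m2 <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  expect_equal(quantile_normalize(m2), m2)
  expect_warning(quantile_normalize(matrix(1:3, ncol = 1)), "single-column")
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(1)
  for (i in 1:3) {
    m <- matrix(rnorm(200 * 6, mean = i), 200, 6)
    q <- quantile_normalize(m)
    sorted <- apply(q, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
})

test_that("baseline_to_median centers rows and is idempotent", {
  m <- rbind(c(5, 5, 5), c(1, 2, 3))
  b <- baseline_to_median(m)
  expect_equal(unname(b), rbind(c(0, 0, 0), c(-1, 0, 1)))
  expect_equal(baseline_to_median(b), b)
  expect_true(all(apply(b, 1, median) == 0))
})

test_that("replicate correlation flags bad replicates and handles edge cases", {
  design <- standard_design()
  set.seed(7)
  base <- matrix(rnorm(5000 * 6, 8, 2), 5000, 6)
  values <- base[, rep(1:6, each = 2)] + rnorm(5000 * 12, sd = 0.05)
  colnames(values) <- design$sample_id
  qc <- replicate_correlation(values, design)
  expect_true(all(qc$replicate_qc$pass))
  expect_true(all(qc$replicate_qc$r > 0.99))
  # each replicate pair merges first in the complete-linkage tree
  merges <- qc$tree$merge[1:6, ]
  first_pairs <- apply(merges, 1, function(r) {
    if (any(r > 0)) return(NA_character_)
    ids <- colnames(values)[-r]
    paste(sort(sub("-[12]$", "", ids)), collapse = "|")
  })
  expect_setequal(first_pairs,
                  sapply(TIME_POINTS, function(tp) paste(tp, tp, sep = "|")))

  # duplicated column: r = 1; negated column: r = -1
  v2 <- values
  v2[, "CK-2"] <- v2[, "CK-1"]
  cors <- replicate_correlation(v2, design)$correlations
  expect_equal(cors["CK-1", "CK-2"], 1)
  expect_equal(cor(values[, 1], -values[, 1]), -1)

  # zero-variance column reported as failure
  v3 <- values
  v3[, "8h-2"] <- 0
  expect_warning(qc3 <- replicate_correlation(v3, design), "zero-variance")
  expect_false(qc3$replicate_qc$pass[qc3$replicate_qc$time_point == "8h"])
})

test_that("flag filter keeps exactly the probes with >= 6 of 12 P flags", {
  flags <- t(sapply(0:12, function(k) c(rep("P", k), rep("A", 12 - k))))
  values <- matrix(0, 13, 12)
  rownames(values) <- rownames(flags) <- sprintf("pr%02d", 0:12)
  ds <- tiny_dataset(values, flags)
  kept <- suppressMessages(flag_filter(ds))
  expect_identical(kept, sprintf("pr%02d", 6:12))
  # M flags never count as present
  flags_m <- matrix("M", 1, 12, dimnames = list("pm", NULL))
  dm <- tiny_dataset(matrix(0, 1, 12, dimnames = list("pm", NULL)), flags_m)
  expect_length(suppressMessages(flag_filter(dm)), 0)
})

test_that("fold changes are differences of replicate-mean log2 values", {
  values <- matrix(3, 1, 12, dimnames = list("p1", NULL))
  ds <- tiny_dataset(values)
  # 20min replicates at log2 4.585 vs CK 3.0 -> ~ 3-fold
  ds$values[1, c("20min-1", "20min-2")] <- 4.585
  ds$values[1, c("2h-1", "2h-2")] <- 1  # 4-fold down
  fct <- fold_changes(ds)
  expect_equal(unname(fct["p1", "20min"]), 1.585)
  expect_equal(unname(fct["p1", "2h"]), -2)
  expect_equal(unname(fct["p1", "8h"]), 0)
})

test_that("differential calls use strict more-than-threshold inequalities", {
  fct <- matrix(0, 3, 5, dimnames = list(c("a", "b", "c"), TREATMENT_TIMES))
  fct["a", "20min"] <- 2.0          # 4-fold up
  fct["b", "60min"] <- log2(3)      # exactly 3-fold: excluded
  fct["c", "2h"] <- -1.7            # ~3.25-fold down
  calls <- differential_probes(fct, fold = 3)
  expect_identical(calls$up[["20min"]], "a")
  expect_length(calls$up[["60min"]], 0)
  expect_identical(calls$down[["2h"]], "c")
  expect_error(differential_probes(fct, fold = 1), "> 1")
  # up and down are disjoint at every time point
  for (tp in TREATMENT_TIMES)
    expect_length(intersect(calls$up[[tp]], calls$down[[tp]]), 0)
})

test_that("all-time-point intersection and HR rules are direction-agnostic", {
  fct <- matrix(0, 4, 5, dimnames = list(sprintf("p%d", 1:4), TREATMENT_TIMES))
  fct["p1", ] <- c(2, 2, -2, 2, 2)        # differential at all 5, mixed signs
  fct["p2", ] <- c(2, 2, 2, 2, 0)         # 4 of 5
  fct["p3", ] <- c(2, 0, 0, 0, -2)        # 2 of 5, opposite directions
  fct["p4", ] <- c(2, 0, 0, 0, 0)         # 1 of 5
  calls <- differential_probes(fct, 3)
  expect_identical(intersect_all_timepoints(calls)$probes, "p1")
  hr <- heat_responsive(calls)
  expect_identical(hr$probes, c("p1", "p2", "p3"))
  expect_error(heat_responsive(calls, min_timepoints = 6), "exceed")
  # empty calls give empty sets
  empty <- differential_probes(fct * 0, 3)
  expect_length(intersect_all_timepoints(empty)$probes, 0)
  expect_length(heat_responsive(empty)$probes, 0)
})

test_that("probe sets collapse to genes by the any-probe rule", {
  pg <- c(P1 = "G", P2 = "G", P3 = "H")
  expect_identical(map_probes_to_genes(c("P1", "P2"), pg), "G")
  expect_identical(map_probes_to_genes(c("P1", "P3"), pg), c("G", "H"))
  expect_warning(out <- map_probes_to_genes(c("P1", "PX"), pg), "1 probe")
  expect_identical(out, "G")
})

test_that("thresholds are monotone: higher bars never enlarge the sets", {
  sim <- generate_expression_dataset(
    expression_sim_config(n_probes = 600, n_planted_per_cluster = 20,
                          noise_sd = 0.4, flag_absent_rate = 0, seed = 13))
  fct <- fold_changes(sim$dataset)
  c3 <- differential_probes(fct, 3)
  c4 <- differential_probes(fct, 4)
  for (tp in TREATMENT_TIMES) {
    expect_true(all(c4$up[[tp]] %in% c3$up[[tp]]))
    expect_true(all(c4$down[[tp]] %in% c3$down[[tp]]))
  }
  hr1 <- heat_responsive(c3, min_timepoints = 1)
  hr2 <- heat_responsive(c3, min_timepoints = 2)
  hr5 <- heat_responsive(c3, min_timepoints = 5)
  venn <- intersect_all_timepoints(c3)
  expect_true(all(hr2$probes %in% hr1$probes))
  expect_true(all(hr5$probes %in% hr2$probes))
  expect_true(all(venn$probes %in% hr2$probes))
  expect_identical(sort(venn$probes), sort(hr5$probes))
  # gene count never exceeds probe count
  genes <- map_probes_to_genes(hr2$probes, sim$dataset$probe_gene)
  expect_lte(length(genes), length(hr2$probes))
})

test_that("datasets survive a TSV round trip", {
  sim <- generate_expression_dataset(
    expression_sim_config(n_probes = 30, n_planted_per_cluster = 1,
                          seed = 5))
  dir <- withr::local_tempdir()
  write_expression_dataset(sim$dataset, dir)
  back <- read_expression_dataset(dir)
  expect_equal(back$values, sim$dataset$values)
  expect_identical(back$flags, sim$dataset$flags)
  expect_identical(unname(back$probe_gene[rownames(back$values)]),
                   unname(sim$dataset$probe_gene[rownames(back$values)]))
})
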