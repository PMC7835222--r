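make_de <- function(genes, lfc, sig = TRUE, label = "A") {
  as_tbl <- tibble::tibble(gene = genes, log2fc = lfc,
                           significant = rep_len(sig, length(genes)))
  attr(as_tbl, "condition_label") <- label
  class(as_tbl) <- c("de_table", class(as_tbl))
  as_tbl
}

al1_pr3 <- function(dir_prmt3) {
  regulator_rule(paste0("AL1High_PR3", if (dir_prmt3 == "down") "Low" else "High"),
                 c("ALDH1A1", "PRMT3"), c("up", dir_prmt3))
}

test_that("regulator rules classify the two condition archetypes", {
  # ALDH1A1 strongly up, PRMT3 down -> AL1-high / PR3-low
  de1 <- make_de(c("ALDH1A1", "PRMT3", "GAPDH"), c(3.8, -1.2, 0.1))
  c1 <- classify_condition(de1, al1_pr3("down"))
  expect_true(c1$matched)
  expect_equal(c1$label, "AL1High_PR3Low")

  # ALDH1A1 modestly up, PRMT3 up -> AL1-high / PR3-high
  de2 <- make_de(c("ALDH1A1", "PRMT3"), c(1.4, 0.9))
  c2 <- classify_condition(de2, al1_pr3("up"))
  expect_equal(c2$label, "AL1High_PR3High")

  # non-significant regulator blocks classification
  de3 <- make_de(c("ALDH1A1", "PRMT3"), c(3.8, -1.2), sig = c(FALSE, TRUE))
  c3 <- classify_condition(de3, al1_pr3("down"))
  expect_equal(c3$label, "unclassified")
  expect_equal(c3$diagnostics$reason[1], "not_significant")

  # missing regulator is diagnosed, not an error
  de4 <- make_de(c("ALDH1A1"), 3.8)
  c4 <- classify_condition(de4, al1_pr3("down"))
  expect_equal(c4$diagnostics$reason[2], "regulator_missing")
})

test_that("target intersection keeps the shared requested-direction class", {
  up_genes <- sprintf("T%02d", 1:40)
  targets <- tibble::tibble(gene = c(up_genes, "D1", "D2", "D3", "D4", "D5"),
                            direction = rep(c("up", "down"), c(40, 5)))
  de_a <- make_de(up_genes[1:36], rnorm(36), label = "A")
  de_b <- make_de(up_genes[4:40], rnorm(37), label = "B")
  shared <- intersect_targets(list(de_a, de_b), targets, "up")
  expect_equal(nrow(shared), 33L)  # 4..36 present in both
  expect_false("T01" %in% shared$gene)

  # the 5-member down class is refused under the default minimum of 6
  expect_error(intersect_targets(list(de_a, de_b), targets, "down"),
               class = "coevkit_class_too_small")
  expect_error(intersect_targets(list(de_a), targets, "up"), "at least 2")
})

test_that("directionality analysis reports medians, counts and tests coherently", {
  genes <- sprintf("G%02d", 1:10)
  shared <- tibble::tibble(gene = genes,
                           log2fc_a = c(2, 3, 1, 4, 2.5, -1, 3, 2, 1.5, 2.2),
                           log2fc_b = c(-2, -3, -1, -4, -2.5, 1, -3, -2, -1.5, -2.2))
  attr(shared, "condition_labels") <- c("condA", "condB")
  rep_out <- directionality_analysis(shared)
  expect_equal(unname(rep_out$medians),
               c(median(shared$log2fc_a), median(shared$log2fc_b)))
  expect_equal(unname(rep_out$up_counts), c(9L, 1L))
  expect_equal(rep_out$up_counts + rep_out$down_counts,
               c(condA = 10L, condB = 10L))
  # report is recomputable from the emitted per-gene table
  pg <- rep_out$per_gene
  expect_equal(unname(rep_out$medians[1]), median(pg$log2fc_a))
  expect_equal(unname(rep_out$up_counts[2]), sum(pg$log2fc_b >= 0))
  expect_true(all(diff(pg$delta) <= 0))  # ordered by delta

  # swapping condition order flips columns, not p-values
  swapped <- shared
  swapped$log2fc_a <- shared$log2fc_b
  swapped$log2fc_b <- shared$log2fc_a
  attr(swapped, "condition_labels") <- c("condB", "condA")
  rep_sw <- directionality_analysis(swapped)
  expect_equal(rep_sw$rank_sum$p_value, rep_out$rank_sum$p_value)
  expect_equal(rep_sw$fisher$p_value, rep_out$fisher$p_value)
  expect_equal(unname(rep_sw$medians), unname(rev(rep_out$medians)))
})

test_that("degenerate and extreme inputs are flagged, not mangled", {
  genes <- sprintf("G%02d", 1:6)
  same <- tibble::tibble(gene = genes, log2fc_a = rep(1, 6),
                         log2fc_b = rep(1, 6))
  rep_same <- directionality_analysis(same)
  expect_true(rep_same$degenerate)
  expect_equal(rep_same$rank_sum$p_value, 1)

  # fully separated directions give the minimal attainable Fisher p
  split <- tibble::tibble(gene = genes, log2fc_a = rep(2, 6),
                          log2fc_b = rep(-2, 6))
  rep_split <- directionality_analysis(split)
  expect_equal(unname(rep_split$up_counts), c(6L, 0L))
  expect_equal(rep_split$fisher$p_value,
               fisher_exact_2x2(matrix(c(6, 0, 0, 6), 2, byrow = TRUE))$p_value)
})

test_that("the planted DE signal is recovered through the full analysis", {
  sim <- simulate_de_tables(de_sim_config(seed = 21L))
  shared <- intersect_targets(list(sim$table_a, sim$table_b), sim$targets, "up")
  rep_out <- directionality_analysis(shared)
  expect_equal(rep_out$n_shared, 33L)
  expect_lt(abs(rep_out$medians[[1]] - 2.5), 0.5)
  expect_lt(abs(rep_out$medians[[2]] - (-2.6)), 0.5)
  expect_lt(rep_out$rank_sum$p_value, 1e-4)
  expect_lt(rep_out$fisher$p_value, 0.01)
})

test_that("gene matching is case-insensitive with unique symbols", {
  de_a <- make_de(c("Rai3", "TIG1"), c(2, 1), label = "A")
  de_b <- make_de(c("RAI3", "tig1"), c(-2, -1), label = "B")
  targets <- tibble::tibble(gene = sprintf("RAI%d", c(3, 4, 5, 6, 7, 8)),
                            direction = "up")
  targets$gene[2:6] <- c("TIG1", "X1", "X2", "X3", "X4")
  shared <- intersect_targets(list(de_a, de_b), targets, "up",
                              min_class_size = 2L)
  expect_equal(nrow(shared), 2L)
})
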