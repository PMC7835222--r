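## expression_partition: classify expression-profiling conditions by the
## fold-change signs of the two regulators (ALDH1A1 / PRMT3), intersect the
## literature retinoic-acid target list across conditions, and test whether
## target fold-change directionality differs between the condition classes.

#' Define a regulator classification rule
#'
#' A condition matches the rule when every listed regulator gene is present
#' in its DE table, significant (where required), and has the required
#' fold-change sign. Example: ALDH1A1 up + PRMT3 down defines the
#' "AL1-high / PR3-low" class.
#'
#' @param label class label assigned on a match.
#' @param genes character vector of regulator gene symbols.
#' @param directions matching vector of `"up"` / `"down"` requirements.
#' @param require_significant logical scalar or vector: demand significance.
#' @return list of class `regulator_rule`.
#' @export
regulator_rule <- function(label, genes, directions,
                           require_significant = TRUE) {
  if (length(genes) == 0L) abort("rule needs at least one gene")
  if (anyDuplicated(genes)) abort("rule genes must be unique")
  if (length(directions) != length(genes) ||
      any(!(directions %in% c("up", "down")))) {
    abort("`directions` must be 'up'/'down', one per gene")
  }
  require_significant <- rep_len(require_significant, length(genes))
  structure(list(label = label, genes = as.character(genes),
                 directions = directions,
                 require_significant = require_significant),
            class = "regulator_rule")
}

#' Classify a condition by its regulator fold changes
#'
#' @param de a `de_table`.
#' @param rule a [regulator_rule()].
#' @return list: `label` (the rule's label, or `"unclassified"`), `matched`
#'   (logical), `diagnostics` (per-gene tibble with the failure reason:
#'   `ok`, `regulator_missing`, `not_significant`, or `wrong_direction`).
#'   Gene matching is case-insensitive.
#' @export
classify_condition <- function(de, rule) {
  stopifnot(inherits(rule, "regulator_rule"))
  idx <- match(toupper(rule$genes), toupper(de$gene))
  reason <- character(length(rule$genes))
  for (k in seq_along(rule$genes)) {
    if (is.na(idx[k])) {
      reason[k] <- "regulator_missing"
    } else if (rule$require_significant[k] && !isTRUE(de$significant[idx[k]])) {
      reason[k] <- "not_significant"
    } else {
      sgn_ok <- if (rule$directions[k] == "up") {
        de$log2fc[idx[k]] > 0
      } else {
        de$log2fc[idx[k]] < 0
      }
      reason[k] <- if (sgn_ok) "ok" else "wrong_direction"
    }
  }
  matched <- all(reason == "ok")
  list(label = if (matched) rule$label else "unclassified",
       matched = matched,
       diagnostics = tibble::tibble(
         gene = rule$genes, required = rule$directions,
         log2fc = ifelse(is.na(idx), NA_real_, de$log2fc[idx]),
         reason = reason))
}

#' Intersect literature targets of one direction class across DE tables
#'
#' Keeps the targets of the requested direction that are present in every
#' table. A direction class smaller than `min_class_size` is refused with a
#' classed error (`coevkit_class_too_small`) -- the analysis cannot say
#' anything meaningful about a handful of genes, mirroring the exclusion of
#' the five known downregulated targets in the motivating analysis.
#'
#' @param tables list of >= 2 `de_table`s.
#' @param targets target-list tibble (columns `gene`, `direction`).
#' @param direction_class `"up"` or `"down"`.
#' @param min_class_size smallest usable class (default 6).
#' @return tibble `gene`, `log2fc_a`, `log2fc_b`, ... one fold-change column
#'   per table, with attribute `condition_labels`.
#' @export
intersect_targets <- function(tables, targets,
                              direction_class = c("up", "down"),
                              min_class_size = 6L) {
  direction_class <- match.arg(direction_class)
  min_class_size <- check_count(min_class_size, "min_class_size")
  if (length(tables) < 2L) abort("need at least 2 DE tables")
  class_genes <- targets$gene[targets$direction == direction_class]
  if (length(class_genes) < min_class_size) {
    abort(sprintf(
      "class_too_small: %d '%s' targets (< min_class_size = %d); class excluded",
      length(class_genes), direction_class, min_class_size),
      class = "coevkit_class_too_small")
  }
  labels <- vapply(tables, function(t) {
    as.character(attr(t, "condition_label"))
  }, character(1))
  shared <- class_genes
  for (t in tables) shared <- shared[toupper(shared) %in% toupper(t$gene)]
  if (length(shared) == 0L) abort("no targets shared by all tables")
  out <- tibble::tibble(gene = shared)
  for (k in seq_along(tables)) {
    idx <- match(toupper(shared), toupper(tables[[k]]$gene))
    out[[paste0("log2fc_", letters[k])]] <- tables[[k]]$log2fc[idx]
  }
  attr(out, "condition_labels") <- labels
  attr(out, "direction_class") <- direction_class
  out
}

#' Fold-change directionality analysis of shared targets
#'
#' Given the shared targets' fold changes in two condition classes, reports
#' the per-condition medians, up/down counts and proportions (log2FC > 0 is
#' "up"; exact zeros are counted as up and flagged), the Wilcoxon rank-sum
#' comparison of the two fold-change distributions, Fisher's exact test on
#' the condition x direction 2x2 table, and a per-gene fold-change
#' difference table ordered by difference (the heatmap input).
#'
#' @param shared output of [intersect_targets()] (two fold-change columns).
#' @return list of class `partition_report`: `condition_labels`, `n_shared`,
#'   `medians`, `up_counts`, `down_counts`, `prop_up`, `rank_sum`, `fisher`
#'   (both `test_result`s), `per_gene` (gene, log2fc_a, log2fc_b, delta),
#'   `n_zero_fc` (flagged exact zeros), `degenerate` flag.
#' @export
directionality_analysis <- function(shared) {
  if (nrow(shared) < 3L) abort("need at least 3 shared targets")
  a <- shared$log2fc_a; b <- shared$log2fc_b
  labels <- attr(shared, "condition_labels")
  if (is.null(labels)) labels <- c("A", "B")
  up_a <- sum(a >= 0); up_b <- sum(b >= 0)
  n <- nrow(shared)
  degenerate <- length(unique(c(a, b))) == 1L
  rs <- if (degenerate) {
    new_test_result(NA_real_, 1, "degenerate", c(n, n))
  } else {
    wilcoxon_rank_sum(a, b)
  }
  fisher <- fisher_exact_2x2(matrix(c(up_a, n - up_a, up_b, n - up_b),
                                    2L, byrow = TRUE))
  per_gene <- tibble::tibble(gene = shared$gene, log2fc_a = a, log2fc_b = b,
                             delta = a - b)
  per_gene <- per_gene[order(-per_gene$delta), ]
  structure(list(
    condition_labels = labels, n_shared = n,
    medians = stats::setNames(c(stats::median(a), stats::median(b)), labels),
    up_counts = stats::setNames(c(up_a, up_b), labels),
    down_counts = stats::setNames(c(n - up_a, n - up_b), labels),
    prop_up = stats::setNames(c(up_a, up_b) / n, labels),
    rank_sum = rs, fisher = fisher, per_gene = per_gene,
    n_zero_fc = sum(a == 0) + sum(b == 0),
    degenerate = degenerate), class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf(
    "<partition_report> %d shared targets (%s vs %s)\n  medians: %.3g / %.3g; up: %d/%d vs %d/%d\n  rank-sum p = %.3g; Fisher p = %.3g\n",
    x$n_shared, x$condition_labels[1], x$condition_labels[2],
    x$medians[1], x$medians[2], x$up_counts[1], x$n_shared,
    x$up_counts[2], x$n_shared, x$rank_sum$p_value, x$fisher$p_value))
  invisible(x)
}
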