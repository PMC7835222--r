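## coevolution: compare region conservation between partner-positive and
## partner-negative ortholog alignments and attach uncertainty via a label
## permutation test plus a paired signed-rank test.

#' Default interface region presets (reference residue numbering)
#'
#' The C-terminal region of human ALDH1A1 that contacts PRMT3 spans residues
#' 336-501 (`"ctr"`); the two-hybrid clones covered 371-501 (`"y2h"`).
#'
#' @param preset `"ctr"` or `"y2h"`.
#' @return integer vector `c(start, end)`.
#' @export
interface_region <- function(preset = c("ctr", "y2h")) {
  switch(match.arg(preset), ctr = c(336L, 501L), y2h = c(371L, 501L))
}

#' Paired region scores from two conservation profiles
#'
#' @param profile_pos,profile_neg [conservation_profile()]s sharing the same
#'   reference protein.
#' @param region inclusive 1-based reference-residue interval
#'   `c(start, end)`.
#' @return tibble with one row per region residue mapped in both profiles:
#'   `ref_pos`, `score_pos`, `score_neg` (windowed scores), `delta` =
#'   `score_pos - score_neg`. The number of region residues dropped because
#'   they are gapped out of either alignment is attached as attribute
#'   `n_unmapped`.
#' @export
region_scores <- function(profile_pos, profile_neg, region) {
  if (!identical(attr(profile_pos, "reference_id"),
                 attr(profile_neg, "reference_id"))) {
    abort("profiles must share the same reference protein")
  }
  wanted <- seq.int(region[1], region[2])
  sp <- profile_pos$windowed[match(wanted, profile_pos$ref_pos)]
  sn <- profile_neg$windowed[match(wanted, profile_neg$ref_pos)]
  both <- !is.na(sp) & !is.na(sn)
  if (!any(both)) {
    abort("no comparable residues: region unmapped in one or both profiles")
  }
  out <- tibble::tibble(ref_pos = wanted[both],
                        score_pos = sp[both], score_neg = sn[both],
                        delta = sp[both] - sn[both])
  attr(out, "n_unmapped") <- sum(!both)
  out
}

#' Mean conservation difference over a region
#'
#' Positive values mean the region is more conserved in the partner-positive
#' set -- the signature expected if the region coevolved with the partner.
#'
#' @param paired output of [region_scores()].
#' @return arithmetic mean of the per-residue deltas.
#' @export
delta_statistic <- function(paired) mean(paired$delta)

## mean windowed score over `cols` for the alignment formed by ref_row +
## pooled[rows, ]; the reference stays in every (re)built alignment so the
## coordinate frame is fixed.
set_region_mean <- function(ref_row, pooled, rows, cols, params, background) {
  mat <- rbind(ref_row, pooled[rows, , drop = FALSE])
  weights <- if (params$use_sequence_weighting) {
    weights_engine(mat)
  } else {
    rep(1 / nrow(mat), nrow(mat))
  }
  ## raw scores are needed only on the region plus its smoothing margin;
  ## window truncation inside the margin matches the full-profile result
  ## because every region column keeps its complete neighborhood
  lo <- max(1L, min(cols) - params$window_radius)
  hi <- min(ncol(mat), max(cols) + params$window_radius)
  sc <- raw_scores_engine(mat, weights, background, params$pseudocount,
                          cols = lo:hi)
  windowed <- window_smooth(sc$raw, params$window_radius, params$window_weight)
  mean(windowed[cols - lo + 1L])
}

#' Permutation test for partner-conditioned region conservation
#'
#' Pools the organisms of the two sets, reassigns set labels at random
#' (preserving set sizes), recomputes both conservation profiles and the
#' region delta for every reassignment, and reports the two-sided add-one
#' permutation p-value (1 + #\{|delta*| >= |delta_obs|\}) / (N + 1). The
#' reference sequence stays in both alignments and never swaps.
#'
#' @param aln_pos,aln_neg `msa`s over identical columns, both containing the
#'   (identical) reference row.
#' @param reference_id reference sequence id.
#' @param region inclusive reference-residue interval.
#' @param params a [cons_params()].
#' @param n_perm number of permutations (>= 19; default 999).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param background background distribution.
#' @return list: `delta_obs`, `p_value`, `n_perm`, `seed`, `perm_deltas`.
#' @export
permutation_test <- function(aln_pos, aln_neg, reference_id, region,
                             params = cons_params(), n_perm = 999L,
                             seed, background = blosum62_background()) {
  n_perm <- check_count(n_perm, "n_perm", 1L)
  if (n_perm < 19L) abort("n_perm < 19: permutation p-value floor too coarse")
  if (aln_pos$n_col != aln_neg$n_col) {
    abort("alignments must share a common column space")
  }
  ri_pos <- match(reference_id, aln_pos$ids)
  ri_neg <- match(reference_id, aln_neg$ids)
  if (is.na(ri_pos) || is.na(ri_neg)) {
    abort(sprintf("reference id '%s' must be present in both alignments",
                  reference_id))
  }
  ref_row <- aln_pos$mat[ri_pos, ]
  if (!identical(unname(ref_row), unname(aln_neg$mat[ri_neg, ]))) {
    abort("reference rows differ between the two alignments")
  }
  ref_pos_map <- rep(NA_integer_, length(ref_row))
  ref_pos_map[ref_row > 0L] <- seq_len(sum(ref_row > 0L))
  cols <- which(ref_pos_map %in% seq.int(region[1], region[2]))
  if (length(cols) == 0L) abort("region unmapped in the shared reference")

  pooled <- rbind(aln_pos$mat[-ri_pos, , drop = FALSE],
                  aln_neg$mat[-ri_neg, , drop = FALSE])
  n_pos <- aln_pos$n_seq - 1L
  n_all <- nrow(pooled)
  if (n_pos < 2L || n_all - n_pos < 2L) {
    abort("each set needs at least 2 organism sequences")
  }

  delta_for <- function(rows_pos) {
    set_region_mean(ref_row, pooled, rows_pos, cols, params, background) -
      set_region_mean(ref_row, pooled, setdiff(seq_len(n_all), rows_pos),
                      cols, params, background)
  }
  delta_obs <- delta_for(seq_len(n_pos))
  ## canonicalize the pooled row order (by sequence content) before drawing
  ## permutations, so exchanging the two input sets leaves the permutation
  ## null -- and hence the p-value -- exactly unchanged
  canon <- order(apply(pooled, 1L, paste, collapse = ""))
  pooled <- pooled[canon, , drop = FALSE]
  k_draw <- min(n_pos, n_all - n_pos)  # |delta| is swap-symmetric
  perm_deltas <- with_local_seed(seed, {
    vapply(seq_len(n_perm),
           function(k) delta_for(sample.int(n_all, k_draw)),
           numeric(1))
  })
  p <- (1 + sum(abs(perm_deltas) >= abs(delta_obs))) / (n_perm + 1)
  list(delta_obs = delta_obs, p_value = p, n_perm = n_perm,
       seed = as.integer(seed), perm_deltas = perm_deltas)
}

#' Wilcoxon signed-rank test on paired region deltas
#'
#' Two-sided test of symmetry of the per-residue score deltas around zero;
#' zero deltas are dropped. The exact null distribution is used for n <= 25
#' when the absolute deltas are tie-free, otherwise a normal approximation
#' with continuity correction and tie-corrected variance.
#'
#' @param paired output of [region_scores()] (or any data frame with a
#'   `delta` column).
#' @param exact_max largest n for the exact branch (default 25).
#' @return list of class `test_result`: `statistic` (W+, sum of positive
#'   ranks), `p_value`, `method` (`"exact"`/`"approximate"`/`"degenerate"`),
#'   `n` (non-zero deltas).
#' @export
signed_rank_test <- function(paired, exact_max = 25L) {
  d <- paired$delta
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_test_result(0, 1, "degenerate", 0))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    p <- 2 * min(stats::psignrank(w_plus, n),
                 stats::psignrank(w_plus - 1, n, lower.tail = FALSE))
    return(new_test_result(w_plus, min(p, 1), "exact", n))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(new_test_result(w_plus, 1, "degenerate", n))
  z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
  new_test_result(w_plus, min(2 * stats::pnorm(-abs(z)), 1), "approximate", n)
}

#' Full region comparison between two ortholog alignments
#'
#' Convenience wrapper producing the paired per-residue table, the mean
#' delta, the label-permutation p-value and the paired signed-rank p-value
#' in one object. Both tests are always reported; neither is privileged.
#'
#' @inheritParams permutation_test
#' @return list of class `region_comparison`: `region`, `paired`,
#'   `delta_mean`, `permutation_p`, `signed_rank_p`, `n_perm`, `seed`.
#' @export
compare_region <- function(aln_pos, aln_neg, reference_id,
                           region = interface_region("ctr"),
                           params = cons_params(), n_perm = 999L, seed,
                           background = blosum62_background()) {
  prof_pos <- conservation_profile(aln_pos, reference_id, params, background)
  prof_neg <- conservation_profile(aln_neg, reference_id, params, background)
  paired <- region_scores(prof_pos, prof_neg, region)
  perm <- permutation_test(aln_pos, aln_neg, reference_id, region,
                           params, n_perm, seed, background)
  structure(list(region = as.integer(region), paired = paired,
                 delta_mean = delta_statistic(paired),
                 permutation_p = perm$p_value,
                 signed_rank_p = signed_rank_test(paired)$p_value,
                 n_perm = perm$n_perm, seed = as.integer(seed),
                 profile_pos = prof_pos, profile_neg = prof_neg),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf(
    "<region_comparison> residues %d-%d (%d compared)\n  delta_mean = %.4f, permutation p = %.4g (N = %d), signed-rank p = %.4g\n",
    x$region[1], x$region[2], nrow(x$paired), x$delta_mean,
    x$permutation_p, x$n_perm, x$signed_rank_p))
  invisible(x)
}
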