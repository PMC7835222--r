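## conservation: per-column Jensen-Shannon-divergence residue conservation
## against the BLOSUM62 background, with position-based sequence weighting,
## linear gap penalty, window smoothing and reference-coordinate mapping.
## The columnwise engine is vectorized over the whole alignment because the
## coevolution permutation test recomputes profiles hundreds of times.

#' Conservation-scoring parameters
#'
#' @param window_radius columns on each side contributing to the smoothed
#'   score (default 3, the scoring method's standard setting).
#' @param window_weight mixing weight of the neighborhood mean in the
#'   smoothed score, in \[0, 1\] (default 0.5).
#' @param pseudocount added to each weighted residue count (default 1e-7).
#' @param use_sequence_weighting apply position-based sequence weights that
#'   down-weight redundant sequences (default TRUE).
#' @return list of class `cons_params`.
#' @export
cons_params <- function(window_radius = 3L, window_weight = 0.5,
                        pseudocount = 1e-7, use_sequence_weighting = TRUE) {
  window_radius <- check_count(window_radius, "window_radius")
  check_number(window_weight, "window_weight", 0, 1)
  check_number(pseudocount, "pseudocount", min = 1e-300)
  check_flag(use_sequence_weighting, "use_sequence_weighting")
  structure(list(window_radius = window_radius,
                 window_weight = window_weight,
                 pseudocount = pseudocount,
                 use_sequence_weighting = use_sequence_weighting,
                 gap_penalty_mode = "linear"),
            class = "cons_params")
}

#' Position-based sequence weights
#'
#' Henikoff-style weighting that rewards "surprising" sequences: in a column
#' with r distinct symbols (gap counts as a symbol) where sequence i's symbol
#' occurs s times, sequence i earns 1 / (r * s); weights are the per-sequence
#' means over columns, normalized to sum to 1. Over-sampled clades (e.g.
#' strain duplicates) are thereby down-weighted.
#'
#' @param aln an `msa`.
#' @return numeric weight vector (sums to 1), named by sequence id.
#' @export
sequence_weights <- function(aln) {
  w <- weights_engine(aln$mat)
  stats::setNames(w, aln$ids)
}

weights_engine <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  ## symbol counts per column, gap (0) included as a symbol
  C <- vapply(0:20, function(s) colSums(mat == s), numeric(L))  # L x 21
  if (L == 1L) C <- matrix(C, nrow = 1L)
  r <- rowSums(C > 0L)
  ## s[i, c] = multiplicity of sequence i's symbol in column c
  S <- matrix(C[cbind(rep(seq_len(L), each = n), as.vector(mat) + 1L)], n, L)
  raw <- rowMeans(sweep(1 / S, 2L, r, "/"))
  raw / sum(raw)
}

#' Weighted residue distribution of one alignment column
#'
#' @param aln an `msa`.
#' @param column 1-based column index.
#' @param weights sequence weights (default uniform).
#' @param pseudocount pseudocount added per residue.
#' @return list with `p` (named distribution over the 20 amino acids,
#'   sums to 1) and `gap_fraction` (weight-weighted). An all-gap column
#'   returns the uniform placeholder with `gap_fraction` 1 (it scores 0
#'   downstream).
#' @export
column_distribution <- function(aln, column, weights = NULL,
                                pseudocount = 1e-7) {
  if (column < 1L || column > aln$n_col) abort("column out of range")
  if (is.null(weights)) weights <- rep(1 / aln$n_seq, aln$n_seq)
  v <- aln$mat[, column]
  counts <- vapply(1:20, function(a) sum(weights[v == a]), numeric(1))
  nongap <- sum(weights[v > 0L])
  p <- (counts + pseudocount) / (nongap + 20 * pseudocount)
  list(p = stats::setNames(p, AA20), gap_fraction = sum(weights[v == 0L]))
}

#' Jensen-Shannon divergence between two distributions (base 2)
#'
#' JSD(p, q) = KL(p || r)/2 + KL(q || r)/2 with r = (p + q)/2 and base-2
#' logarithms, so the score is symmetric and bounded in \[0, 1\]; 0 iff
#' p = q, 1 for distributions with disjoint support.
#'
#' @param p,q non-negative numeric vectors over the same support, each
#'   summing to 1 (within 1e-6).
#' @return divergence in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) abort("p and q must share a support")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("p and q must each sum to 1")
  }
  r <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / r[nz]))
  }
  min(max((kl(p) + kl(q)) / 2, 0), 1)
}

#' Raw conservation score of one column
#'
#' JSD between the column's weighted residue distribution and the background,
#' linearly penalized by the gapped weight fraction:
#' S = JSD(p, background) * (1 - gap_fraction). An all-gap column scores 0.
#'
#' @inheritParams column_distribution
#' @param background background distribution (default
#'   [blosum62_background()]).
#' @return score in \[0, 1\].
#' @export
column_score <- function(aln, column, weights = NULL,
                         background = blosum62_background(),
                         pseudocount = 1e-7) {
  cd <- column_distribution(aln, column, weights, pseudocount)
  jsd(cd$p, background) * (1 - cd$gap_fraction)
}

## Vectorized raw scores for all columns of an integer alignment matrix
## (optionally restricted to a column subset).
raw_scores_engine <- function(mat, weights, background, pseudocount,
                              cols = NULL) {
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  L <- ncol(mat)
  WC <- matrix(0, 20L, L)
  for (a in 1:20) WC[a, ] <- colSums((mat == a) * weights)
  nongap <- colSums((mat > 0L) * weights)
  gapf <- colSums((mat == 0L) * weights)
  P <- sweep(WC + pseudocount, 2L, nongap + 20 * pseudocount, "/")
  R <- (P + background) / 2
  jsd_cols <- 0.5 * colSums(P * log2(P / R)) +
    0.5 * colSums(background * log2(background / R))
  raw <- pmin(pmax(jsd_cols, 0), 1) * (1 - gapf)
  list(raw = raw, gap_fraction = gapf)
}

## Window smoothing: S' = (1 - lambda) * S + lambda * mean(S over the window
## excluding the center), truncated at the alignment edges; a column with no
## valid neighbors keeps its raw score.
window_smooth <- function(raw, radius, lambda) {
  L <- length(raw)
  if (radius == 0L || lambda == 0 || L == 1L) return(raw)
  cs <- c(0, cumsum(raw))
  idx <- seq_len(L)
  lo <- pmax(1L, idx - radius); hi <- pmin(L, idx + radius)
  cnt <- hi - lo + 1L
  nb_mean <- (cs[hi + 1L] - cs[lo] - raw) / pmax(cnt - 1L, 1L)
  out <- (1 - lambda) * raw + lambda * nb_mean
  out[cnt == 1L] <- raw[cnt == 1L]
  out
}

#' Per-column conservation profile of an alignment
#'
#' Computes raw and window-smoothed JSD conservation scores for every
#' alignment column and maps columns onto the residue numbering of a
#' reference sequence in the alignment (1-based over its ungapped length).
#'
#' @param aln an `msa` containing `reference_id`.
#' @param reference_id id of the reference sequence.
#' @param params a [cons_params()].
#' @param background background distribution.
#' @return tibble of class `conservation_profile` with columns `column`,
#'   `ref_pos` (NA where the reference is gapped), `gap_fraction`, `raw`,
#'   `windowed`; attributes `params`, `reference_id`, `weights`.
#' @export
conservation_profile <- function(aln, reference_id, params = cons_params(),
                                 background = blosum62_background()) {
  if (!(reference_id %in% aln$ids)) {
    abort(sprintf("reference id '%s' not in alignment", reference_id))
  }
  weights <- if (params$use_sequence_weighting) {
    weights_engine(aln$mat)
  } else {
    rep(1 / aln$n_seq, aln$n_seq)
  }
  sc <- raw_scores_engine(aln$mat, weights, background, params$pseudocount)
  windowed <- window_smooth(sc$raw, params$window_radius,
                            params$window_weight)
  ref_codes <- aln$mat[match(reference_id, aln$ids), ]
  ref_pos <- rep(NA_integer_, aln$n_col)
  ref_pos[ref_codes > 0L] <- seq_len(sum(ref_codes > 0L))
  out <- tibble::tibble(column = seq_len(aln$n_col), ref_pos = ref_pos,
                        gap_fraction = sc$gap_fraction,
                        raw = sc$raw, windowed = windowed)
  attr(out, "params") <- params
  attr(out, "reference_id") <- reference_id
  attr(out, "weights") <- stats::setNames(weights, aln$ids)
  class(out) <- c("conservation_profile", class(out))
  out
}
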