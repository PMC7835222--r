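# Independent oracles used to cross-check the package implementations.
# Deliberately naive (loops, full enumeration) and kept free of any code
# path they are used to verify.

# Jensen-Shannon divergence by direct formula evaluation, element loop.
naive_jsd <- function(p, q) {
  r <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * log2(p[i] / r[i])
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * log2(q[i] / r[i])
  }
  unname(acc)
}

# Optimal affine-gap global alignment score by exhaustive enumeration of all
# move sequences (diagonal / up / left), scoring gaps as open + extend per
# gapped position with a fresh opening charge whenever the gap state changes.
enum_align_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > na && j > nb) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= na && j <= nb) {
      rec(i + 1L, j + 1L, score + mat[ca[i], cb[j]], "M")
    }
    if (i <= na) {
      rec(i + 1L, j, score - gap_extend - if (identical(last, "X")) 0 else gap_open, "X")
    }
    if (j <= nb) {
      rec(i, j + 1L, score - gap_extend - if (identical(last, "Y")) 0 else gap_open, "Y")
    }
  }
  rec(1L, 1L, 0, "")
  best
}

# Two-sided Fisher p by explicit enumeration of every table with the
# observed margins, using dhyper for the cell probabilities.
enum_fisher_p <- function(tb) {
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- sum(tb)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Exact two-sided rank-sum p by full enumeration of all labelings of the
# pooled (tie-free) sample; same 2*min(two tails) convention as the package.
enum_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  labelings <- utils::combn(nx + ny, nx)
  u_all <- apply(labelings, 2L, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(2 * min(p_lo, p_hi), 1)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments.
enum_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)), 1)
}

# Straightforward per-column reimplementation of the conservation profile
# (explicit loops; position-based weights, pseudocount, linear gap penalty,
# window smoothing) for oracle comparison on random alignments.
naive_profile <- function(aln, params = cons_params(),
                          background = blosum62_background()) {
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)
  if (params$use_sequence_weighting) {
    raw_w <- numeric(n)
    for (i in seq_len(n)) {
      contrib <- numeric(L)
      for (cix in seq_len(L)) {
        col <- mat[, cix]
        rr <- length(unique(col))
        ss <- sum(col == col[i])
        contrib[cix] <- 1 / (rr * ss)
      }
      raw_w[i] <- mean(contrib)
    }
    w <- raw_w / sum(raw_w)
  } else {
    w <- rep(1 / n, n)
  }
  eps <- params$pseudocount
  raw <- numeric(L)
  for (cix in seq_len(L)) {
    col <- mat[, cix]
    counts <- numeric(20)
    for (a in 1:20) counts[a] <- sum(w[col == a])
    nongap <- sum(w[col > 0])
    p <- (counts + eps) / (nongap + 20 * eps)
    gapf <- sum(w[col == 0])
    raw[cix] <- naive_jsd(p, background) * (1 - gapf)
  }
  windowed <- numeric(L)
  wr <- params$window_radius; lam <- params$window_weight
  for (cix in seq_len(L)) {
    nb <- setdiff(max(1, cix - wr):min(L, cix + wr), cix)
    windowed[cix] <- if (length(nb) == 0) {
      raw[cix]
    } else {
      (1 - lam) * raw[cix] + lam * mean(raw[nb])
    }
  }
  list(raw = raw, windowed = windowed, weights = w)
}

# Random protein sequence over the standard alphabet.
random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# Random gapped alignment as an msa.
random_msa <- function(n_seq, n_col, gap_prob = 0.1) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  seqs <- replicate(n_seq, {
    chars <- sample(aa, n_col, replace = TRUE)
    chars[runif(n_col) < gap_prob] <- "-"
    paste(chars, collapse = "")
  })
  # guarantee at least one gap-free sequence so no column is all-gap-prone
  seqs[1] <- paste(sample(aa, n_col, replace = TRUE), collapse = "")
  new_msa(sprintf("s%02d", seq_len(n_seq)), seqs)
}

# Alignments (reference + organisms) for the two sets of a simulated family.
family_alignments <- function(fam) {
  list(
    pos = new_msa(c(fam$reference$id, fam$partner_pos$id),
                  c(fam$reference$sequence, fam$partner_pos$sequence)),
    neg = new_msa(c(fam$reference$id, fam$partner_neg$id),
                  c(fam$reference$sequence, fam$partner_neg$sequence))
  )
}
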