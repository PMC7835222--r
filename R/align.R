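## Affine-gap global protein alignment (Gotoh three-state dynamic program),
## re-implemented here so ortholog curation is self-contained and exactly
## testable against exhaustive enumeration. A gap of length k costs
## gap_open + gap_extend * k (the Biostrings convention, so
## pairwiseAlignment with the same parameters is a drop-in cross-check).

#' Optimal global alignment of two protein sequences with affine gaps
#'
#' Computes the optimal global alignment score under an affine gap model
#' (three-state Gotoh recurrence) and one optimal alignment by deterministic
#' traceback. Ties are broken by preferring a match/mismatch step over a gap
#' in the second sequence over a gap in the first, so the returned alignment
#' is reproducible.
#'
#' @param a,b protein sequences (gap-free, standard 20-letter alphabet).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open gap opening penalty (positive; default 11).
#' @param gap_extend gap extension penalty per gapped position (default 1).
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and `identity` (identical
#'   columns over all alignment columns, gap columns counting against
#'   identity).
#' @export
#' @examples
#' global_align("ACDE", "ACDE")$identity  # 1
global_align <- function(a, b, matrix = blosum62_matrix(),
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  ca <- encode_seq(toupper(a)); cb <- encode_seq(toupper(b))
  if (anyNA(ca) || any(ca == 0L)) abort("invalid residue in first sequence")
  if (anyNA(cb) || any(cb == 0L)) abort("invalid residue in second sequence")
  n <- length(ca); m <- length(cb)
  go <- gap_open; ge <- gap_extend
  NEG <- -1e18

  ## state matrices, rows 0..n (index +1), cols 0..m
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (m > 0) Y[1, 2:(m + 1L)] <- -go - ge * (1:m)
  if (n > 0) X[2:(n + 1L), 1] <- -go - ge * (1:n)

  jj <- 2:(m + 1L)
  for (i in 2:(n + 1L)) {
    sub <- matrix[ca[i - 1L], cb]
    prev_best <- pmax(M[i - 1L, ], X[i - 1L, ], Y[i - 1L, ])
    M[i, jj] <- prev_best[jj - 1L] + sub
    X[i, jj] <- pmax(M[i - 1L, jj] - go - ge,
                     X[i - 1L, jj] - ge,
                     Y[i - 1L, jj] - go - ge)
    ## horizontal state via running maximum:
    ## Y[i,j] = -go - ge*j + max_{k<j} (max(M,X)[i,k] + ge*k)
    B <- pmax(M[i, ], X[i, ])
    run <- cummax(B[seq_len(m)] + ge * (0:(m - 1L)))
    Y[i, jj] <- run - go - ge * (1:m)
  }

  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  ## deterministic traceback, preference M (diagonal) > X (up) > Y (left)
  tol <- 1e-9
  pick <- function(vals) which(vals >= max(vals) - tol)[1]
  state <- c("M", "X", "Y")[pick(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                                   Y[n + 1L, m + 1L]))]
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i == 0L) state <- "Y" else if (j == 0L) state <- "X"
    if (state == "M") {
      out_a <- c(AA20[ca[i]], out_a); out_b <- c(AA20[cb[j]], out_b)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[pick(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      out_a <- c(AA20[ca[i]], out_a); out_b <- c("-", out_b)
      cand <- c(M[i, j + 1L] - go - ge, X[i, j + 1L] - ge,
                Y[i, j + 1L] - go - ge)
      target <- X[i + 1L, j + 1L]
      state <- c("M", "X", "Y")[which(abs(cand - target) <= tol)[1]]
      i <- i - 1L
    } else {
      out_a <- c("-", out_a); out_b <- c(AA20[cb[j]], out_b)
      cand <- c(M[i + 1L, j] - go - ge, X[i + 1L, j] - go - ge,
                Y[i + 1L, j] - ge)
      target <- Y[i + 1L, j + 1L]
      state <- c("M", "X", "Y")[which(abs(cand - target) <= tol)[1]]
      j <- j - 1L
    }
  }

  aln <- structure(list(aligned_a = paste(out_a, collapse = ""),
                        aligned_b = paste(out_b, collapse = ""),
                        score = score),
                   class = "pairwise_alignment")
  aln$identity <- percent_identity(aln)
  aln
}

#' Fraction of identical columns in a pairwise alignment
#'
#' Identity = number of columns where both sequences carry the same residue,
#' divided by the total number of alignment columns (gap columns count
#' against identity; conventions vary, this one is stated).
#'
#' @param aln a `pairwise_alignment`.
#' @return fraction in \[0, 1\].
#' @export
percent_identity <- function(aln) {
  xa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  xb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  if (length(xa) != length(xb)) abort("aligned strings differ in length")
  mean(xa == xb & xa != "-")
}

## identity of every record's sequence to a single target sequence
identities_to <- function(records, target_seq, matrix, gap_open, gap_extend) {
  vapply(records$sequence, function(s) {
    global_align(s, target_seq, matrix, gap_open, gap_extend)$identity
  }, numeric(1), USE.NAMES = FALSE)
}
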