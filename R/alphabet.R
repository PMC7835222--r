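#' @keywords internal
"_PACKAGE"

## Amino-acid alphabet in BLOSUM62 matrix order. All internal integer codings
## use this order; gap ('-') is coded 0.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Background amino-acid frequencies underlying the BLOSUM62 substitution
## matrix (the marginal probabilities of the target pair distribution), the
## standard "no evolutionary pressure" reference for divergence-based
## conservation scoring. Order matches AA20.
BLOSUM62_BACKGROUND_RAW <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
  Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
  L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
  S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072
)

#' Background amino-acid distribution derived from BLOSUM62
#'
#' Returns the 20 published marginal amino-acid frequencies of the BLOSUM62
#' substitution matrix, renormalized to sum exactly to 1. This is the
#' reference distribution against which column conservation is scored: a
#' column whose residue distribution matches it carries no evidence of
#' evolutionary constraint.
#'
#' @return Named numeric vector of length 20 (names are one-letter amino-acid
#'   codes in BLOSUM62 matrix order), strictly positive, summing to 1.
#' @export
#' @examples
#' bg <- blosum62_background()
#' sum(bg)              # 1
#' names(which.max(bg)) # "L" -- leucine is the most frequent residue
blosum62_background <- function() {
  BLOSUM62_BACKGROUND_RAW / sum(BLOSUM62_BACKGROUND_RAW)
}

#' BLOSUM62 substitution scores for the 20 standard amino acids
#'
#' @return 20 x 20 integer matrix of log-odds scores, rows/columns in
#'   BLOSUM62 matrix order.
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "integer"
  m
}

## Encode an amino-acid string (possibly gapped) as integer codes 1..20,
## gap = 0. Unknown letters become NA.
encode_seq <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- match(chars, AA20)
  codes[chars == "-"] <- 0L
  codes
}

decode_seq <- function(codes) {
  out <- character(length(codes))
  out[codes == 0L] <- "-"
  out[codes > 0L] <- AA20[codes[codes > 0L]]
  paste(out, collapse = "")
}
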