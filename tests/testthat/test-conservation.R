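test_that("the background distribution has the published shape", {
  bg <- blosum62_background()
  expect_equal(sum(bg), 1, tolerance = 1e-9)
  expect_true(all(bg > 0 & bg < 0.12))
  expect_equal(names(which.max(bg)), "L")
})

test_that("position-based weights reward rare sequences", {
  # n identical sequences share weight equally
  aln <- new_msa(sprintf("s%d", 1:4), rep("ACDE", 4))
  expect_equal(unname(sequence_weights(aln)), rep(0.25, 4))
  # single column A, A, C: 1/(r*s) gives (1/4, 1/4, 1/2)
  aln2 <- new_msa(c("a", "b", "c"), c("A", "A", "C"))
  expect_equal(unname(sequence_weights(aln2)), c(0.25, 0.25, 0.5))
  # normalization holds on random alignments
  set.seed(41)
  for (k in 1:5) {
    expect_equal(sum(sequence_weights(random_msa(6, 30))), 1,
                 tolerance = 1e-12)
  }
})

test_that("column distributions respect weights, gaps and pseudocounts", {
  aln <- new_msa(c("a", "b", "c", "d"), c("A", "A", "A", "A"))
  cd <- column_distribution(aln, 1)
  expect_gt(cd$p[["A"]], 1 - 1e-5)
  expect_equal(sum(cd$p), 1, tolerance = 1e-9)
  expect_equal(cd$gap_fraction, 0)

  aln2 <- new_msa(c("a", "b"), c("A", "-"))
  cd2 <- column_distribution(aln2, 1)
  expect_equal(cd2$gap_fraction, 0.5)
  expect_gt(cd2$p[["A"]], 1 - 1e-5)

  # weighted distribution equals direct recomputation on fuzz columns
  set.seed(42)
  for (k in 1:10) {
    aln3 <- random_msa(8, 12)
    w <- unname(sequence_weights(aln3))
    cix <- sample(12, 1)
    cd3 <- column_distribution(aln3, cix, w)
    col <- aln3$mat[, cix]
    counts <- vapply(1:20, function(a) sum(w[col == a]), numeric(1))
    p_ref <- (counts + 1e-7) / (sum(w[col > 0]) + 20e-7)
    expect_equal(unname(cd3$p), p_ref, tolerance = 1e-12)
    expect_equal(cd3$gap_fraction, sum(w[col == 0]), tolerance = 1e-12)
  }
})

test_that("JSD closed forms and oracle agreement hold", {
  u <- rep(1 / 20, 20)
  one_hot <- function(i) { p <- rep(0, 20); p[i] <- 1; p }
  expect_equal(jsd(u, u), 0)
  expect_equal(jsd(one_hot(1), one_hot(3)), 1)
  expect_equal(jsd(one_hot(1), u), naive_jsd(one_hot(1), u),
               tolerance = 1e-12)
  expect_equal(jsd(one_hot(1), u), 0.85500, tolerance = 1e-4)
  expect_equal(jsd(u, one_hot(5)), jsd(one_hot(5), u))  # symmetry
  expect_error(jsd(u * 2, u), "sum to 1")
})

test_that("column scores behave at the conservation extremes", {
  # all-gap column scores 0
  aln <- new_msa(c("a", "b"), c("A-C", "A-C"))
  expect_equal(column_score(aln, 2), 0)
  # fully conserved gap-free columns score at the one-hot divergence of
  # their residue (high for rare residues, lowest ~0.77 for leucine)
  bg <- blosum62_background()
  for (i in seq_along(bg)) {
    res <- names(bg)[i]
    aln_res <- new_msa(c("a", "b", "c"), rep(res, 3))
    one_hot <- replace(rep(0, 20), i, 1)
    expect_equal(column_score(aln_res, 1), naive_jsd(one_hot, bg),
                 tolerance = 1e-4)
    expect_gt(column_score(aln_res, 1), 0.75)
  }
  expect_gt(column_score(new_msa(c("a", "b"), c("C", "C")), 1), 0.8)
  # columns drawn from the background score low at large n
  set.seed(43)
  bg <- blosum62_background()
  for (k in 1:20) {
    codes <- sample.int(20, 200, replace = TRUE, prob = bg)
    aln_bg <- suppressWarnings(
      new_msa(sprintf("s%03d", 1:200),
              vapply(codes, function(cc) {
                c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")[cc]
              }, character(1))))
    expect_lt(column_score(aln_bg, 1), 0.05)
  }
})

test_that("profiles match a straightforward reimplementation exactly", {
  set.seed(44)
  for (k in 1:5) {
    aln <- random_msa(7, 25)
    prof <- conservation_profile(aln, aln$ids[1])
    oracle <- naive_profile(aln)
    expect_equal(prof$raw, oracle$raw, tolerance = 1e-12)
    expect_equal(prof$windowed, oracle$windowed, tolerance = 1e-12)
    expect_equal(unname(attr(prof, "weights")), oracle$weights,
                 tolerance = 1e-12)
  }
})

test_that("window smoothing degenerates correctly", {
  # single column: no neighbors, windowed equals raw
  aln1 <- new_msa(c("a", "b", "c"), c("A", "A", "C"))
  p1 <- conservation_profile(aln1, "a")
  expect_equal(p1$windowed, p1$raw)
  # identical columns: all raw scores equal, smoothing is a no-op
  aln2 <- new_msa(c("a", "b", "c"), c("AAAAAA", "AAAAAA", "CCCCCC"))
  p2 <- conservation_profile(aln2, "a")
  expect_true(all(abs(p2$windowed - p2$raw) < 1e-12))
})

test_that("reference mapping covers exactly the ungapped reference positions", {
  aln <- new_msa(c("ref", "x", "y"), c("AC-DE", "ACWDE", "ACW-E"))
  prof <- conservation_profile(aln, "ref")
  expect_equal(prof$ref_pos, c(1L, 2L, NA, 3L, 4L))
  mapped <- prof$ref_pos[!is.na(prof$ref_pos)]
  expect_true(all(diff(mapped) > 0))
  expect_error(conservation_profile(aln, "zz"), "not in alignment")
})

test_that("scores are invariant to sequence order", {
  set.seed(45)
  aln <- random_msa(9, 20)
  prof <- conservation_profile(aln, aln$ids[1])
  perm <- sample(aln$n_seq)
  aln_shuf <- new_msa(aln$ids[perm], aln$seqs[perm])
  prof_shuf <- conservation_profile(aln_shuf, aln$ids[1])
  expect_lt(max(abs(prof$windowed - prof_shuf$windowed)), 1e-12)
})

test_that("sequence weighting absorbs redundant duplicates", {
  set.seed(46)
  # fully diverged columns (background-level substitution everywhere), so
  # stacking duplicates visibly distorts unweighted frequencies
  fam <- simulate_ortholog_families(
    msa_sim_config(reference_length = 120L, n_partner_pos = 8L,
                   n_partner_neg = 0L, region = c(41L, 70L),
                   p_sub_region_pos = 0.3, p_sub_background = 0.3,
                   n_strain_duplicates = 0L, seed = 19L))
  aln <- new_msa(c(fam$reference$id, fam$partner_pos$id),
                 c(fam$reference$sequence, fam$partner_pos$sequence))
  region_mean <- function(a, weighted) {
    p <- conservation_profile(
      a, "REF_QUERY", cons_params(use_sequence_weighting = weighted))
    mean(p$windowed)
  }
  base_w <- region_mean(aln, TRUE)
  base_u <- region_mean(aln, FALSE)
  # without duplicates the two schemes agree closely
  expect_lt(abs(base_w - base_u), 0.05)

  # stack 10 copies of one diverged sequence onto the alignment
  dup_seq <- fam$partner_pos$sequence[1]
  aln_dup <- new_msa(c(aln$ids, sprintf("dup%02d", 1:10)),
                     c(aln$seqs, rep(dup_seq, 10)))
  expect_lt(abs(region_mean(aln_dup, TRUE) - base_w), 0.02)
  expect_gt(abs(region_mean(aln_dup, FALSE) - base_u), 0.02)
})
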