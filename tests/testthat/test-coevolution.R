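small_family <- function(seed, p_region_pos = 0.02, n = 10L) {
  fam <- simulate_ortholog_families(
    msa_sim_config(reference_length = 100L, n_partner_pos = n,
                   n_partner_neg = n, region = c(41L, 60L),
                   p_sub_region_pos = p_region_pos,
                   n_strain_duplicates = 0L, seed = seed))
  family_alignments(fam)
}

test_that("region pairing keeps residues mapped in both profiles", {
  aln_pos <- new_msa(c("ref", "a", "b"), c("ACDEF", "ACDEF", "ACWEF"))
  aln_neg <- new_msa(c("ref", "c", "d"), c("ACDEF", "AC-EF", "ACW-F"))
  pp <- conservation_profile(aln_pos, "ref")
  pn <- conservation_profile(aln_neg, "ref")
  paired <- region_scores(pp, pn, c(1, 5))
  expect_equal(nrow(paired), 5L)
  expect_equal(attr(paired, "n_unmapped"), 0L)

  # identical profiles give all-zero deltas
  paired_same <- region_scores(pp, pp, c(2, 4))
  expect_true(all(paired_same$delta == 0))

  # a residue gapped out of one reference mapping is excluded
  aln_neg2 <- new_msa(c("ref", "c", "d"), c("AC-EF", "ACDEF", "ACWEF"))
  pn2 <- conservation_profile(aln_neg2, "ref")
  paired2 <- region_scores(pp, pn2, c(1, 5))
  expect_equal(nrow(paired2), 4L)
  expect_equal(attr(paired2, "n_unmapped"), 1L)
})

test_that("the delta statistic averages and is antisymmetric under profile swap", {
  expect_equal(delta_statistic(data.frame(delta = c(0.1, 0.3))), 0.2)
  alns <- small_family(seed = 23L)
  pp <- conservation_profile(alns$pos, "REF_QUERY")
  pn <- conservation_profile(alns$neg, "REF_QUERY")
  d_fwd <- delta_statistic(region_scores(pp, pn, c(41, 60)))
  d_rev <- delta_statistic(region_scores(pn, pp, c(41, 60)))
  expect_equal(d_fwd, -d_rev)
  expect_gt(d_fwd, 0)  # planted signal points the right way
})

test_that("permutation p-value respects its floor and degenerate null", {
  alns <- small_family(seed = 29L)
  # two identical copies of one set: observed delta is exactly 0, p = 1
  res <- permutation_test(alns$pos, alns$pos, "REF_QUERY", c(41, 60),
                          n_perm = 99L, seed = 1L)
  expect_equal(res$delta_obs, 0)
  expect_gt(res$p_value, 0.9)
  # add-one estimator bound
  strong <- permutation_test(alns$pos, alns$neg, "REF_QUERY", c(41, 60),
                             n_perm = 99L, seed = 1L)
  expect_gte(strong$p_value, 1 / 100)
  expect_error(permutation_test(alns$pos, alns$neg, "REF_QUERY", c(41, 60),
                                n_perm = 10L, seed = 1L), "floor")
})

test_that("permutation test is deterministic and swap-invariant", {
  alns <- small_family(seed = 31L)
  r1 <- permutation_test(alns$pos, alns$neg, "REF_QUERY", c(41, 60),
                         n_perm = 99L, seed = 7L)
  r2 <- permutation_test(alns$pos, alns$neg, "REF_QUERY", c(41, 60),
                         n_perm = 99L, seed = 7L)
  expect_identical(r1$perm_deltas, r2$perm_deltas)
  swapped <- permutation_test(alns$neg, alns$pos, "REF_QUERY", c(41, 60),
                              n_perm = 99L, seed = 7L)
  expect_equal(swapped$delta_obs, -r1$delta_obs)
  expect_equal(swapped$p_value, r1$p_value)
})

test_that("signed-rank test matches enumeration and handles degeneracy", {
  expect_equal(signed_rank_test(data.frame(delta = c(0, 0, 0)))$p_value, 1)
  expect_equal(signed_rank_test(data.frame(delta = c(0, 0, 0)))$method,
               "degenerate")
  expect_equal(signed_rank_test(data.frame(delta = c(1, 2, 3)))$p_value, 0.25)
  set.seed(51)
  for (k in 1:20) {
    d <- round(rnorm(sample(4:9, 1)), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    expect_equal(signed_rank_test(data.frame(delta = d))$p_value,
                 enum_signedrank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank exact and approximate branches agree near the cutover", {
  set.seed(52)
  for (k in 1:20) {
    d <- rnorm(25)
    exact <- signed_rank_test(data.frame(delta = d))
    expect_equal(exact$method, "exact")
    approx <- signed_rank_test(data.frame(delta = d), exact_max = 0L)
    expect_equal(approx$method, "approximate")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
})

test_that("region comparison detects a planted signal end to end", {
  alns <- small_family(seed = 37L)
  cmp <- compare_region(alns$pos, alns$neg, "REF_QUERY", c(41, 60),
                        n_perm = 199L, seed = 11L)
  expect_gt(cmp$delta_mean, 0)
  expect_lte(cmp$permutation_p, 0.05)
  expect_lt(cmp$signed_rank_p, 0.01)
  expect_equal(cmp$delta_mean, mean(cmp$paired$delta), tolerance = 1e-12)
})

test_that("mismatched references and empty regions are rejected", {
  alns <- small_family(seed = 41L)
  expect_error(permutation_test(alns$pos, alns$neg, "nope", c(41, 60),
                                n_perm = 99L, seed = 1L), "reference")
  aln_other <- new_msa(c("REF_QUERY", "z1", "z2"),
                       c("ACDEF", "ACDEF", "ACWEF"))
  expect_error(permutation_test(alns$pos, aln_other, "REF_QUERY", c(1, 5),
                                n_perm = 99L, seed = 1L), "column space")
})
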