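test_that("zero substitution probability reproduces the reference everywhere", {
  cfg <- msa_sim_config(reference_length = 50L, n_partner_pos = 4L,
                        n_partner_neg = 4L, region = c(11L, 20L),
                        p_sub_background = 0, p_sub_region_pos = 0,
                        p_sub_region_neg = 0, n_strain_duplicates = 1L,
                        paralog_divergence = 0, seed = 3L)
  fam <- simulate_ortholog_families(cfg)
  ref <- fam$reference$sequence
  expect_true(all(fam$partner_pos$sequence == ref))
  expect_true(all(fam$partner_neg$sequence == ref))
  expect_equal(fam$paralog$sequence, ref)
})

test_that("family generation is deterministic given config and seed", {
  cfg <- msa_sim_config(reference_length = 80L, n_partner_pos = 5L,
                        n_partner_neg = 5L, region = c(21L, 40L), seed = 42L)
  f1 <- simulate_ortholog_families(cfg)
  f2 <- simulate_ortholog_families(cfg)
  expect_identical(f1$partner_pos, f2$partner_pos)
  expect_identical(f1$partner_neg, f2$partner_neg)
  expect_identical(f1$truth, f2$truth)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_ortholog_families(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("per-site divergence matches its binomial expectation", {
  cfg <- msa_sim_config(reference_length = 200L, n_partner_pos = 30L,
                        n_partner_neg = 0L, region = c(1L, 1L),
                        p_sub_background = 0.3, p_sub_region_pos = 0.3,
                        n_strain_duplicates = 0L, seed = 7L)
  fam <- simulate_ortholog_families(cfg)
  ref <- strsplit(fam$reference$sequence, "")[[1]]
  diffs <- vapply(fam$partner_pos$sequence, function(s) {
    mean(strsplit(s, "")[[1]] != ref)
  }, numeric(1))
  n_draws <- 200 * 30
  se <- sqrt(0.3 * 0.7 / n_draws)
  expect_lt(abs(mean(diffs) - 0.3), 3 * se)
})

test_that("strain duplicates share a species key with their host organism", {
  cfg <- msa_sim_config(reference_length = 60L, n_partner_pos = 3L,
                        n_partner_neg = 3L, region = c(11L, 20L),
                        n_strain_duplicates = 4L, seed = 9L)
  fam <- simulate_ortholog_families(cfg)
  truth <- fam$truth
  dups <- truth[truth$strain_duplicate, ]
  expect_equal(nrow(dups), 4L)
  hosts <- truth[!truth$strain_duplicate, ]
  expect_true(all(dups$species_key %in% hosts$species_key))
  # duplicates land in the same partner set as their host species
  for (k in seq_len(nrow(dups))) {
    expect_equal(dups$set[k],
                 hosts$set[hosts$species_key == dups$species_key[k]][1])
  }
})

test_that("DE simulation plants the requested medians and regulators", {
  cfg <- de_sim_config(sigma = 0.01, seed = 11L)
  sim <- simulate_de_tables(cfg)
  up <- sim$targets$gene[sim$targets$direction == "up"]
  expect_equal(length(up), 33L)
  med_a <- median(sim$table_a$log2fc[sim$table_a$gene %in% up])
  med_b <- median(sim$table_b$log2fc[sim$table_b$gene %in% up])
  expect_lt(abs(med_a - 2.5), 0.05)
  expect_lt(abs(med_b - (-2.6)), 0.05)
  # regulators carry their exact planted values
  expect_equal(sim$table_a$log2fc[sim$table_a$gene == "ALDH1A1"], 3.8)
  expect_equal(sim$table_b$log2fc[sim$table_b$gene == "ALDH1A1"], 1.4)
  # determinism
  sim2 <- simulate_de_tables(cfg)
  expect_identical(sim$table_a$log2fc, sim2$table_a$log2fc)
})

test_that("DE simulation includes the small down-target class", {
  sim <- simulate_de_tables(de_sim_config(seed = 2L))
  expect_equal(sum(sim$targets$direction == "down"), 5L)
})

test_that("time-course simulation is linear without noise and flat when fully inhibited", {
  cfg <- kinetics_sim_config(v_true = 1.0, noise_sd = 0,
                             inhibition_fraction = c(control = 0, full = 1),
                             seed = 5L)
  sim <- simulate_timecourses(cfg)
  tc <- sim$timecourse
  ctrl <- tc[tc$condition == "control" & tc$replicate == "rep1", ]
  expect_equal(ctrl$reading, ctrl$time_min)
  full <- tc[tc$condition == "full", ]
  expect_true(all(full$reading == 0))
  # determinism with noise
  cfgn <- kinetics_sim_config(noise_sd = 0.2, seed = 5L)
  expect_identical(simulate_timecourses(cfgn)$timecourse$reading,
                   simulate_timecourses(cfgn)$timecourse$reading)
})

test_that("configs validate their invariants", {
  expect_error(msa_sim_config(region = c(0L, 10L)), "region")
  expect_error(msa_sim_config(p_sub_background = 1.2), "p_sub_background")
  expect_error(de_sim_config(sigma = 0), "sigma")
  expect_error(kinetics_sim_config(duration = 3, interval = 2), "duration")
  expect_error(kinetics_sim_config(inhibition_fraction = c(0.5)), "named")
})
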