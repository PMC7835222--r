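#!/usr/bin/env Rscript
# Stage 2: ortholog curation and partner-conditioned conservation.
#
# Runs the full chain on the simulated families (same seed as stage 1):
# strain deduplication -> one-to-one assignment against the paralog decoy ->
# partner presence/absence partition -> per-set JSD conservation profiles ->
# interface-region comparison with a 999-permutation label test.
# Outputs land under results/coevolution/.

suppressMessages(library(coevkit))

SEED <- 20260920L
res <- run_coevolution(list(
  sim = msa_sim_config(seed = SEED),
  n_perm = 999L,
  seed = SEED + 10L,
  out_dir = file.path("results", "coevolution")))

cat(sprintf("curation: %d/%d organisms assigned a one-to-one ortholog (paralog assigned: %s)\n",
            res$truth_recovery$n_assigned, res$truth_recovery$n_species,
            res$truth_recovery$paralog_assigned))
cat(sprintf("partition: %d partner-positive vs %d partner-negative organisms\n",
            length(res$partition$partner_positive),
            length(res$partition$partner_negative)))
print(res$comparison)
cat("Interpretation: a positive delta with a small permutation p indicates\n")
cat("the interface region is under elevated constraint specifically in\n")
cat("partner-positive organisms -- the coevolution signature.\n")
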