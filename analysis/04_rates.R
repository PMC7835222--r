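#!/usr/bin/env Rscript
# Stage 4: enzyme initial rates and inhibition.
#
# Reads the NADH time courses written by stage 1, fits per-replicate initial
# velocities (OLS over the first 6 points, i.e. 0-10 min at the 2-min
# cadence), and summarizes mean rate, percent inhibition and a two-tailed t
# test against the uninhibited control. Outputs land under results/rates/.

suppressMessages(library(coevkit))

tc <- read_timecourse(file.path("results", "data", "timecourses.csv"))
res <- run_rates(list(
  timecourse = file.path("results", "data", "timecourses.csv"),
  control = "control",
  window_points = 6L,
  out_dir = file.path("results", "rates")))

print(res$result)
trt <- res$result$summary[res$result$summary$condition == "treated", ]
cat(sprintf("treated condition: %.1f%% inhibition vs control (t-test p = %.2g)\n",
            trt$percent_inhibition, trt$t_p_value))
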