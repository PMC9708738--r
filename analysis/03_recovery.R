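#!/usr/bin/env Rscript
# Parameter-recovery experiment: simulate static-mean observers on a grid
# of generative prior weights and verify that the regression-index
# estimator recovers them without bias, and that the offset estimator
# recovers the generative response bias.
#
# Usage: Rscript analysis/03_recovery.R

library(contextdep)

rec <- run_recovery(w_values = seq(0.1, 0.9, by = 0.1), n_participants = 200,
                    seed = 101, bias = -0.05, noise_cv = 0.12)
dir.create("results", showWarnings = FALSE)
write.csv(rec, "results/recovery.csv", row.names = FALSE)

cat("Regression-index and offset recovery (200 observers per cell,\n")
cat("66 trials each, sensory noise 12% of the mean stimulus, bias -0.05):\n\n")
print(rec, digits = 3)
cat(sprintf("\nmax |RI bias| = %.4f (target: unbiased, E[RI] = w)\n",
            max(abs(rec$ri_bias))))
cat(sprintf("grid-mean offset error = %.4f (generative bias -0.05)\n",
            mean(rec$offset_error)))
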