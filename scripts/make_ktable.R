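#!/usr/bin/env Rscript
# Regenerates inst/extdata/k_table.csv, the pattern-to-k correction table for
# the up-down threshold estimator. The values are maximum-likelihood
# corrections under a normal psychometric function with sigma equal to one
# ladder step; see ?make_k_table. Run from the repository root.

library(eegbico)

kt <- make_k_table(max_prefix = 7, n_post = 6)
write.csv(kt, "inst/extdata/k_table.csv", row.names = FALSE)
cat("wrote", nrow(kt), "patterns\n")
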