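#!/usr/bin/env Rscript
# Apply the NEWS-Y-IPEN scoring protocol to the item responses of the
# simulated cohort and reconstruct the pooled (sample-size-weighted)
# subscale means from the country profiles.

library(newsyipen)

cohort <- read.csv("results/cohort.csv")
scored <- score_cohort(cohort)
write.csv(scored, "results/scored.csv", row.names = FALSE)
cat(sprintf("scored %d respondents; %d *_score columns\n", nrow(scored),
            sum(grepl("_score$", names(scored)))))

# sample-size-weighted reconstruction of the pooled subscale means
pr <- country_profiles()
pooled <- vapply(news_subscales(), function(sub)
  weighted.mean(pr[[paste0(sub, "_mean")]], pr$n), numeric(1))
cat("\npooled (N-weighted) subscale means from the country profiles:\n")
print(round(pooled, 2))
write.csv(data.frame(subscale = names(pooled), pooled_mean = unname(pooled)),
          "results/pooled_means.csv", row.names = FALSE)
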