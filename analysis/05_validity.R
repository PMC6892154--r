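#!/usr/bin/env Rscript
# Construct validity: linear mixed models of each subscale score on binary
# area-level SES and walkability with random unit intercepts, adjusted for
# age, sex and country, and evaluation of the a priori hypotheses.

library(newsyipen)

cohort <- read.csv("results/cohort.csv")
rows <- lapply(news_subscales(), function(sub) {
  est <- fit_validity_lmm(cohort, outcome = sub)
  do.call(rbind, lapply(c(ses = "ses_high", walk = "walk_high"), function(term) {
    r <- est[est$term == term, ]
    data.frame(subscale = sub,
               exposure = if (term == "ses_high") "ses" else "walk",
               b = r$b, se = r$se, lo95 = r$lo95, hi95 = r$hi95, p = r$p)
  }))
})
estimates <- do.call(rbind, rows)
evaluation <- hypothesis_evaluation(estimates)
write.csv(estimates, "results/validity_estimates.csv", row.names = FALSE)
write.csv(evaluation, "results/validity_hypotheses.csv", row.names = FALSE)

cat("hypothesis evaluation:\n")
print(evaluation[, c("subscale", "exposure", "expected", "b", "p", "status")],
      digits = 3)
cat(sprintf("\n%d of %d hypothesized positive associations confirmed\n",
            sum(evaluation$status == "confirmed"),
            sum(evaluation$expected == "+")))
cat("wrote results/validity_estimates.csv, results/validity_hypotheses.csv\n")
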