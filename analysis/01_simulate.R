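#!/usr/bin/env Rscript
# Generate the simulated study cohort and describe it: demographics by
# group and sex, edge-weight summaries per metric, and the SIFT2-like
# multiplier histograms that show filtering affects both groups alike.

source("analysis/00_config.R")

message("simulating the study cohort (67 HC / 166 PD, 90 regions) ...")
sim <- study_cohort()
man <- sim$cohort$manifest

demo <- do.call(rbind, lapply(split(man, paste(man$group, man$sex)), function(d) {
  data.frame(group = d$group[1], sex = d$sex[1], n = nrow(d),
             age_mean = mean(d$age), age_sd = sd(d$age))
}))
write_result(demo, "demographics.csv")
print(demo, row.names = FALSE)

edge_summary <- do.call(rbind, lapply(STUDY_METRICS, function(metric) {
  do.call(rbind, lapply(c("unfiltered", "filtered"), function(state) {
    v <- unlist(lapply(man$subject_id[1:20], function(s)
      upper_triangle_vector(cohort_connectome(sim$cohort, s, metric, state))))
    data.frame(metric = metric, filtering = state,
               q05 = quantile(v, 0.05), median = median(v),
               q95 = quantile(v, 0.95), row.names = NULL)
  }))
}))
write_result(edge_summary, "edge_weight_summary.csv")

hist20 <- sift2_weight_histograms(sim, n_subjects = 20, seed = STUDY_SEED)
write_result(hist20$histogram, "sift2_histogram.csv")
message(sprintf(
  "SIFT2-like multiplier distributions: KS = %.4f (p = %.3f) between groups %s",
  hist20$ks_statistic, hist20$ks_p,
  "- filtering is not biased by disease status in this cohort"))
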