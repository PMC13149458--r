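# Shared settings for the analysis workflow. Every script sources this
# file and regenerates what it needs from the master seed, so each one can
# be run standalone with Rscript from the repository root.

library(filtconn)

STUDY_SEED <- 42L
STUDY_METRICS <- c("SC", "FA", "AD", "RD", "MD")
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Simulated stand-in for the imaging cohort: 67 HC vs 166 PD over the 90
# AAL regions, all five connectivity metrics, paired filtered/unfiltered
# connectomes, no planted group effect (the null scenario the study's
# findings correspond to).
study_cohort <- function(metrics = STUDY_METRICS) {
  simulate_cohort(simulation_config(metrics = metrics, seed = STUDY_SEED))
}

write_result <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  message("  wrote ", path)
  invisible(path)
}
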