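# Shared setup for the analysis drivers: the reference synthetic study and
# its LD annotation, regenerated deterministically (seed 42) rather than
# cached, so every driver is self-contained. Sourced, not run directly.

suppressMessages(library(ldenrich))
suppressMessages(library(data.table))

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

study_config <- generator_config()  # the documented defaults, seed 42

build_study <- function(cfg = study_config) {
    study <- simulate_study(cfg)
    nbhd <- compute_ld(study$panel)
    score_table <- build_score_table(study$panel, study$tracks, nbhd = nbhd)
    stats <- align_stats(study$stats, study$panel)
    list(study = study, nbhd = nbhd, score_table = score_table,
         stats = stats, mhc = cfg$track_specs$mhc)
}
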