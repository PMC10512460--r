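# Shared configuration for the analysis scripts: one synthetic two-site
# case-control study, used by every downstream driver. Per-site group sizes
# are typical of open two-site schizophrenia cohorts after matching and
# exclusions (47/47 and 62/73 patients/controls); the connectome is scaled
# to 60 nodes (1,770 edges) so every script runs in seconds.

library(conncpm)

STUDY_SEED <- 20230907L
N_NODES <- 60L
THRESHOLD <- 0.05

study_design <- site_design(n_shared_decreased = 30,
                            n_increased_per_site = 30,
                            overlap = 0,
                            n_controls = c(47, 73),
                            n_patients = c(47, 62))
study_plan <- effect_plan(n_nodes = N_NODES, delta = 0.2)

build_study <- function() {
  generate_two_sites(study_design, study_plan, seed = STUDY_SEED)
}

study_atlas <- function() make_atlas(N_NODES)

results_dir <- file.path("results")
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
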