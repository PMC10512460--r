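#!/usr/bin/env Rscript
# Generate the synthetic two-site study and deposit it in the standard
# on-disk layout (per-subject connectivity matrices, phenotype tables,
# atlas, ground-truth JSON). Large per-subject files go under scratch/;
# small summaries under results/.

source(file.path("analysis", "00_config.R"))

study <- build_study()

data_dir <- file.path("scratch", "data")
for (site in c("site1", "site2")) {
  dir <- file.path(data_dir, site)
  write_cohort(study[[site]], dir)
  message("wrote ", length(study[[site]]$subject_ids),
          " subject matrices under ", dir)
}
write_atlas(study_atlas(), file.path(data_dir, "atlas.csv"))
jsonlite::write_json(study$truth, file.path(data_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

summary <- do.call(rbind, lapply(c("site1", "site2"), function(site) {
  d <- study[[site]]
  data.frame(site = site,
             n_controls = sum(d$labels == 0),
             n_patients = sum(d$labels == 1),
             n_nodes = d$n_nodes,
             n_edges = ncol(d$edges),
             planted_decreased = length(study$truth$decreased_edges),
             planted_increased = length(study$truth[[paste0(
               "increased_edges_", site)]]))
}))
write.csv(summary, file.path(results_dir, "study_summary.csv"),
          row.names = FALSE)
print(summary)
message("Decreased effects are shared across sites; increased effects are ",
        "site-specific (overlap ", study_design$overlap, ").")
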