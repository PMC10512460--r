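#!/usr/bin/env Rscript
# Cross-site generalization: train the directional CPM on all subjects of
# one site and predict every subject of the other, in both directions and
# for all three feature sets. Because the decreased effects are shared
# between sites while the increased effects are site-specific, decreased-
# edge models should transfer and increased-edge models should not.

source(file.path("analysis", "00_config.R"))

study <- build_study()

rows <- list()
for (dir in list(c("site1", "site2"), c("site2", "site1"))) {
  train <- study[[dir[1]]]
  test <- study[[dir[2]]]
  for (mode in c("increased", "decreased", "both")) {
    out <- suppressWarnings(
      cross_dataset_predict(train, test, mode, threshold = THRESHOLD))
    perm <- permutation_test(train, mode, threshold = THRESHOLD, B = 200,
                             seed = STUDY_SEED + 2L,
                             evaluator = "cross_dataset", test = test)
    rows[[paste(dir[1], dir[2], mode)]] <- data.frame(
      train = dir[1], test = dir[2], mode = mode,
      n_test = length(test$labels),
      accuracy = out$accuracy,
      permutation_p = perm$p_value,
      sign_test_p = sign_test(out$predictions, test$labels))
    message(sprintf("%s -> %s  %-9s accuracy %.3f (perm p %.4f)",
                    dir[1], dir[2], mode, out$accuracy, perm$p_value))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(results_dir, "transfer_accuracy.csv"),
          row.names = FALSE)

for (d in c("site1", "site2")) {
  sub <- tab[tab$train == d, ]
  message("training on ", d, ": decreased-mode transfer ",
          ifelse(sub$accuracy[sub$mode == "decreased"] >
                 sub$accuracy[sub$mode == "increased"],
                 "beats", "does not beat"),
          " increased-mode transfer (",
          round(sub$accuracy[sub$mode == "decreased"], 3), " vs ",
          round(sub$accuracy[sub$mode == "increased"], 3), ")")
}
message("Wrote results/transfer_accuracy.csv")
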