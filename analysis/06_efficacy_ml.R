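#!/usr/bin/env Rscript
# Step 6 — sequence features of guide efficacy.
#
# Guides whose target reaches |F_wmean| >= 1 in some condition enter the
# modeling set; each contributes a fixed 40-nt window (spacer + balanced
# genomic flanks), one-hot encoded into 160 features, labeled low/high
# efficacy at E = 0.5. A 75/25 split feeds the classifier harness (random
# forest and depth-1 gradient boosting here); position-wise importance and
# class-versus-library logo weights summarize the sequence signal.

suppressMessages(library(crisprifit))

ft <- read_fitness("results/fitness.tsv")
lib <- utils::read.delim("results/sim/library.tsv")

ids <- select_modeling_set(ft, min_abs_F = 1)
sub <- lib[lib$sgrna_id %in% ids, ]
E <- vapply(split(ft$sgrna$E, ft$sgrna$sgrna_id), max, numeric(1))[sub$sgrna_id]
y <- label_efficacy(E)
cat(sprintf("modeling set: %d guides (%d high, %d low efficacy)\n",
            length(y), sum(y == "high"), sum(y == "low")))

windows <- mapply(build_window, sub$spacer, sub$flank5, sub$flank3)
pos <- window_positions(nchar(sub$spacer[1]))
x <- encode_windows(unname(windows), pos)
rownames(x) <- sub$sgrna_id

sp <- split_train_validation(nrow(x), fraction = 0.75, seed = 606L)
res <- train_and_evaluate(x[sp$train, ], y[sp$train],
                          x[sp$validation, ], y[sp$validation],
                          models = c("random_forest", "gradient_boosting"),
                          seed = 607L)
utils::write.table(res$metrics, "results/ml_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(res$metrics)
cat(sprintf("high-efficacy validation guides recovered by >= 1 model: %d of %d\n",
            res$union_high, res$n_high_val))

imp <- position_importance(res$fits$random_forest, colnames(x))
utils::write.table(imp$sequence, "results/ml_importance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
lw <- logo_weights(windows[y == "high"], windows, positions = pos)
utils::write.table(lw, "results/ml_logo_weights.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
top <- imp$sequence[order(-imp$sequence$importance)[1:3], ]
cat("top importance cells (position, base):\n"); print(top)
cat("wrote results/ml_metrics.tsv, ml_importance.tsv, ml_logo_weights.tsv\n")
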