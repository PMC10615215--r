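#!/usr/bin/env Rscript
# Step 5 — screen statistics.
#
# Per-class hit summary (S >= 4 in any condition), false-call rate among
# truly neutral targets, condition-effect decomposition of each target's
# fitness profile by ordinary least squares on the cultivation design, and
# per-pathway median fitness.

suppressMessages(library(crisprifit))

ft <- read_fitness("results/fitness.tsv")
truth_tg <- utils::read.delim("results/sim/truth_targets.tsv")

# hit summary; the synthetic catalog is all protein-coding targets
classes <- setNames(rep("gene", nrow(truth_tg)), truth_tg$target_id)
summ <- class_summary(ft$target, classes, threshold = 4)
utils::write.table(summ, "results/class_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(summ)

neutral <- truth_tg$target_id[truth_tg$class == "neutral"]
sig_any <- tapply(!is.na(ft$target$S) & ft$target$S >= 4,
                  ft$target$target_id, any)
cat(sprintf("false calls among %d truly neutral targets: %.2f%%\n",
            length(neutral), 100 * mean(sig_any[neutral])))
cat(sprintf("sensitivity among non-neutral targets: %.1f%%\n",
            100 * mean(sig_any[setdiff(truth_tg$target_id, neutral)])))

# condition-effect regression on a synthetic cultivation design: the four
# simulated conditions are assigned a 2x2 CO2-by-glucose layout (light is
# held constant so one residual degree of freedom remains)
F_wide <- with(ft$target, tapply(F_wmean, list(target_id, condition_id), c))
design <- data.frame(condition_id = colnames(F_wide),
                     co2 = c("high", "high", "low", "low"),
                     light = 60, fluctuating_light = 0,
                     glucose = c(0, 1, 0, 1),
                     DCMU = 0, N_limitation = 0, generation_time_h = 20)
reg <- condition_regression(F_wide, design,
                            terms = c("co2_high", "glucose"))
utils::write.table(reg, "results/condition_regression.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("condition regression: %d coefficient rows for %d targets\n",
            nrow(reg), nrow(F_wide)))

# pathway medians over an arbitrary grouping of the synthetic catalog
set.seed(505)
pathways <- setNames(sample(sprintf("pathway_%02d", 1:12),
                            nrow(truth_tg), replace = TRUE),
                     truth_tg$target_id)
med <- pathway_median_fitness(ft$target, pathways)
utils::write.table(med, "results/pathway_medians.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("pathway medians: %d (pathway, condition) rows; most depleted: %s (%.2f)\n",
            nrow(med), med$pathway[which.min(med$median_F)], min(med$median_F)))
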