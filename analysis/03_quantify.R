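#!/usr/bin/env Rscript
# Step 3 — counts to normalized log2 fold changes.
#
# Median-of-ratios size factors, pseudocount (0.5) log2FC against each
# condition's replicate-matched generation-0 reference, then quantile
# normalization across samples so fitness scores are comparable between
# conditions with different effective generation counts.

suppressMessages(library(crisprifit))

cm <- read_counts("results/sim/counts.tsv", "results/sim/metadata.tsv")
sf <- size_factors(cm)
cat(sprintf("size factors: range %.3f - %.3f across %d samples\n",
            min(sf), max(sf), length(sf)))

l2 <- log2fc(cm, sf, pseudocount = 0.5, ref = "matched")
l2 <- quantile_normalize(l2)
meta <- attr(l2, "meta")

out <- data.frame(sgrna_id = rownames(l2), l2, check.names = FALSE)
utils::write.table(out, "results/l2fc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(meta, "results/l2fc_meta.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("log2FC matrix: %d guides x %d samples; wrote results/l2fc.tsv\n",
            nrow(l2), ncol(l2)))
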