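#!/usr/bin/env Rscript
# Normalize the main count matrix: quantile normalization within cell
# types, the >=10-normalized-counts-in->=3-samples filter, log2-CPM with
# the voom-style offsets, and the fitted mean-variance trend.

suppressMessages(library(hydroxyscan))

inp <- "results/01_sim"
out <- "results/04_norm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts(file.path(inp, "counts.tsv"))
sheet <- read_tsv(file.path(inp, "sample_sheet.tsv"))
norm <- normalize_pipeline(counts, sheet)

write_tsv(data.frame(site = rownames(norm$logcpm), norm$logcpm,
                     check.names = FALSE),
          file.path(out, "logcpm.tsv"))
write_tsv(norm$trend$trend, file.path(out, "mean_variance_trend.tsv"))
message("retained ", sum(norm$keep), " of ", length(norm$keep),
        " sites after the low-count filter")
message("mean-variance trend fitted on design with columns: ",
        paste(colnames(norm$design), collapse = ", "))
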