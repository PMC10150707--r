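#!/usr/bin/env Rscript
# Two-way UPGMA clustering (Pearson 1-r dissimilarity) of the top
# differentiated sites (p < 0.01) with the row Z-score matrix in
# dendrogram order, and a static heatmap.

suppressMessages(library(hydroxyscan))

out <- "results/07_cluster"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lc <- read_tsv("results/04_norm/logcpm.tsv")
logcpm <- as.matrix(lc[, -1])
rownames(logcpm) <- lc$site
diff <- read_tsv("results/05_diff/diff.tsv")

cl <- cluster_top_sites(logcpm, diff, p_thresh = 0.01)
message(length(cl$sites), " sites at p < 0.01 clustered")
write_tsv(data.frame(site = rownames(cl$zscores), cl$zscores,
                     check.names = FALSE),
          file.path(out, "zscores.tsv"))
writeLines(cl$sample_tree$labels[cl$sample_tree$order],
           file.path(out, "sample_order.txt"))
write_tsv(data.frame(merge1 = cl$sample_tree$merge[, 1],
                     merge2 = cl$sample_tree$merge[, 2],
                     height = cl$sample_tree$height),
          file.path(out, "sample_tree.tsv"))
message("sample leaf order: ",
        paste(cl$sample_tree$labels[cl$sample_tree$order],
              collapse = ", "))

png(file.path(out, "heatmap.png"), width = 900, height = 1200)
sheet <- read_tsv("results/01_sim/sample_sheet.tsv")
ann_col <- data.frame(cell_type = sheet$cell_type[
  match(colnames(cl$zscores), sheet$sample)],
  row.names = colnames(cl$zscores))
pheatmap::pheatmap(cl$zscores, cluster_rows = FALSE,
                   cluster_cols = FALSE, show_rownames = FALSE,
                   annotation_col = ann_col,
                   main = "Z-scores of top differentiated 5hmC sites")
invisible(dev.off())
message("heatmap written to ", file.path(out, "heatmap.png"))
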