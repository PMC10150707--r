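#!/usr/bin/env Rscript
# Annotate the demo-reference sites: mutually exclusive genomic feature
# per site (5'UTR > 3'UTR > exon > intron > promoter > intergenic), CpG
# landscape (island / 2-kb shore / 2-4-kb shelf / open sea), gene
# mapping, and the +/-1-kb TSS profile in 50-bp bins.

suppressMessages(library(hydroxyscan))

inp <- "results/01_sim"
out <- "results/03_annot"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sitemap <- read_site_map("results/02_quant/sites.bed")
gm <- read_gene_models(file.path(inp, "ref/genes.gtf"))
ann <- annotate_sites(sitemap, gm, file.path(inp, "ref/cgi.bed"))
write_tsv(ann, file.path(out, "annotation.tsv"))

feat <- table(ann$feature)
land <- table(ann$landscape)
write_tsv(data.frame(feature = names(feat), n = as.integer(feat),
                     pct = round(100 * as.integer(feat) / nrow(ann), 1)),
          file.path(out, "feature_fractions.tsv"))
write_tsv(data.frame(landscape = names(land), n = as.integer(land),
                     pct = round(100 * as.integer(land) / nrow(ann), 1)),
          file.path(out, "landscape_fractions.tsv"))
message("features: ",
        paste(names(feat), as.integer(feat), sep = "=", collapse = ", "))
message("landscape: ",
        paste(names(land), as.integer(land), sep = "=", collapse = ", "))

counts <- read_counts("results/02_quant/counts.tsv")
prof <- tss_profile(sitemap, gm, counts = counts)
write_tsv(prof, file.path(out, "tss_profile.tsv"))
message("TSS window: ", sum(prof$n_sites), " (site, TSS) pairs in +/-1 kb")

genes <- map_sites_to_genes(sitemap, gm)
write_tsv(genes$genes, file.path(out, "gene_site_counts.tsv"))
message("sites map to ", nrow(genes$genes), " genes")
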