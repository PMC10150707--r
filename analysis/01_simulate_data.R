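#!/usr/bin/env Rscript
# Generate the synthetic study inputs:
#  (a) a small RRHP read-level dataset (reference genome with planted
#      CCGG sites, per-sample FASTQ with decoy reads) used to exercise
#      the quantification stack, and
#  (b) the main 20,000-site count matrix for the paired iPSC/NSC design
#      with a global NSC hypo-hydroxymethylation shift (-0.3 log2), 2%
#      site-specific effects and one planted 9-site DhMR.

suppressMessages(library(hydroxyscan))

out <- "results/01_sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L

## (a) read-level demo: 2 chromosomes x 80 kb, ~1 CCGG per 500 bp
g <- simulate_genome(n_chrom = 2, chrom_length = 80000,
                     ccgg_rate = 1 / 500, seed = seed,
                     dir = file.path(out, "ref"))
message("reference: ", nrow(g$sitemap), " CCGG sites on 2 chromosomes")

design <- sim_design(seed = seed, n_sites = 20000)
sheet <- design$sample_sheet
write_tsv(sheet, file.path(out, "sample_sheet.tsv"))

# per-site 5hmC levels: NSC samples globally reduced
set.seed(seed)
lv <- matrix(runif(nrow(g$sitemap) * nrow(sheet), 0.2, 1),
             nrow(g$sitemap), dimnames = list(NULL, sheet$sample))
lv[, sheet$cell_type == "NSC"] <- 0.8 * lv[, sheet$cell_type == "NSC"]
rd <- simulate_reads(g$genome, g$sitemap, lv, depth = 12,
                     decoy_frac = 0.1, seed = seed,
                     dir = file.path(out, "fastq"))
write_tsv(data.frame(site = rownames(rd$tallies), rd$tallies,
                     check.names = FALSE),
          file.path(out, "true_read_tallies.tsv"))
write_tsv(data.frame(sample = names(rd$n_decoys),
                     n_decoys = as.integer(rd$n_decoys)),
          file.path(out, "decoy_log.tsv"))
message("reads: ", sum(vapply(rd$reads, nrow, integer(1))),
        " total across ", length(rd$reads), " samples (",
        sum(rd$n_decoys), " decoys)")

## (b) main count matrix: planted truth for the differential analysis
smp <- simulate_site_positions(20000, n_chrom = 4, seed = seed)
pd <- data.frame(chrom = "chr2", start_index = 1200L, k = 9L,
                 effect = -2)
sim <- simulate_counts(smp, design,
                       sim_effects(global_shift = -0.3,
                                   frac_affected = 0.02,
                                   planted_dhmrs = pd,
                                   dispersion = 0.05))
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_tsv(sim$truth, file.path(out, "ground_truth.tsv"))
message("counts: ", nrow(sim$counts$counts), " sites x ",
        ncol(sim$counts$counts), " samples; ",
        sum(sim$truth$affected), " non-null sites, one planted 9-site DhMR")
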