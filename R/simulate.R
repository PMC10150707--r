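#' Study design for the synthetic-data generator
#'
#' Mirrors the paired iPSC/NSC case-sibling structure: each subject
#' contributes one sample per cell type; disease cases are matched to
#' same-sex, age-matched unaffected siblings via pair ids.
#'
#' @param n_subjects number of subjects (default 4: 2 cases + 2
#'   siblings).
#' @param cell_types two cell states per subject (default iPSC, NSC).
#' @param n_sites number of assayable sites to simulate (default 20000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a \code{sim_design} list with a ready \code{sample_sheet}
#'   (sample, subject, cell_type, group, pair, age, sex).
#' @export
sim_design <- function(n_subjects = 4L, cell_types = c("iPSC", "NSC"),
                       n_sites = 20000L, seed = 1L) {
  if (n_subjects %% 2L != 0L)
    hx_stop("n_subjects must be even (case/sibling pairs)")
  pair <- rep(seq_len(n_subjects / 2L), each = 2L)
  group <- rep(c("case", "sibling"), n_subjects / 2L)
  sex <- rep(c("M", "F"), length.out = n_subjects / 2L)[pair]
  age <- (14L + pair)[seq_len(n_subjects)]
  subjects <- sprintf("SUBJ%02d", seq_len(n_subjects))
  sheet <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    data.frame(sample = paste0(subjects[i], "_", cell_types),
               subject = subjects[i], cell_type = cell_types,
               group = group[i], pair = pair[i], age = age[i],
               sex = sex[i], stringsAsFactors = FALSE)
  }))
  structure(list(n_subjects = n_subjects, cell_types = cell_types,
                 n_sites = as.integer(n_sites), seed = as.integer(seed),
                 sample_sheet = sheet),
            class = "sim_design")
}

#' Effect structure for the synthetic-data generator
#'
#' @param global_shift log2 mean shift applied to every site in the
#'   second cell type (default -0.3: global NSC
#'   hypo-hydroxymethylation).
#' @param frac_affected fraction of sites given an extra site-specific
#'   effect (default 0.02).
#' @param site_effect_sd sd of the per-site log2 effects (default 1).
#' @param planted_dhmrs data.frame(chrom, start_index, k, effect): runs
#'   of k consecutive sites (by within-chromosome order) sharing one
#'   log2 effect.
#' @param dispersion negative-binomial dispersion (default 0.05); 0
#'   means Poisson counts.
#' @param base_meanlog,base_sdlog log-normal baseline of per-site mean
#'   counts (defaults log(50), 1).
#' @param subject_sd sd of the subject random effect on the log2 scale
#'   (default 0.3), inducing the within-pair correlation the paired test
#'   assumes.
#' @param libsize_range relative library-depth factors drawn uniformly
#'   (default c(0.9, 1.1)).
#' @param universe_depth sequencing depth of the full aligned library
#'   the simulated sites are a subset of (default 5e6); carried as the
#'   per-sample library size.
#' @return a \code{sim_effects} list.
#' @export
sim_effects <- function(global_shift = -0.3, frac_affected = 0.02,
                        site_effect_sd = 1, planted_dhmrs = NULL,
                        dispersion = 0.05, base_meanlog = log(50),
                        base_sdlog = 1, subject_sd = 0.3,
                        libsize_range = c(0.9, 1.1),
                        universe_depth = 5e6) {
  if (frac_affected < 0 || frac_affected > 1)
    hx_stop("frac_affected must lie in [0, 1]")
  if (!is.null(planted_dhmrs) && any(planted_dhmrs$k < 2))
    hx_stop("planted DhMR run length must be >= 2")
  structure(list(global_shift = global_shift,
                 frac_affected = frac_affected,
                 site_effect_sd = site_effect_sd,
                 planted_dhmrs = planted_dhmrs,
                 dispersion = dispersion,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 subject_sd = subject_sd,
                 libsize_range = libsize_range,
                 universe_depth = universe_depth),
            class = "sim_effects")
}

#' Synthetic site positions without a sequence
#'
#' Builds a \code{site_map} directly (uniform random positions, minimum
#' spacing 5 bp) for count-level simulations that do not need a genome.
#'
#' @param n_sites total sites.
#' @param n_chrom chromosomes to spread them over (default 4).
#' @param mean_spacing mean distance between consecutive sites in bases
#'   (default 500).
#' @param seed RNG seed.
#' @return a \code{site_map}.
#' @export
simulate_site_positions <- function(n_sites, n_chrom = 4L,
                                    mean_spacing = 500, seed = 1L) {
  set.seed(seed)
  per <- diff(round(seq(0, n_sites, length.out = n_chrom + 1L)))
  entries <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    gaps <- 4L + stats::rpois(per[i], mean_spacing - 4)
    data.frame(chrom = sprintf("chr%d", i), pos = cumsum(gaps) + 1L,
               stringsAsFactors = FALSE)
  }))
  structure(entries, genome_id = "synthetic_positions",
            class = c("site_map", "data.frame"))
}

#' Simulate a reference genome with planted CCGG sites, CpG islands and
#' gene models
#'
#' Background sequence is scrubbed of accidental CCGG motifs so the
#' digest recovers exactly the planted sites; CCGG motifs are placed as
#' a minimum-gap Poisson process. Disjoint CpG islands and stranded gene
#' models (5' UTR, CDS exons, introns, 3' UTR) are laid down
#' independently.
#'
#' @param n_chrom,chrom_length chromosome count and length (bases).
#' @param ccgg_rate expected CCGG motifs per base (default 1/500; 0
#'   gives a site-free genome).
#' @param cgi_density,gene_density expected islands / genes per base.
#' @param seed RNG seed.
#' @param dir optional output directory; when given, writes genome.fa,
#'   cgi.bed and genes.gtf.
#' @return list: genome (named character), sitemap, cgi (GRanges),
#'   gene_models (as [read_gene_models()]), paths (when written).
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length = 100000L,
                            ccgg_rate = 1 / 500, cgi_density = 1 / 20000,
                            gene_density = 1 / 10000, seed = 1L,
                            dir = NULL) {
  if (n_chrom < 1L || chrom_length < 200L)
    hx_stop("need at least one chromosome of >= 200 bases")
  set.seed(seed)
  genome <- character(n_chrom)
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  site_rows <- list()
  for (i in seq_len(n_chrom)) {
    s <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
               collapse = "")
    s <- scrub_motif(s, "CCGG")
    n_sites <- stats::rpois(1, ccgg_rate * chrom_length)
    pos <- integer(0)
    if (n_sites > 0) {
      margin <- 80L
      cand <- sort(sample(seq(margin, chrom_length - margin), n_sites))
      pos <- cand[c(TRUE, diff(cand) >= 80L)]
      for (p in pos) substr(s, p, p + 3L) <- "CCGG"
      s <- scrub_motif(s, "CCGG", protect = pos)
    }
    genome[i] <- s
    if (length(pos))
      site_rows[[i]] <- data.frame(chrom = names(genome)[i], pos = pos,
                                   stringsAsFactors = FALSE)
  }
  sitemap <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(chrom = character(), pos = integer())
  sitemap <- structure(sitemap[order(sitemap$chrom, sitemap$pos), ,
                               drop = FALSE],
                       genome_id = "synthetic",
                       class = c("site_map", "data.frame"))
  rownames(sitemap) <- NULL
  cgi <- random_intervals(names(genome), chrom_length, cgi_density,
                          width_range = c(500L, 1500L))
  gene_models <- random_gene_models(names(genome), chrom_length,
                                    gene_density)
  out <- list(genome = genome, sitemap = sitemap, cgi = cgi,
              gene_models = gene_models)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
    bed <- file.path(dir, "cgi.bed")
    rtracklayer::export(cgi, bed, format = "BED")
    gtf <- file.path(dir, "genes.gtf")
    export_gene_models_gtf(gene_models, gtf)
    out$paths <- list(fasta = fa, cgi = bed, gtf = gtf)
  }
  out
}

# Internal: destroy every motif occurrence except those starting at a
# protected position, mutating a base that no protected motif covers
# (mutation to "A" can never create a new CCGG).
scrub_motif <- function(s, motif, protect = integer(0)) {
  mlen <- nchar(motif)
  prot_bases <- if (length(protect))
    unlist(lapply(protect, function(p) p:(p + mlen - 1L))) else integer(0)
  repeat {
    hits <- BiocGenerics::start(
      Biostrings::matchPattern(motif, Biostrings::DNAString(s)))
    hits <- setdiff(hits, protect)
    if (length(hits) == 0L) return(s)
    changed <- FALSE
    for (h in hits) {
      free <- setdiff(h:(h + mlen - 1L), prot_bases)
      if (length(free) == 0L) next
      b <- free[length(free)]
      substr(s, b, b) <- "A"
      changed <- TRUE
    }
    if (!changed)
      hx_stop("could not scrub accidental motifs around protected sites")
  }
}

# Internal: disjoint random intervals on each chromosome.
random_intervals <- function(chroms, chrom_length, density, width_range) {
  rows <- list()
  for (ch in chroms) {
    n <- stats::rpois(1, density * chrom_length)
    if (n == 0L) next
    w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
    st <- sort(sample(seq(1L, chrom_length - max(w)), n))
    keep <- c(TRUE, diff(st) > max(w))   # enforce disjointness
    rows[[ch]] <- data.frame(chrom = ch, start = st[keep],
                             end = st[keep] + w[keep] - 1L)
  }
  if (!length(rows))
    return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# Internal: random stranded gene models with UTR/CDS/intron structure.
random_gene_models <- function(chroms, chrom_length, density) {
  tx_rows <- list(); ex_rows <- list(); u5_rows <- list(); u3_rows <- list()
  gid <- 0L
  for (ch in chroms) {
    n <- stats::rpois(1, density * chrom_length)
    if (n == 0L) next
    glen <- sample(3000:8000, n, replace = TRUE)
    st <- sort(sample(seq(2000L, chrom_length - max(glen) - 2000L), n))
    keep <- c(TRUE, diff(st) > max(glen) + 2000L)  # genes + promoters disjoint
    st <- st[keep]; glen <- glen[keep]
    for (j in seq_along(st)) {
      gid <- gid + 1L
      gene_id <- sprintf("GENE%04d", gid)
      strand <- sample(c("+", "-"), 1)
      g_start <- st[j]; g_end <- st[j] + glen[j] - 1L
      # 5' UTR | CDS exon | intron | CDS exon | 3' UTR along the strand
      u5w <- 200L; u3w <- 300L; e1 <- 500L; e2 <- 600L
      b <- cumsum(c(0L, u5w, e1, glen[j] - u5w - u3w - e1 - e2, e2, u3w))
      seg <- data.frame(start = g_start + b[-length(b)],
                        end = g_start + b[-1] - 1L)
      lab <- c("utr5", "exon1", "intron", "exon2", "utr3")
      if (strand == "-") lab <- rev(lab)
      tx_rows[[gene_id]] <- data.frame(chrom = ch, start = g_start,
                                       end = g_end, strand = strand,
                                       gene_id = gene_id)
      exon_segs <- seg[lab %in% c("utr5", "exon1", "exon2", "utr3"), ]
      ex_rows[[gene_id]] <- data.frame(chrom = ch, start = exon_segs$start,
                                       end = exon_segs$end, strand = strand,
                                       gene_id = gene_id)
      u5_rows[[gene_id]] <- data.frame(chrom = ch,
                                       start = seg$start[lab == "utr5"],
                                       end = seg$end[lab == "utr5"],
                                       strand = strand, gene_id = gene_id)
      u3_rows[[gene_id]] <- data.frame(chrom = ch,
                                       start = seg$start[lab == "utr3"],
                                       end = seg$end[lab == "utr3"],
                                       strand = strand, gene_id = gene_id)
    }
  }
  to_gr <- function(rows) {
    if (!length(rows)) return(GenomicRanges::GRanges())
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gr$gene_id <- df$gene_id
    gr$transcript_id <- paste0(df$gene_id, ".1")
    gr
  }
  tx <- to_gr(tx_rows)
  build_gene_models(tx, to_gr(ex_rows), to_gr(u5_rows), to_gr(u3_rows))
}

# Internal: write a gene-model list as a GENCODE-style GTF.
export_gene_models_gtf <- function(gm, path) {
  stack <- function(gr, type) {
    if (length(gr) == 0L) return(NULL)
    gr$type <- type
    gr
  }
  all <- c(stack(gm$transcripts, "transcript"),
           stack(gm$exons, "exon"),
           stack(gm$utr5, "five_prime_utr"),
           stack(gm$utr3, "three_prime_utr"))
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Simulate a site-by-sample count matrix with planted effects
#'
#' Per-site baseline mean counts are log-normal; each subject carries a
#' Gaussian random effect (shared by its two samples, inducing the
#' within-pair correlation); the second cell type's means are shifted by
#' \code{global_shift} plus site-specific effects for affected sites and
#' planted DhMR runs. Counts are negative binomial at the stated
#' dispersion. Library sizes carried on the result are the exogenous
#' full-library sequencing depths, of which the simulated sites are the
#' analysis subset.
#'
#' @param sitemap a \code{site_map} (e.g. [simulate_site_positions()]).
#' @param design a [sim_design()].
#' @param effects a [sim_effects()].
#' @return list: \code{counts} (a \code{site_counts}), \code{truth}
#'   (per-site data.frame: site, affected, log2_effect, dhmr_id),
#'   \code{design}, \code{effects}.
#' @export
simulate_counts <- function(sitemap, design = sim_design(),
                            effects = sim_effects()) {
  set.seed(design$seed)
  sheet <- design$sample_sheet
  n_sites <- nrow(sitemap)
  n_samp <- nrow(sheet)
  keys <- site_key(sitemap$chrom, sitemap$pos)
  base_log2 <- log2(stats::rlnorm(n_sites, effects$base_meanlog,
                                  effects$base_sdlog))
  subj_eff <- stats::rnorm(design$n_subjects, 0, effects$subject_sd)
  names(subj_eff) <- unique(sheet$subject)
  # per-site log2 effect in the second cell type
  delta <- rep(effects$global_shift, n_sites)
  affected <- rep(FALSE, n_sites)
  dhmr_id <- rep(NA_integer_, n_sites)
  n_aff <- round(effects$frac_affected * n_sites)
  if (n_aff > 0) {
    idx <- sample.int(n_sites, n_aff)
    delta[idx] <- delta[idx] + stats::rnorm(n_aff, 0,
                                            effects$site_effect_sd)
    affected[idx] <- TRUE
  }
  if (!is.null(effects$planted_dhmrs)) {
    pd <- effects$planted_dhmrs
    for (r in seq_len(nrow(pd))) {
      on_chr <- which(sitemap$chrom == pd$chrom[r])
      run <- on_chr[pd$start_index[r]:(pd$start_index[r] + pd$k[r] - 1L)]
      if (any(is.na(run)))
        hx_stop("planted DhMR run exceeds chromosome site count")
      delta[run] <- effects$global_shift + pd$effect[r]
      affected[run] <- TRUE
      dhmr_id[run] <- r
    }
  }
  is_B <- sheet$cell_type == design$cell_types[2]
  libfac <- stats::runif(n_samp, effects$libsize_range[1],
                         effects$libsize_range[2])
  counts <- matrix(0L, n_sites, n_samp, dimnames = list(keys, sheet$sample))
  for (j in seq_len(n_samp)) {
    log2mu <- base_log2 + log2(libfac[j]) + subj_eff[sheet$subject[j]] +
      if (is_B[j]) delta else 0
    mu <- 2^log2mu
    counts[, j] <- if (effects$dispersion > 0)
      stats::rnbinom(n_sites, mu = mu, size = 1 / effects$dispersion)
    else stats::rpois(n_sites, mu)
  }
  library_sizes <- round(effects$universe_depth * libfac)
  names(library_sizes) <- sheet$sample
  truth <- data.frame(site = keys, affected = affected,
                      log2_effect = delta - effects$global_shift,
                      global_shift = effects$global_shift,
                      dhmr_id = dhmr_id, stringsAsFactors = FALSE)
  list(counts = site_counts(counts, sitemap, library_sizes),
       truth = truth, design = design, effects = effects)
}

#' Simulate RRHP FASTQ reads from per-site 5hmC levels
#'
#' Each site emits Poisson(depth x level) reads per sample; a read is
#' the CCGG-prefixed genomic sequence from the motif in either fragment
#' orientation, with a terminal "CG" P7 adapter remnant. A stated
#' fraction of decoy reads lacking the CCGG prefix exercises the P5
#' filter.
#'
#' @param genome named character vector (from [simulate_genome()]).
#' @param sitemap the matching \code{site_map}.
#' @param levels matrix in [0, 1], sites x samples.
#' @param depth expected reads per site at level 1 (default 20).
#' @param read_len genomic bases per read before the adapter (default
#'   50).
#' @param decoy_frac fraction of each sample's reads that are decoys
#'   (default 0).
#' @param seed RNG seed.
#' @param dir optional directory; when given, writes
#'   \code{<sample>.fastq.gz}.
#' @return list: \code{reads} (record table per sample),
#'   \code{tallies} (integer matrix of emitted genuine reads per site),
#'   \code{n_decoys} (per sample), \code{paths} (when written).
#' @export
simulate_reads <- function(genome, sitemap, levels, depth = 20,
                           read_len = 50L, decoy_frac = 0, seed = 1L,
                           dir = NULL) {
  if (any(levels < 0 | levels > 1)) hx_stop("levels must lie in [0, 1]")
  set.seed(seed)
  samples <- colnames(levels)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(levels)))
  keys <- site_key(sitemap$chrom, sitemap$pos)
  tallies <- matrix(0L, nrow(sitemap), length(samples),
                    dimnames = list(keys, samples))
  n_decoys <- setNames(integer(length(samples)), samples)
  reads_out <- list()
  qual1 <- function(n) strrep("I", n)
  for (j in seq_along(samples)) {
    recs <- list()
    for (s in seq_len(nrow(sitemap))) {
      n_r <- stats::rpois(1, depth * levels[s, j])
      if (n_r == 0L) next
      ch <- sitemap$chrom[s]; p <- sitemap$pos[s]
      chrom_seq <- genome[[ch]]
      emitted <- 0L
      seqs <- character(0)
      for (r in seq_len(n_r)) {
        fwd <- stats::runif(1) < 0.5
        g <- if (fwd) {
          if (p + read_len - 1L > nchar(chrom_seq)) next
          substring(chrom_seq, p, p + read_len - 1L)
        } else {
          if (p + 3L - read_len + 1L < 1L) next
          revcomp(substring(chrom_seq, p + 3L - read_len + 1L, p + 3L))
        }
        seqs <- c(seqs, paste0(g, "CG"))
        emitted <- emitted + 1L
      }
      tallies[s, j] <- tallies[s, j] + emitted
      if (emitted)
        recs[[length(recs) + 1L]] <- data.frame(
          id = sprintf("%s_site%s_%d", samples[j], keys[s],
                       seq_len(emitted)),
          seq = seqs, stringsAsFactors = FALSE)
    }
    genuine <- if (length(recs)) do.call(rbind, recs) else
      data.frame(id = character(), seq = character())
    nd <- if (decoy_frac > 0)
      as.integer(round(decoy_frac / (1 - decoy_frac) * nrow(genuine)))
    else 0L
    if (nd > 0) {
      decoy_seq <- vapply(seq_len(nd), function(i) {
        paste0("A", paste(sample(c("A", "C", "G", "T"), read_len + 1L,
                                 replace = TRUE), collapse = ""))
      }, character(1))
      genuine <- rbind(genuine,
                       data.frame(id = sprintf("%s_decoy_%d", samples[j],
                                               seq_len(nd)),
                                  seq = decoy_seq,
                                  stringsAsFactors = FALSE))
    }
    n_decoys[j] <- nd
    genuine$qual <- qual1(nchar(genuine$seq))
    reads_out[[samples[j]]] <- genuine
  }
  out <- list(reads = reads_out, tallies = tallies, n_decoys = n_decoys)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- vapply(samples, function(sm) {
      p <- file.path(dir, paste0(sm, ".fastq.gz"))
      write_fastq(reads_out[[sm]], p)
      p
    }, character(1))
  }
  out
}
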