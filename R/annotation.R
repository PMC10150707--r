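#' Load gene models from GTF/GFF or BED12
#'
#' Accepts a GENCODE-dialect GTF/GFF3 (gene / transcript / exon / CDS /
#' five_prime_utr / three_prime_utr features, or "UTR" resolved against
#' CDS position) or a BED12 file (thick region taken as CDS).
#'
#' @param path gene-model file.
#' @return list of GRanges: \code{transcripts} (with \code{gene_id},
#'   \code{transcript_id}), \code{exons}, \code{utr5}, \code{utr3},
#'   and a \code{tss} GRanges of width-1 strand-aware start sites.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed1?2?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(gene_models_from_bed12(gr))
  }
  gr <- rtracklayer::import(path)
  ty <- tolower(as.character(gr$type))
  tx <- gr[ty %in% c("transcript", "mrna")]
  if (length(tx) == 0L) tx <- gr[ty == "gene"]
  exons <- gr[ty == "exon"]
  utr5 <- gr[ty %in% c("five_prime_utr", "5utr", "utr5")]
  utr3 <- gr[ty %in% c("three_prime_utr", "3utr", "utr3")]
  if (length(utr5) == 0L && length(utr3) == 0L && any(ty == "utr")) {
    # split generic UTR records by position relative to the CDS
    utr <- gr[ty == "utr"]
    cds <- gr[ty == "cds"]
    split5 <- split_utrs(utr, cds)
    utr5 <- split5$utr5
    utr3 <- split5$utr3
  }
  norm <- function(x) {
    if (length(x) && is.null(x$gene_id)) x$gene_id <- x$transcript_id
    x
  }
  build_gene_models(norm(tx), norm(exons), norm(utr5), norm(utr3))
}

# Internal: assemble the gene-model list and TSS set.
build_gene_models <- function(tx, exons, utr5, utr3) {
  tss <- GenomicRanges::resize(tx, width = 1L, fix = "start")
  list(transcripts = tx, exons = exons, utr5 = utr5, utr3 = utr3, tss = tss)
}

# Internal: classify generic "UTR" records as 5' or 3' against the CDS.
split_utrs <- function(utr, cds) {
  if (length(utr) == 0L)
    return(list(utr5 = utr, utr3 = utr))
  is5 <- logical(length(utr))
  for (i in seq_along(utr)) {
    txid <- utr$transcript_id[i]
    cds_tx <- cds[cds$transcript_id == txid]
    if (length(cds_tx) == 0L) { is5[i] <- TRUE; next }
    minus <- as.character(BiocGenerics::strand(utr[i])) == "-"
    before_cds <- BiocGenerics::end(utr[i]) < min(BiocGenerics::start(cds_tx))
    is5[i] <- if (minus) !before_cds else before_cds
  }
  list(utr5 = utr[is5], utr3 = utr[!is5])
}

# Internal: BED12 -> gene model list.
gene_models_from_bed12 <- function(gr) {
  gr$gene_id <- gr$name
  gr$transcript_id <- gr$name
  exons <- unlist(rtracklayer::blocks(gr))
  exons$gene_id <- names(exons)
  exons$transcript_id <- names(exons)
  # thick region = CDS; leading/trailing blocks outside it are UTRs
  utr5 <- GenomicRanges::GRanges()
  utr3 <- GenomicRanges::GRanges()
  if (!is.null(gr$thick)) {
    left <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
      IRanges::IRanges(BiocGenerics::start(gr),
                       pmax(BiocGenerics::start(gr$thick) - 1L,
                            BiocGenerics::start(gr) - 1L)),
      strand = BiocGenerics::strand(gr))
    right <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
      IRanges::IRanges(pmin(BiocGenerics::end(gr$thick) + 1L,
                            BiocGenerics::end(gr) + 1L),
                       BiocGenerics::end(gr)),
      strand = BiocGenerics::strand(gr))
    left$gene_id <- gr$gene_id; right$gene_id <- gr$gene_id
    left$transcript_id <- gr$gene_id; right$transcript_id <- gr$gene_id
    keep_l <- BiocGenerics::width(left) > 0
    keep_r <- BiocGenerics::width(right) > 0
    minus <- as.character(BiocGenerics::strand(gr)) == "-"
    utr5 <- c(left[keep_l & !minus], right[keep_r & minus])
    utr3 <- c(left[keep_l & minus], right[keep_r & !minus])
  }
  build_gene_models(gr, exons, utr5, utr3)
}

# Internal: width-1 GRanges at site motif-start positions.
sites_as_granges <- function(sitemap) {
  GenomicRanges::GRanges(sitemap$chrom,
                         IRanges::IRanges(sitemap$pos, width = 1L))
}

# Internal: strand-aware promoter windows strictly upstream of each TSS.
promoter_ranges <- function(gene_models, promoter_span) {
  tss <- gene_models$tss
  minus <- as.character(BiocGenerics::strand(tss)) == "-"
  p <- BiocGenerics::start(tss)
  st <- ifelse(minus, p + 1L, pmax(p - promoter_span, 1L))
  en <- ifelse(minus, p + promoter_span, p - 1L)
  keep <- en >= st
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss)[keep],
                               IRanges::IRanges(st[keep], en[keep]))
  gr$gene_id <- tss$gene_id[keep]
  gr
}

#' Classify sites into mutually exclusive genomic features
#'
#' Precedence (configurable): 5' UTR > 3' UTR > exon > intron > promoter
#' > intergenic, evaluated over all overlapping transcripts. The promoter
#' is the window strictly upstream of a TSS (strand-aware), 1 kb by
#' default.
#'
#' @param sitemap \code{site_map} (or data.frame with chrom/pos).
#' @param gene_models list from [read_gene_models()].
#' @param promoter_span bases upstream of the TSS (default 1000).
#' @param precedence class order, highest first.
#' @return factor of feature classes, one per site.
#' @export
classify_feature <- function(sitemap, gene_models, promoter_span = 1000L,
                             precedence = c("utr5", "utr3", "exon",
                                            "intron", "promoter",
                                            "intergenic")) {
  check_intervals(gene_models$transcripts)
  gr <- sites_as_granges(sitemap)
  hit <- function(subject) {
    if (length(subject) == 0L) return(logical(length(gr)))
    IRanges::overlapsAny(gr, subject, ignore.strand = TRUE)
  }
  in_tx <- hit(gene_models$transcripts)
  flags <- list(utr5 = hit(gene_models$utr5),
                utr3 = hit(gene_models$utr3),
                exon = hit(gene_models$exons),
                intron = in_tx,
                promoter = hit(promoter_ranges(gene_models, promoter_span)))
  assigned <- rep(NA_character_, length(gr))
  for (cls in precedence) {
    sel <- if (cls == "intergenic") is.na(assigned) else
      flags[[cls]] & is.na(assigned)
    assigned[sel] <- cls
  }
  factor(assigned, levels = precedence)
}

# Internal: reject transcripts with end < start.
check_intervals <- function(gr) {
  if (length(gr) && any(BiocGenerics::width(gr) < 1L))
    hx_stop("transcript with end < start in gene models")
  invisible(TRUE)
}

#' Classify sites by CpG-island landscape
#'
#' Island if inside a CpG island; shore if within \code{shore_span}
#' (2 kb) of the nearest island boundary; shelf if within
#' \code{shelf_span} (4 kb); open sea beyond.
#'
#' @param sitemap \code{site_map}.
#' @param cgi GRanges of CpG islands, or a BED path.
#' @param shore_span,shelf_span distances in bases (defaults 2000, 4000).
#' @return factor with levels island, shore, shelf, open_sea.
#' @export
classify_landscape <- function(sitemap, cgi, shore_span = 2000L,
                               shelf_span = 4000L) {
  if (is.character(cgi)) cgi <- rtracklayer::import(cgi, format = "BED")
  cgi <- GenomicRanges::reduce(BiocGenerics::sort(cgi), ignore.strand = TRUE)
  gr <- sites_as_granges(sitemap)
  out <- rep("open_sea", length(gr))
  if (length(cgi)) {
    d <- GenomicRanges::distanceToNearest(gr, cgi, ignore.strand = TRUE)
    dist <- rep(NA_integer_, length(gr))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    # GRanges gap -> coordinate distance: adjacent bases are 1 apart
    coord_dist <- dist + 1L
    out[!is.na(dist) & dist == 0L &
          IRanges::overlapsAny(gr, cgi, ignore.strand = TRUE)] <- "island"
    sea <- out == "open_sea" & !is.na(dist)
    out[sea & coord_dist <= shore_span] <- "shore"
    out[sea & coord_dist > shore_span & coord_dist <= shelf_span] <- "shelf"
  }
  factor(out, levels = c("island", "shore", "shelf", "open_sea"))
}

#' Site density and signal profile around transcription start sites
#'
#' Signed strand-aware distance from each TSS: negative upstream. Bins of
#' \code{bin} bases tile [-half_window, +half_window); a site inside the
#' window of several TSSs contributes to each.
#'
#' @param sitemap \code{site_map}.
#' @param gene_models list from [read_gene_models()]; every transcript's
#'   TSS is used.
#' @param counts optional \code{site_counts}; when given, per-bin summed
#'   counts (over all samples) are returned too.
#' @param half_window,bin window half-width and bin size in bases
#'   (defaults 1000, 50); \code{bin} must divide \code{half_window}.
#' @return data.frame with bin_start, bin_end, n_sites and (optionally)
#'   total_counts.
#' @export
tss_profile <- function(sitemap, gene_models, counts = NULL,
                        half_window = 1000L, bin = 50L) {
  if (half_window %% bin != 0L)
    hx_stop("bin must divide half_window")
  tss <- gene_models$tss
  gr <- sites_as_granges(sitemap)
  win <- GenomicRanges::resize(GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(tss),
    IRanges::IRanges(BiocGenerics::start(tss), width = 1L)),
    width = 2L * half_window, fix = "center")
  ov <- GenomicRanges::findOverlaps(gr, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  minus <- as.character(BiocGenerics::strand(tss))[si] == "-"
  d <- sitemap$pos[qi] - BiocGenerics::start(tss)[si]
  d <- ifelse(minus, -d, d)
  keep <- d >= -half_window & d < half_window
  d <- d[keep]; qi <- qi[keep]
  breaks <- seq(-half_window, half_window, by = bin)
  bin_idx <- floor(d / bin) + half_window / bin + 1L
  n_bins <- 2L * half_window / bin
  n_sites <- tabulate(bin_idx, nbins = n_bins)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1],
                    n_sites = n_sites)
  if (!is.null(counts)) {
    site_totals <- rowSums(counts$counts)
    keys <- site_key(sitemap$chrom, sitemap$pos)
    tot <- vapply(seq_len(n_bins), function(b) {
      sum(site_totals[keys[qi[bin_idx == b]]])
    }, numeric(1))
    out$total_counts <- tot
  }
  out
}

#' Map sites to genes (body or promoter)
#'
#' @param sitemap \code{site_map}.
#' @param gene_models list from [read_gene_models()].
#' @param promoter_span promoter width upstream of TSS (default 1000).
#' @param gene_list optional character vector (e.g. disease risk genes)
#'   to intersect with.
#' @return list with \code{genes} (data.frame gene_id / n_sites),
#'   \code{site_genes} (per-site gene lists), and, when a gene list is
#'   supplied, \code{intersection} of mapped genes with it.
#' @export
map_sites_to_genes <- function(sitemap, gene_models, promoter_span = 1000L,
                               gene_list = NULL) {
  gr <- sites_as_granges(sitemap)
  targets <- c(GenomicRanges::granges(gene_models$transcripts),
               GenomicRanges::granges(promoter_ranges(gene_models,
                                                      promoter_span)))
  gene_ids <- c(gene_models$transcripts$gene_id,
                promoter_ranges(gene_models, promoter_span)$gene_id)
  ov <- GenomicRanges::findOverlaps(gr, targets, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  gid <- gene_ids[S4Vectors::subjectHits(ov)]
  per_site <- lapply(seq_along(gr), function(i) unique(gid[qi == i]))
  names(per_site) <- site_key(sitemap$chrom, sitemap$pos)
  tab <- table(unlist(lapply(per_site, unique)))
  genes <- data.frame(gene_id = names(tab), n_sites = as.integer(tab),
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_sites, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes, site_genes = per_site)
  if (!is.null(gene_list))
    out$intersection <- intersect(genes$gene_id, gene_list)
  out
}

#' Full per-site annotation table
#'
#' Combines feature class, CpG landscape, mapped genes and signed
#' distance to the nearest TSS into one table keyed by chrom:pos.
#'
#' @inheritParams classify_feature
#' @inheritParams classify_landscape
#' @return data.frame: chrom, pos, feature, landscape, gene_ids
#'   (comma-collapsed), tss_distance.
#' @export
annotate_sites <- function(sitemap, gene_models, cgi,
                           promoter_span = 1000L, shore_span = 2000L,
                           shelf_span = 4000L) {
  feature <- classify_feature(sitemap, gene_models, promoter_span)
  landscape <- classify_landscape(sitemap, cgi, shore_span, shelf_span)
  gmap <- map_sites_to_genes(sitemap, gene_models, promoter_span)
  gene_ids <- vapply(gmap$site_genes, paste, character(1), collapse = ",")
  tssd <- nearest_tss_distance(sitemap, gene_models)
  data.frame(chrom = sitemap$chrom, pos = sitemap$pos,
             feature = as.character(feature),
             landscape = as.character(landscape),
             gene_ids = gene_ids, tss_distance = tssd,
             stringsAsFactors = FALSE)
}

# Internal: signed distance to the nearest TSS over all transcripts
# (negative = upstream of the TSS on the transcript's strand).
nearest_tss_distance <- function(sitemap, gene_models) {
  tss <- gene_models$tss
  gr <- sites_as_granges(sitemap)
  if (length(tss) == 0L) return(rep(NA_integer_, length(gr)))
  nn <- GenomicRanges::nearest(gr, GenomicRanges::granges(tss),
                               ignore.strand = TRUE)
  d <- sitemap$pos - BiocGenerics::start(tss)[nn]
  minus <- as.character(BiocGenerics::strand(tss))[nn] == "-"
  out <- ifelse(minus, -d, d)
  out[is.na(nn)] <- NA_integer_
  as.integer(out)
}
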