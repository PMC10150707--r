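#' Read filtering parameters for RRHP libraries
#'
#' In an RRHP library only fragments whose MspI junction carried
#' glucosylated 5hmC are amplifiable, and these reads start with the
#' protected-site signature CCGG. Reads are filtered on that 5' motif,
#' a terminal P7 adapter remnant ("CG") is removed, low-quality 3' bases
#' are trimmed at a Phred floor, and short reads are discarded.
#'
#' @param p5_motif 5' protected-site motif (default "CCGG").
#' @param p7_adapter 3' adapter remnant removed once if present
#'   (default "CG").
#' @param min_length minimum read length in bases after trimming
#'   (default 35).
#' @param quality_floor Phred score below which trailing 3' bases are
#'   trimmed (default 20).
#' @return a \code{read_filter_params} list.
#' @export
read_filter_params <- function(p5_motif = "CCGG", p7_adapter = "CG",
                               min_length = 35L, quality_floor = 20L) {
  if (!grepl("^[ACGT]+$", p5_motif) || !grepl("^[ACGT]+$", p7_adapter))
    hx_stop("adapter motifs must be uppercase ACGT")
  if (min_length <= nchar(p5_motif))
    hx_stop("min_length must exceed the P5 motif length")
  structure(list(p5_motif = p5_motif, p7_adapter = p7_adapter,
                 min_length = as.integer(min_length),
                 quality_floor = as.integer(quality_floor)),
            class = "read_filter_params")
}

#' Read a FASTQ file into a record table
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a record table as FASTQ
#'
#' @param reads data.frame with \code{id}, \code{seq}, \code{qual}.
#' @param path output path; ".gz" suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    rec <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Filter and trim RRHP reads on the protected-site signature
#'
#' A read is kept iff it begins with the P5 motif and, after removing one
#' terminal P7 adapter occurrence and trimming 3' bases below the quality
#' floor, its length is at least \code{min_length}.
#'
#' @param reads data.frame from [read_fastq()] (columns id, seq, qual).
#' @param params a [read_filter_params()] object.
#' @return list with \code{kept} (trimmed record table) and \code{report}
#'   (total, kept, and dropped counts by reason).
#' @export
filter_and_trim <- function(reads, params = read_filter_params()) {
  stopifnot(is.data.frame(reads))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    hx_stop("malformed FASTQ record at index ", bad[1],
            ": sequence and quality lengths differ")
  n <- nrow(reads)
  has_p5 <- startsWith(reads$seq, params$p5_motif)
  seq <- reads$seq
  qual <- reads$qual
  len <- nchar(seq)
  # remove one terminal P7 adapter occurrence
  p7 <- params$p7_adapter
  p7len <- nchar(p7)
  has_p7 <- has_p5 & len >= p7len &
    substring(seq, len - p7len + 1L, len) == p7
  len <- ifelse(has_p7, len - p7len, len)
  # 3' quality trimming at a fixed Phred floor (offset 33)
  floorv <- params$quality_floor
  trim_len <- vapply(which(has_p5), function(i) {
    li <- len[i]
    q <- utf8ToInt(substr(qual[i], 1L, li)) - 33L
    while (li > 0L && q[li] < floorv) li <- li - 1L
    li
  }, integer(1))
  len[has_p5] <- trim_len
  keep <- has_p5 & len >= params$min_length
  kept <- data.frame(id = reads$id[keep],
                     seq = substring(seq[keep], 1L, len[keep]),
                     qual = substring(qual[keep], 1L, len[keep]),
                     stringsAsFactors = FALSE)
  report <- list(total = n,
                 kept = sum(keep),
                 dropped_no_p5_motif = sum(!has_p5),
                 dropped_too_short = sum(has_p5 & len < params$min_length))
  list(kept = kept, report = report)
}

# Internal: length of the k-mer used to index site contexts for placement.
PLACE_KEY_LEN <- 20L

# Internal: build the forward / reverse context index for exact placement.
build_site_index <- function(sitemap, genome) {
  seqs <- as_dna_set(genome)
  chrom_seq <- setNames(as.character(seqs), names(seqs))
  keys <- character(0)
  vals <- character(0)
  for (ch in unique(sitemap$chrom)) {
    s <- chrom_seq[[ch]]
    if (is.null(s)) hx_stop("sitemap chromosome absent from genome: ", ch)
    pos <- sitemap$pos[sitemap$chrom == ch]
    motif <- substring(s, pos, pos + 3L)
    if (any(motif != "CCGG"))
      hx_stop("sitemap/genome mismatch: no CCGG motif at ", ch, ":",
              pos[which(motif != "CCGG")[1]])
    k <- PLACE_KEY_LEN
    fok <- pos + k - 1L <= nchar(s)
    fkey <- substring(s, pos, pos + k - 1L)
    rok <- pos - (k - 4L) >= 1L
    rctx <- substring(s, pmax(pos - (k - 4L), 1L), pos + 3L)
    rkey <- vapply(rctx, revcomp, character(1), USE.NAMES = FALSE)
    sk <- site_key(ch, pos)
    keys <- c(keys, paste0("F", fkey[fok]), paste0("R", rkey[rok]))
    vals <- c(vals, paste0(sk[fok], "|F"), paste0(sk[rok], "|R"))
  }
  idx <- split(vals, keys)
  list(index = idx, chrom_seq = chrom_seq)
}

# Internal: reverse complement of a character sequence.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Place filtered reads on the site map by exact matching
#'
#' A read is assigned to a site when its full sequence matches the
#' reference exactly, starting at the site's motif on the forward strand
#' or ending at the motif on the reverse strand (CCGG is palindromic, so
#' both orientations begin with the motif). Reads matching no site, or
#' more than one, are left unassigned.
#'
#' @param reads filtered record table (from [filter_and_trim()]).
#' @param sitemap a \code{site_map} built from the same genome.
#' @param genome the reference the sitemap was built from.
#' @return list with \code{assignments} (character vector per read:
#'   site key or NA), and \code{report} (assigned / unassigned /
#'   ambiguous tallies).
#' @export
place_reads <- function(reads, sitemap, genome) {
  idx <- build_site_index(sitemap, genome)
  k <- PLACE_KEY_LEN
  assign_one <- function(seq) {
    if (nchar(seq) < k) return(NA_character_)
    cand_f <- idx$index[[paste0("F", substr(seq, 1L, k))]]
    cand_r <- idx$index[[paste0("R", substr(seq, 1L, k))]]
    cands <- unique(c(cand_f, cand_r))
    if (is.null(cands) || length(cands) == 0L) return(NA_character_)
    hits <- character(0)
    for (cv in cands) {
      parts <- strsplit(cv, "|", fixed = TRUE)[[1]]
      sk <- parts[1]; orient <- parts[2]
      loc <- parse_site_key(sk)
      s <- idx$chrom_seq[[loc$chrom]]
      len <- nchar(seq)
      ref <- if (orient == "F") {
        if (loc$pos + len - 1L > nchar(s)) "" else
          substring(s, loc$pos, loc$pos + len - 1L)
      } else {
        if (loc$pos + 3L - len + 1L < 1L) "" else
          revcomp(substring(s, loc$pos + 3L - len + 1L, loc$pos + 3L))
      }
      if (identical(ref, seq)) hits <- c(hits, sk)
    }
    hits <- unique(hits)
    if (length(hits) == 1L) hits
    else if (length(hits) > 1L) "AMBIGUOUS" else NA_character_
  }
  raw <- vapply(reads$seq, assign_one, character(1), USE.NAMES = FALSE)
  ambiguous <- !is.na(raw) & raw == "AMBIGUOUS"
  assignments <- ifelse(ambiguous, NA_character_, raw)
  list(assignments = assignments,
       report = list(total = nrow(reads),
                     assigned = sum(!is.na(assignments)),
                     unassigned = sum(is.na(assignments) & !ambiguous),
                     ambiguous = sum(ambiguous)))
}

#' Tabulate per-site read counts across samples
#'
#' @param assignments named list: one character vector of site keys per
#'   sample (NA entries, i.e. unassigned reads, are ignored).
#' @param sitemap the \code{site_map}; all its sites appear as rows even
#'   when their count is zero in every sample.
#' @return a \code{site_counts} object: integer matrix \code{counts}
#'   (rows keyed chrom:pos), \code{samples}, and per-sample
#'   \code{library_sizes} (column sums).
#' @export
count_sites <- function(assignments, sitemap) {
  samples <- names(assignments)
  if (is.null(samples) || any(duplicated(samples)))
    hx_stop("assignments must be a named list with unique sample identifiers")
  keys <- site_key(sitemap$chrom, sitemap$pos)
  counts <- vapply(assignments, function(a) {
    a <- a[!is.na(a)]
    tab <- table(factor(a, levels = keys))
    as.integer(tab)
  }, integer(length(keys)))
  counts <- matrix(counts, nrow = length(keys),
                   dimnames = list(keys, samples))
  site_counts(counts, sitemap)
}

#' Construct a site-by-sample count container
#'
#' @param counts non-negative integer matrix, rows keyed "chrom:pos".
#' @param sitemap optional \code{site_map}; reconstructed from row keys
#'   when absent.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @return a \code{site_counts} object.
#' @export
site_counts <- function(counts, sitemap = NULL, library_sizes = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    hx_stop("counts must be non-negative integers")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (is.null(sitemap)) {
    sm <- parse_site_key(rownames(counts))
    sitemap <- structure(sm, genome_id = "unknown",
                         class = c("site_map", "data.frame"))
  }
  structure(list(counts = counts, sites = sitemap,
                 samples = colnames(counts),
                 library_sizes = library_sizes),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("site_counts:", nrow(x$counts), "sites x", ncol(x$counts),
      "samples; library sizes",
      paste(x$library_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV (rows keyed chrom:pos)
#'
#' Library sizes are preserved across the round trip in a
#' \code{# library_sizes} comment line, since they need not equal the
#' column sums of an exported subset of sites.
#'
#' @param x a \code{site_counts} object.
#' @param path TSV path.
#' @export
write_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# library_sizes\t",
                    paste(colnames(x$counts), x$library_sizes,
                          sep = "=", collapse = "\t")), con)
  df <- data.frame(site = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  lib <- NULL
  if (startsWith(first, "# library_sizes")) {
    kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=", fixed = TRUE)
    lib <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  }
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$site
  if (!is.null(lib)) lib <- lib[colnames(m)]
  site_counts(m, library_sizes = lib)
}

#' Import external alignments onto the site map
#'
#' Supports SAM (converted internally and read with Rsamtools) and BED.
#' A record increments a site iff its 5' motif start coincides with the
#' site coordinate: forward-strand records at their leftmost position,
#' reverse-strand records resolved to (leftmost + read length - 4).
#' Records on unknown chromosomes are skipped with a warning; unmapped
#' records are skipped silently.
#'
#' @param files named character vector of alignment paths, one per sample.
#' @param sitemap the \code{site_map}.
#' @param format "sam" or "bed".
#' @return a \code{site_counts} object.
#' @export
import_alignments <- function(files, sitemap, format = c("sam", "bed")) {
  format <- match.arg(format)
  if (is.null(names(files)) || any(duplicated(names(files))))
    hx_stop("files must be named by unique sample identifiers")
  keys <- site_key(sitemap$chrom, sitemap$pos)
  known <- unique(sitemap$chrom)
  assignments <- lapply(files, function(f) {
    rec <- if (format == "sam") read_sam_records(f) else read_bed_records(f)
    rec <- rec[!is.na(rec$pos), , drop = FALSE]
    unknown <- setdiff(unique(rec$chrom), known)
    if (length(unknown)) {
      warning("skipping records on unknown chromosome(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
      rec <- rec[rec$chrom %in% known, , drop = FALSE]
    }
    motif_start <- ifelse(rec$strand == "-", rec$pos + rec$width - 4L, rec$pos)
    k <- site_key(rec$chrom, motif_start)
    k[k %in% keys]
  })
  count_sites(assignments, sitemap)
}

# Internal: read a SAM file (converted to BAM on the fly) into a
# chrom/pos/strand/width table; unmapped records dropped.
read_sam_records <- function(path) {
  tmp <- tempfile(fileext = ".bam")
  bam <- Rsamtools::asBam(path, sub("\\.bam$", "", tmp),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth", "flag")))[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  data.frame(chrom = as.character(res$rname)[mapped],
             pos = res$pos[mapped],
             strand = as.character(res$strand)[mapped],
             width = res$qwidth[mapped],
             stringsAsFactors = FALSE)
}

# Internal: read a BED file of aligned reads.
read_bed_records <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             pos = BiocGenerics::start(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             width = BiocGenerics::width(gr),
             stringsAsFactors = FALSE)
}
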