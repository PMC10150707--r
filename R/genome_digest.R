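#' Enumerate assayable 5hmC sites by in-silico MspI digestion
#'
#' MspI cuts C^CGG irrespective of CpG methylation, so every CCGG motif on
#' the forward strand defines one assayable 5hmC site in an RRHP library.
#' The motif is palindromic, so forward-strand occurrences cover both
#' strands; sites are strand-collapsed to one entry per motif. Motifs
#' overlapping N (masked reference) are skipped.
#'
#' @param genome a named character vector of sequences, a
#'   \code{Biostrings::DNAStringSet}, or a path to a FASTA file.
#' @param genome_id free-text identifier stored on the map.
#' @return A \code{site_map}: data.frame with columns \code{chrom} and
#'   \code{pos} (1-based coordinate of the first C of the CCGG motif),
#'   sorted by (chrom, pos), with attribute \code{genome_id}.
#' @examples
#' find_ccgg_sites(c(chr1 = "ACCGGT"))  # one site at position 2
#' @export
find_ccgg_sites <- function(genome, genome_id = "genome") {
  seqs <- as_dna_set(genome)
  if (length(seqs) == 0L || all(Biostrings::width(seqs) == 0L))
    hx_stop("empty genome: no sequences to digest")
  check_alphabet(seqs)
  hits <- Biostrings::vmatchPattern("CCGG", seqs, fixed = TRUE)
  entries <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st) == 0L) return(NULL)
    data.frame(chrom = names(seqs)[i], pos = st, stringsAsFactors = FALSE)
  }))
  if (is.null(entries))
    entries <- data.frame(chrom = character(), pos = integer(),
                          stringsAsFactors = FALSE)
  entries <- entries[order(entries$chrom, entries$pos), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, genome_id = genome_id, class = c("site_map", "data.frame"))
}

#' Fragment a genome at MspI cut positions
#'
#' The cut falls between the first C and the CGG of each CCGG motif
#' (C^CGG). Fragments tile each sequence exactly, so their concatenation
#' reproduces the input.
#'
#' @inheritParams find_ccgg_sites
#' @return named list (one element per sequence) of data.frames with
#'   columns \code{start}, \code{end} (1-based inclusive) and \code{seq}.
#' @export
digest_fragments <- function(genome) {
  seqs <- as_dna_set(genome)
  if (length(seqs) == 0L) hx_stop("empty genome: no sequences to digest")
  check_alphabet(seqs)
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    n <- nchar(s)
    hits <- BiocGenerics::start(Biostrings::matchPattern("CCGG", seqs[[i]],
                                                         fixed = TRUE))
    cuts <- hits  # cut after the first C: fragment boundary at pos (C | CGG)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    keep <- starts <= ends
    data.frame(start = starts[keep], end = ends[keep],
               seq = substring(s, starts[keep], ends[keep]),
               stringsAsFactors = FALSE)
  })
  names(out) <- names(seqs)
  out
}

#' Write a site map as BED and/or TSV
#'
#' Coordinates are 1-based inclusive internally; BED output converts to
#' 0-based half-open 4-bp intervals covering the CCGG motif.
#'
#' @param sitemap a \code{site_map}.
#' @param bed,tsv output paths (either may be NULL).
#' @export
write_site_map <- function(sitemap, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = sitemap$chrom,
                         start = sitemap$pos - 1L,
                         end = sitemap$pos + 3L,
                         name = site_key(sitemap$chrom, sitemap$pos))
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) write_tsv(as.data.frame(sitemap), tsv)
  invisible(sitemap)
}

#' Read a site map from the BED written by [write_site_map()]
#'
#' @param bed path to a 4-bp-interval BED file.
#' @param genome_id identifier to attach.
#' @return a \code{site_map}.
#' @export
read_site_map <- function(bed, genome_id = "genome") {
  gr <- rtracklayer::import(bed, format = "BED")
  entries <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        pos = BiocGenerics::start(gr),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$chrom, entries$pos), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, genome_id = genome_id, class = c("site_map", "data.frame"))
}

# Internal: coerce character vector / file path / DNAStringSet to DNAStringSet.
as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (length(genome) == 0L) hx_stop("empty genome: no sequences to digest")
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    return(tryCatch(Biostrings::DNAStringSet(genome),
                    error = function(e)
                      hx_stop("non-nucleotide characters in genome")))
  }
  hx_stop("genome must be a DNAStringSet, named character vector, or FASTA path")
}

# Internal: sequences must be over {A,C,G,T,N}.
check_alphabet <- function(seqs) {
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- freq[setdiff(names(freq), allowed)]
  if (any(bad > 0))
    hx_stop("non-nucleotide characters in genome: ",
            paste(names(bad)[bad > 0], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.site_map <- function(x, ...) {
  cat("site_map:", nrow(x), "CCGG sites on",
      length(unique(x$chrom)), "sequence(s) [",
      attr(x, "genome_id"), "]\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
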