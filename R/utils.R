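#' @importFrom stats pt pchisq var sd lowess approx setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

# Internal: canonical "chrom:pos" key used to index sites across modules.
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

# Internal: split "chrom:pos" keys back into a data.frame.
parse_site_key <- function(keys) {
  m <- regmatches(keys, regexpr(":[0-9]+$", keys))
  pos <- as.integer(sub(":", "", m))
  chrom <- sub(":[0-9]+$", "", keys)
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# Internal: stop() with a consistent prefix, no call in message.
hx_stop <- function(...) stop(..., call. = FALSE)

# Internal: draw a derived RNG seed (< 2^31) for a named sub-stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

#' Write a tab-separated table
#'
#' Thin wrapper used by all modules so output conventions stay uniform
#' (no quotes, no row names, header on).
#'
#' @param x data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path input path.
#' @return data.frame with character columns left unconverted.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
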