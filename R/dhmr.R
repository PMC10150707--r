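#' One-sided t-distribution p-values
#'
#' Lower tail for "less" (evidence of a negative effect), upper tail for
#' "greater". Degenerate sites (zero-variance, flagged upstream) receive
#' p = 0.5 so they are uninformative in any combination.
#'
#' @param t t-statistics.
#' @param df degrees of freedom (scalar or vector).
#' @param direction "less" or "greater".
#' @param degenerate optional logical flags.
#' @return one-sided p-values.
#' @export
one_sided_p <- function(t, df, direction = c("less", "greater"),
                        degenerate = NULL) {
  direction <- match.arg(direction)
  if (any(df < 1)) hx_stop("degrees of freedom must be >= 1")
  p <- stats::pt(t, df, lower.tail = (direction == "less"))
  if (!is.null(degenerate)) p[degenerate] <- 0.5
  p
}

#' DhMR scan parameters
#'
#' @param k sites per window (default 9).
#' @param max_span maximum window span in bases, exclusive (default
#'   50000).
#' @param direction "A_less" (one fixed lower tail), "A_greater", or
#'   "best_of_both" (both tails scanned, smaller combined p reported with
#'   its direction label).
#' @param p_floor smallest admissible member p before the logarithm
#'   (default \code{.Machine$double.xmin}).
#' @return a \code{dhmr_params} list.
#' @export
dhmr_params <- function(k = 9L, max_span = 50000L,
                        direction = c("A_less", "A_greater",
                                      "best_of_both"),
                        p_floor = .Machine$double.xmin) {
  direction <- match.arg(direction)
  if (k < 2L) hx_stop("window size k must be >= 2")
  if (max_span <= 0) hx_stop("max_span must be positive")
  structure(list(k = as.integer(k), max_span = as.integer(max_span),
                 direction = direction, p_floor = p_floor),
            class = "dhmr_params")
}

# Internal: Fisher statistic and combined p for one p-vector.
fisher_combine <- function(p, p_floor) {
  x2 <- -2 * sum(log(pmax(p, p_floor)))
  list(x2 = x2,
       p = stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE))
}

#' Sliding-window Fisher scan for differentially hydroxymethylated
#' regions
#'
#' One window per start index (step 1 site) over sites ordered by
#' chromosome and position, never crossing chromosomes; windows spanning
#' \code{max_span} or more bases are skipped and tallied. Each window's
#' statistic is X2 = -2 * sum(log p_i) over its k member one-sided
#' p-values, referred to a chi-square distribution with 2k degrees of
#' freedom.
#'
#' @param sites data.frame with chrom and pos, sorted by (chrom, pos).
#' @param p_less,p_greater one-sided p-value vectors aligned to
#'   \code{sites}; supply the one(s) the chosen direction needs.
#' @param params a [dhmr_params()] object.
#' @return list: \code{windows} (data.frame chrom, start, end, span_bp,
#'   first_index, x2, df, combined_p, direction), \code{n_skipped_wide}.
#' @export
fisher_windows <- function(sites, p_less = NULL, p_greater = NULL,
                           params = dhmr_params()) {
  k <- params$k
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    hx_stop("sites must be sorted by (chrom, pos)")
  tracks <- list()
  if (params$direction %in% c("A_less", "best_of_both")) {
    if (is.null(p_less)) hx_stop("p_less required for direction ",
                                 params$direction)
    tracks$less <- p_less
  }
  if (params$direction %in% c("A_greater", "best_of_both")) {
    if (is.null(p_greater)) hx_stop("p_greater required for direction ",
                                    params$direction)
    tracks$greater <- p_greater
  }
  for (tr in tracks)
    if (length(tr) != nrow(sites))
      hx_stop("p-value vector length does not match number of sites")
  logs <- lapply(tracks, function(p) log(pmax(p, params$p_floor)))
  rows <- list()
  skipped <- 0L
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n <- length(idx)
    if (n < k) next
    pos <- sites$pos[idx]
    for (i in seq_len(n - k + 1L)) {
      span <- pos[i + k - 1L] - pos[i] + 1L
      if (span >= params$max_span) { skipped <- skipped + 1L; next }
      mem <- idx[i:(i + k - 1L)]
      best <- NULL
      for (dname in names(logs)) {
        x2 <- -2 * sum(logs[[dname]][mem])
        cp <- stats::pchisq(x2, df = 2 * k, lower.tail = FALSE)
        if (is.null(best) || cp < best$p)
          best <- list(x2 = x2, p = cp, dir = dname)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = pos[i], end = pos[i + k - 1L],
        span_bp = span, first_index = mem[1], x2 = best$x2, df = 2L * k,
        combined_p = best$p, direction = best$dir,
        stringsAsFactors = FALSE)
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               span_bp = integer(), first_index = integer(),
               x2 = numeric(), df = integer(), combined_p = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  rownames(windows) <- NULL
  list(windows = windows, n_skipped_wide = skipped, k = k)
}

#' Bonferroni correction over non-overlapping bins
#'
#' The multiplicity denominator is the number of non-overlapping k-site
#' bins, ceiling(n_sites / k), not the number of sliding windows.
#'
#' @param n_sites number of tested sites.
#' @param k sites per bin (default 9).
#' @param alpha family-wise error rate (default 0.05).
#' @return list: n_bins, threshold.
#' @export
bonferroni_bins <- function(n_sites, k = 9L, alpha = 0.05) {
  if (n_sites < k) hx_stop("n_sites must be at least k")
  n_bins <- ceiling(n_sites / k)
  list(n_bins = as.integer(n_bins), threshold = alpha / n_bins)
}

#' Collapse overlapping windows into disjoint DhMR loci
#'
#' Chains of windows sharing at least one member site (on the same
#' chromosome) are reduced to the window with the smallest combined p
#' (ties broken leftmost); output sorted by combined p.
#'
#' @param scan result of [fisher_windows()] (or its \code{windows}
#'   data.frame plus \code{k}).
#' @param k window size, needed when a bare data.frame is given.
#' @return data.frame of representative windows, one per locus, with
#'   \code{size_bp} = end - start + 1.
#' @export
collapse_windows <- function(scan, k = NULL) {
  if (is.list(scan) && !is.data.frame(scan)) {
    windows <- scan$windows
    k <- scan$k
  } else windows <- scan
  if (is.null(k)) hx_stop("window size k required")
  if (nrow(windows) == 0L) {
    windows$size_bp <- integer(0)
    return(windows)
  }
  ord <- order(windows$chrom, windows$first_index)
  w <- windows[ord, , drop = FALSE]
  # windows overlap iff same chromosome and start indices within k - 1
  new_chain <- c(TRUE, !(w$chrom[-1] == w$chrom[-nrow(w)] &
                           w$first_index[-1] - w$first_index[-nrow(w)] <= k - 1))
  chain_id <- cumsum(new_chain)
  reps <- do.call(rbind, lapply(split(w, chain_id), function(g) {
    best <- which(g$combined_p == min(g$combined_p))
    g[best[which.min(g$first_index[best])], , drop = FALSE]
  }))
  reps$size_bp <- reps$end - reps$start + 1L
  reps <- reps[order(reps$combined_p, reps$chrom, reps$start), , drop = FALSE]
  rownames(reps) <- NULL
  reps
}

#' End-to-end DhMR scan from a differential-site table
#'
#' Computes one-sided p-values from the per-site t statistics, runs the
#' sliding-window Fisher scan, collapses overlapping windows, and
#' attaches the non-overlapping-bin Bonferroni threshold.
#'
#' @param diff data.frame from [differential_sites()] (needs chrom, pos,
#'   t_stat, df, degenerate).
#' @param params a [dhmr_params()] object.
#' @param collapse collapse overlapping windows (default TRUE).
#' @return list: loci (collapsed, or all windows when collapse = FALSE),
#'   windows, n_skipped_wide, bonferroni (n_bins, threshold).
#' @export
dhmr_scan <- function(diff, params = dhmr_params(), collapse = TRUE) {
  diff <- diff[order(diff$chrom, diff$pos), , drop = FALSE]
  pl <- one_sided_p(diff$t_stat, diff$df, "less",
                    degenerate = diff$degenerate)
  pg <- 1 - pl
  scan <- fisher_windows(diff[, c("chrom", "pos")], p_less = pl,
                         p_greater = pg, params = params)
  loci <- if (collapse) collapse_windows(scan) else {
    w <- scan$windows
    w$size_bp <- w$end - w$start + 1L
    w[order(w$combined_p), , drop = FALSE]
  }
  bon <- bonferroni_bins(nrow(diff), params$k)
  list(loci = loci, windows = scan$windows,
       n_skipped_wide = scan$n_skipped_wide, bonferroni = bon)
}
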