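#' Quantile-normalize counts within cell-type groups
#'
#' Performed independently within each group: every column's sorted
#' values are replaced by the mean of the order statistics across that
#' group's columns; tied entries receive the mean of their tied target
#' values. Groups with a single sample are returned unchanged with a
#' warning.
#'
#' @param counts numeric matrix (sites x samples) or \code{site_counts}.
#' @param groups character/factor of group labels, one per column.
#' @return numeric matrix of normalized counts, same dimnames.
#' @export
quantile_normalize <- function(counts, groups) {
  m <- if (inherits(counts, "site_counts")) counts$counts else counts
  if (length(groups) != ncol(m))
    hx_stop("groups must have one label per sample column")
  out <- m * 1.0
  for (g in unique(as.character(groups))) {
    cols <- which(as.character(groups) == g)
    if (length(cols) < 2L) {
      warning("group '", g, "' has a single sample; returned unchanged",
              call. = FALSE)
      next
    }
    out[, cols] <- quantile_normalize_block(m[, cols, drop = FALSE])
  }
  out
}

# Internal: mean-of-order-statistics quantile normalization of one block,
# ties assigned the mean of their tied target quantiles.
quantile_normalize_block <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "min")        # first index of each tie run
    runlen <- table(r)                          # tie-run lengths by start rank
    starts <- as.integer(names(runlen))
    # mean of the target values each tie run spans
    tie_mean <- vapply(seq_along(starts), function(i) {
      mean(target[starts[i]:(starts[i] + runlen[i] - 1L)])
    }, numeric(1))
    tie_mean[match(r, starts)]
  })
}

#' Low-count site filter
#'
#' Keeps a site iff it has at least \code{min_count} normalized counts in
#' at least \code{min_samples} samples of either cell-type group.
#'
#' @param norm_counts normalized count matrix (sites x samples).
#' @param groups group labels per column (two groups expected).
#' @param min_count minimum normalized count (default 10).
#' @param min_samples minimum samples per group meeting it (default 3).
#' @return logical vector: TRUE for retained sites.
#' @export
filter_low_counts <- function(norm_counts, groups, min_count = 10,
                              min_samples = 3L) {
  groups <- as.character(groups)
  keep <- rep(FALSE, nrow(norm_counts))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    keep <- keep |
      rowSums(norm_counts[, cols, drop = FALSE] >= min_count) >= min_samples
  }
  keep
}

#' Log2 counts-per-million transform
#'
#' \code{log2((count + prior_count) / (library_size + libsize_adjust) * 1e6)},
#' the standard voom-style transform with a 0.5 prior count and a +1
#' library-size adjustment.
#'
#' @param counts numeric matrix (sites x samples).
#' @param library_sizes per-sample library sizes; defaults to column sums.
#' @param prior_count added to every count (default 0.5).
#' @param libsize_adjust added to every library size (default 1).
#' @return numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, library_sizes = NULL, prior_count = 0.5,
                    libsize_adjust = 1) {
  m <- if (inherits(counts, "site_counts")) counts$counts else counts
  if (is.null(library_sizes)) {
    library_sizes <- if (inherits(counts, "site_counts"))
      counts$library_sizes else colSums(m)
  }
  if (any(library_sizes <= 0))
    hx_stop("zero or negative library size")
  t(log2(t(m + prior_count) / (library_sizes + libsize_adjust) * 1e6))
}

#' Fit a mean-variance trend and derive precision weights
#'
#' Per-site least-squares fits under the design give residual standard
#' deviations; a lowess curve of sqrt-sd against mean log2-CPM is the
#' trend, and each observation's weight is the inverse fourth power of
#' the trend value interpolated at its fitted log-count (voom-style).
#'
#' @param logcpm numeric matrix of log2-CPM values (sites x samples).
#' @param design model matrix (rows = samples); default intercept-only.
#' @param span lowess span (default 0.5).
#' @return list: \code{weights} (matrix, same shape as \code{logcpm}),
#'   \code{trend} (data.frame x = mean log2-CPM, y = sqrt-sd),
#'   \code{sigma} (per-site residual sd), \code{df_residual}.
#' @export
fit_mean_variance_trend <- function(logcpm, design = NULL, span = 0.5) {
  n <- ncol(logcpm)
  if (is.null(design)) design <- matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)"))
  if (qr(design)$rank < ncol(design)) {
    qrd <- qr(design)
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    hx_stop("design matrix is collinear; offending column(s): ",
            paste(bad, collapse = ", "))
  }
  df_resid <- n - ncol(design)
  if (df_resid < 1L) hx_stop("no residual degrees of freedom under design")
  fit <- lm.fit(design, t(logcpm))
  res <- t(fit$residuals)
  sigma <- sqrt(rowSums(res^2) / df_resid)
  fitted <- t(design %*% fit$coefficients)
  mean_log <- rowMeans(logcpm)
  sqrt_sd <- sqrt(sigma)
  ok <- is.finite(sqrt_sd)
  lo <- stats::lowess(mean_log[ok], sqrt_sd[ok], f = span)
  interp <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                          ties = mean)$y
  w <- matrix(1 / pmax(interp, 1e-6)^4, nrow = nrow(logcpm),
              dimnames = dimnames(logcpm))
  list(weights = w, trend = data.frame(x = lo$x, y = lo$y),
       sigma = sigma, df_residual = df_resid)
}

#' One-step normalization pipeline
#'
#' Quantile-normalizes within cell types, filters low-count sites,
#' computes log2-CPM on the retained sites and fits the mean-variance
#' trend under the supplied design.
#'
#' @param counts a \code{site_counts} object.
#' @param sample_sheet data.frame with columns \code{sample} and
#'   \code{cell_type} (and optionally age/sex used in \code{design}).
#' @param design optional model matrix; default intercept + cell type.
#' @param min_count,min_samples low-count filter parameters.
#' @param prior_count,libsize_adjust log-CPM offsets.
#' @return list: \code{logcpm} (filtered sites), \code{normalized}
#'   (full normalized matrix), \code{keep} (filter mask), \code{trend}
#'   (from [fit_mean_variance_trend()]), \code{design}.
#' @export
normalize_pipeline <- function(counts, sample_sheet, design = NULL,
                               min_count = 10, min_samples = 3L,
                               prior_count = 0.5, libsize_adjust = 1) {
  ord <- match(counts$samples, sample_sheet$sample)
  if (any(is.na(ord)))
    hx_stop("sample sheet is missing samples: ",
            paste(setdiff(counts$samples, sample_sheet$sample),
                  collapse = ", "))
  sheet <- sample_sheet[ord, , drop = FALSE]
  groups <- sheet$cell_type
  normalized <- quantile_normalize(counts$counts, groups)
  keep <- filter_low_counts(normalized, groups, min_count, min_samples)
  logcpm <- log_cpm(normalized[keep, , drop = FALSE],
                    library_sizes = counts$library_sizes,
                    prior_count = prior_count,
                    libsize_adjust = libsize_adjust)
  if (is.null(design))
    design <- stats::model.matrix(~cell_type,
                                  data.frame(cell_type = factor(groups)))
  trend <- fit_mean_variance_trend(logcpm, design)
  list(logcpm = logcpm, normalized = normalized, keep = keep,
       trend = trend, design = design, sample_sheet = sheet)
}
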