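#' Per-site paired t-tests on log2-CPM values
#'
#' For each site, differences d_i = value(B member) - value(A member) are
#' formed over subject pairs; t = mean(d) / (sd(d)/sqrt(n)) on n - 1
#' degrees of freedom, two-sided p from the t distribution. Sites with
#' zero difference variance are flagged degenerate and reported with
#' p = 1 (t = 0) so downstream window statistics stay well-defined.
#'
#' @param values numeric matrix of log2-CPM (sites x samples).
#' @param pairs data.frame with columns \code{sample_A} and
#'   \code{sample_B}: one row per subject pair; each sample may appear in
#'   only one pair.
#' @return data.frame per site: mean_diff, t_stat, df, p_value,
#'   degenerate.
#' @export
paired_t <- function(values, pairs) {
  if (nrow(pairs) < 2L) hx_stop("need at least 2 pairs")
  samp <- c(pairs$sample_A, pairs$sample_B)
  if (any(duplicated(samp)))
    hx_stop("a sample appears in more than one pair")
  missing <- setdiff(samp, colnames(values))
  if (length(missing))
    hx_stop("samples absent from the value matrix: ",
            paste(missing, collapse = ", "))
  d <- values[, pairs$sample_B, drop = FALSE] -
    values[, pairs$sample_A, drop = FALSE]
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1))
  degenerate <- sdd == 0
  t_stat <- ifelse(degenerate, 0, md / (sdd / sqrt(n)))
  df <- n - 1L
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  data.frame(site = rownames(values), mean_diff = md, t_stat = t_stat,
             df = df, p_value = p, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-site log2 fold change between two groups
#'
#' mean(log2-CPM in group B) - mean(log2-CPM in group A). The contrast
#' orientation is recorded as an attribute so the sign convention is
#' always explicit.
#'
#' @param values numeric matrix (sites x samples).
#' @param group_A,group_B character vectors of column names.
#' @return numeric vector with attribute \code{contrast} = "B_vs_A"
#'   labels.
#' @export
log2_fold_change <- function(values, group_A, group_B) {
  if (length(group_A) == 0L || length(group_B) == 0L)
    hx_stop("both contrast groups must be non-empty")
  fc <- rowMeans(values[, group_B, drop = FALSE]) -
    rowMeans(values[, group_A, drop = FALSE])
  attr(fc, "contrast") <- paste0(paste(group_B, collapse = "+"), "_vs_",
                                 paste(group_A, collapse = "+"))
  fc
}

# Internal: Newton solve of trigamma(y) = x (x > 0), vectorized.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes prior on per-site variances
#'
#' Models the observed residual variances as scaled F: s^2 ~
#' s0^2 * F(d, d0). The prior degrees of freedom d0 and prior variance
#' s0^2 are estimated by matching the first two moments of log s^2
#' (digamma / trigamma identities). When the excess variance of log s^2
#' is non-positive, d0 is infinite and every posterior variance equals
#' s0^2.
#'
#' @param s_sq per-site variances (zeros tolerated, ignored in fitting).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list with \code{d0} and \code{s0_sq}.
#' @export
estimate_eb_prior <- function(s_sq, df) {
  if (length(s_sq) < 2L) hx_stop("need at least 2 sites to estimate a prior")
  pos <- s_sq > 0
  if (!any(pos)) hx_stop("all variances are zero; no prior can be estimated")
  z <- log(s_sq[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess variability beyond sampling noise: common variance
    d0 <- Inf
    s0_sq <- mean(s_sq[pos])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics with empirical-Bayes variance shrinkage
#'
#' Shrinks each site's variance toward the prior: s_post^2 =
#' (d0 * s0^2 + d * s^2) / (d0 + d), then t = effect / (s_post * scale)
#' on d + d0 degrees of freedom. Borrowing information across sites
#' increases the degrees of freedom and stabilizes small-sample
#' variances.
#'
#' @param effects per-site effect estimates (e.g. mean paired
#'   difference).
#' @param s_sq per-site variances of the underlying observations.
#' @param df residual degrees of freedom (scalar).
#' @param stderr_scale multiplier turning sqrt(s_post^2) into the
#'   standard error of \code{effects} (for a paired design with n pairs,
#'   1/sqrt(n)).
#' @param prior optional list(d0, s0_sq); estimated from \code{s_sq}
#'   when absent.
#' @return data.frame: t_mod, df_total, p_value, s_post_sq, plus the
#'   prior as attributes \code{d0}, \code{s0_sq}.
#' @export
moderated_t <- function(effects, s_sq, df, stderr_scale,
                        prior = NULL) {
  if (is.null(prior)) prior <- estimate_eb_prior(s_sq, df)
  d0 <- prior$d0
  s0 <- prior$s0_sq
  s_post <- if (is.infinite(d0)) rep(s0, length(s_sq)) else
    (d0 * s0 + df * s_sq) / (d0 + df)
  df_total <- df + d0
  t_mod <- effects / (sqrt(s_post) * stderr_scale)
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df_total)
  out <- data.frame(t_mod = t_mod, df_total = df_total, p_value = p,
                    s_post_sq = s_post)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0
  out
}

#' Volcano classification of differential sites
#'
#' down iff log2FC < -fc_thresh and p < p_thresh; up iff log2FC >
#' fc_thresh and p < p_thresh; otherwise ns. Inequalities are strict, so
#' boundary values are not significant.
#'
#' @param log2_fc,p numeric vectors.
#' @param fc_thresh,p_thresh thresholds (defaults 1, 0.05).
#' @return factor with levels down, up, ns.
#' @export
classify_volcano <- function(log2_fc, p, fc_thresh = 1, p_thresh = 0.05) {
  cls <- rep("ns", length(log2_fc))
  cls[log2_fc < -fc_thresh & p < p_thresh] <- "down"
  cls[log2_fc > fc_thresh & p < p_thresh] <- "up"
  factor(cls, levels = c("down", "up", "ns"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1) via
#' \code{stats::p.adjust}.
#'
#' @param p numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    hx_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Direction summary of differential results
#'
#' Fractions of negative fold changes overall and among nominally
#' significant sites, plus volcano class counts — the summary used to
#' describe a global hypo-hydroxymethylation shift.
#'
#' @param diff data.frame with columns log2_fc, p_value and (optionally)
#'   volcano_class.
#' @param p_thresh nominal significance threshold (default 0.05).
#' @return list: frac_negative_overall, frac_negative_significant,
#'   n_total, n_significant, class_counts.
#' @export
summarize_direction <- function(diff, p_thresh = 0.05) {
  if (nrow(diff) == 0L) hx_stop("empty result set")
  sig <- diff$p_value < p_thresh
  out <- list(
    frac_negative_overall = mean(diff$log2_fc < 0),
    frac_negative_significant = if (any(sig))
      mean(diff$log2_fc[sig] < 0) else NA_real_,
    n_total = nrow(diff),
    n_significant = sum(sig))
  if (!is.null(diff$volcano_class))
    out$class_counts <- table(diff$volcano_class)
  out
}

#' Full per-site differential hydroxymethylation table
#'
#' Runs the classical paired t-test (the primary statistic), computes
#' log2 fold changes for the stated contrast, BH FDR, volcano classes,
#' and — alongside — the empirical-Bayes moderated t for comparison.
#'
#' @param logcpm numeric matrix (sites x samples).
#' @param sample_sheet data.frame with sample, subject, cell_type.
#' @param contrast length-2 character: c(group_B, group_A); fold change
#'   and differences are B - A.
#' @param pair_by sample-sheet column identifying pairs (default
#'   "subject").
#' @param fc_thresh,p_thresh volcano thresholds.
#' @return data.frame: site, chrom, pos, log2_fc, t_stat, df, p_value,
#'   fdr, volcano_class, degenerate, t_mod, df_mod, p_mod; contrast and
#'   EB prior recorded as attributes.
#' @export
differential_sites <- function(logcpm, sample_sheet, contrast,
                               pair_by = "subject",
                               fc_thresh = 1, p_thresh = 0.05) {
  stopifnot(length(contrast) == 2L)
  sheet <- sample_sheet
  in_B <- sheet$cell_type == contrast[1]
  in_A <- sheet$cell_type == contrast[2]
  if (!any(in_B) || !any(in_A))
    hx_stop("contrast groups not found in sample sheet cell_type")
  key <- sheet[[pair_by]]
  pairs <- merge(
    data.frame(k = key[in_A], sample_A = sheet$sample[in_A]),
    data.frame(k = key[in_B], sample_B = sheet$sample[in_B]), by = "k")
  pt_res <- paired_t(logcpm, pairs)
  fc <- log2_fold_change(logcpm, group_A = pairs$sample_A,
                         group_B = pairs$sample_B)
  n <- nrow(pairs)
  d <- logcpm[, pairs$sample_B, drop = FALSE] -
    logcpm[, pairs$sample_A, drop = FALSE]
  s_sq <- apply(d, 1, stats::var)
  mod <- moderated_t(pt_res$mean_diff, s_sq, df = n - 1L,
                     stderr_scale = 1 / sqrt(n))
  loc <- parse_site_key(rownames(logcpm))
  out <- data.frame(site = rownames(logcpm),
                    chrom = loc$chrom, pos = loc$pos,
                    log2_fc = as.numeric(fc),
                    t_stat = pt_res$t_stat, df = pt_res$df,
                    p_value = pt_res$p_value,
                    fdr = bh_fdr(pt_res$p_value),
                    volcano_class = as.character(
                      classify_volcano(fc, pt_res$p_value,
                                       fc_thresh, p_thresh)),
                    degenerate = pt_res$degenerate,
                    t_mod = mod$t_mod, df_mod = mod$df_total,
                    p_mod = mod$p_value,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrast") <- paste0(contrast[1], "_vs_", contrast[2])
  attr(out, "eb_prior") <- list(d0 = attr(mod, "d0"),
                                s0_sq = attr(mod, "s0_sq"))
  out
}

#' Unpaired two-sample t-tests (Welch or pooled)
#'
#' Provided for comparisons whose pairing structure is unknown; the
#' paired machinery remains the default elsewhere.
#'
#' @param values numeric matrix (sites x samples).
#' @param group_A,group_B column-name vectors.
#' @param pooled use the pooled-variance statistic instead of Welch.
#' @return data.frame: mean_diff, t_stat, df, p_value, degenerate.
#' @export
unpaired_t <- function(values, group_A, group_B, pooled = FALSE) {
  a <- values[, group_A, drop = FALSE]
  b <- values[, group_B, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) hx_stop("need at least 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  md <- mb - ma
  if (pooled) {
    sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(md))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, 0, md / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  data.frame(site = rownames(values), mean_diff = md, t_stat = t_stat,
             df = df, p_value = p, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}
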