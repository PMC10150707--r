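#' Pearson correlation dissimilarity, 1 - r
#'
#' @param m numeric matrix.
#' @param axis "columns" (dissimilarity between samples) or "rows"
#'   (between sites).
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   [0, 2].
#' @export
pearson_dissimilarity <- function(m, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") t(m) else m
  if (ncol(x) < 2L) hx_stop("need at least 2 vectors")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    nm <- colnames(x)[which(v == 0)[1]]
    hx_stop("zero-variance vector: ",
            if (is.null(nm)) which(v == 0)[1] else nm)
  }
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' UPGMA hierarchical clustering
#'
#' Agglomerative clustering with unweighted average inter-cluster
#' distances: at each step the closest pair of clusters merges, and the
#' distance from the merged cluster to any other is the arithmetic mean
#' over all member pairs. Join heights use the d/2 (ultrametric tree
#' height) convention; ties are broken by the lowest leaf index so the
#' dendrogram is reproducible.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @return an object of class \code{upgma}: \code{merge} (hclust-style
#'   merge matrix), \code{height} (join heights, d/2), \code{labels},
#'   \code{order} (leaf order), \code{height_convention}.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12))
    hx_stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: id < 0 => leaf -id; id > 0 => merge row id
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minleaf <- seq_len(n)            # smallest member leaf, for tie-breaks
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    m <- length(ids)
    # find closest pair; ties -> smallest (minleaf_i, minleaf_j)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      key <- c(dm[i, j], min(minleaf[i], minleaf[j]),
               max(minleaf[i], minleaf[j]))
      if (is.null(best) || key[1] < best$key[1] - 1e-15 ||
          (abs(key[1] - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
                (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- dm[i, j] / 2
    # unweighted average distance to every other cluster
    newrow <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    minleaf <- c(minleaf[keep], min(minleaf[i], minleaf[j]))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = members[[1]], height_convention = "d/2"),
            class = "upgma")
}

#' Convert a UPGMA result to an hclust object
#'
#' Heights are doubled back to full average distances so the object is
#' directly comparable with \code{hclust(..., method = "average")}.
#'
#' @param x an \code{upgma} object.
#' @return an \code{hclust} object.
#' @export
as_hclust <- function(x) {
  structure(list(merge = x$merge, height = 2 * x$height,
                 order = x$order, labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "pearson 1-r"),
            class = "hclust")
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' Distance between two leaves = 2 * height of their lowest common
#' merge (i.e. the full average distance at which they join).
#'
#' @param x an \code{upgma} object.
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_upgma <- function(x) {
  as.matrix(stats::cophenetic(as_hclust(x)))
}

#' Row-wise Z-score standardization
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation
#' 1 — the heatmap-ready transform of normalized 5hmC levels.
#'
#' @param m numeric matrix.
#' @return standardized matrix, same dimnames.
#' @export
zscore_rows <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    key <- rownames(m)[which(sds == 0)[1]]
    hx_stop("constant row: ", if (is.null(key)) which(sds == 0)[1] else key)
  }
  (m - rowMeans(m)) / sds
}

#' Select top differentiated sites by p-value
#'
#' @param diff data.frame with \code{site} and \code{p_value} columns.
#' @param p_thresh strict upper bound on p (default 0.01).
#' @return data.frame of the selected rows, sorted by p.
#' @export
select_top_sites <- function(diff, p_thresh = 0.01) {
  sel <- diff[diff$p_value < p_thresh, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Two-way clustering of top differentiated sites
#'
#' Clusters samples and sites by UPGMA on Pearson dissimilarity of the
#' log2-CPM submatrix of top sites, and returns the row-standardized
#' Z-score matrix in dendrogram order (heatmap-ready).
#'
#' @param logcpm numeric matrix (sites x samples).
#' @param diff differential table ([differential_sites()]).
#' @param p_thresh site-selection threshold (default 0.01).
#' @return list: sample_tree, site_tree (\code{upgma} objects), zscores
#'   (reordered matrix), sites (selected site keys).
#' @export
cluster_top_sites <- function(logcpm, diff, p_thresh = 0.01) {
  top <- select_top_sites(diff, p_thresh)
  if (nrow(top) < 2L) hx_stop("fewer than 2 sites pass p < ", p_thresh)
  sub <- logcpm[top$site, , drop = FALSE]
  sample_tree <- upgma(pearson_dissimilarity(sub, "columns"))
  site_tree <- upgma(pearson_dissimilarity(sub, "rows"))
  z <- zscore_rows(sub)
  z <- z[site_tree$order, sample_tree$order, drop = FALSE]
  list(sample_tree = sample_tree, site_tree = site_tree,
       zscores = z, sites = top$site)
}
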