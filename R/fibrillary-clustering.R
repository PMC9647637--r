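# PCA of the fiber metrics, variable contributions, hierarchical
# clustering on retained principal components (Ward linkage), and
# per-metric cluster characterization (one-way ANOVA eta squared).

#' PCA of a fibrillary metrics table
#'
#' Columns are centred and (by default) unit-scaled; constant columns are
#' dropped with a warning. Loading signs are fixed so each component's
#' largest-magnitude loading is positive, making outputs reproducible
#' across platforms.
#'
#' @param metrics data.frame/matrix of numeric metric columns (complete
#'   rows only are used; >= 3 required).
#' @param standardize unit-scale columns (default TRUE; the metrics mix
#'   incommensurate units).
#' @return object of class `pca_model`: list with `loadings`,
#'   `var_fraction`, `coords`, `center`, `scale`, `columns`, `rows_used`.
#' @export
fit_pca <- function(metrics, standardize = TRUE) {
  X <- as.data.frame(metrics)
  X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  keep_rows <- stats::complete.cases(X)
  X <- X[keep_rows, , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete rows")
  cst <- vapply(X, function(v) stats::var(v) < 1e-12, TRUE)
  if (all(cst)) stop("all columns constant")
  if (any(cst)) {
    warning("dropping constant column(s): ",
            paste(names(X)[cst], collapse = ", "))
    X <- X[, !cst, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  # sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, var_fraction = vf,
                 coords = pc$x, center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 columns = colnames(X), rows_used = which(keep_rows)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", length(x$columns), "metrics,", nrow(x$coords),
      "rows; PC1-2 variance:",
      paste0(round(100 * x$var_fraction[1:2], 1), "%", collapse = " + "),
      "\n")
  invisible(x)
}

#' Per-metric contribution to a principal component
#'
#' Contribution% = 100 * loading^2 / sum(loading^2); metrics above the
#' uniform expectation 100/p are flagged as important contributors.
#'
#' @param model a [fit_pca()] model.
#' @param pc component index.
#' @return data.frame (metric, contribution, above_uniform) sorted
#'   descending, with the uniform line as attribute `uniform`.
#' @export
variable_contributions <- function(model, pc = 1) {
  l2 <- model$loadings[, pc]^2
  contrib <- 100 * l2 / sum(l2)
  out <- data.frame(metric = names(contrib), contribution = unname(contrib),
                    above_uniform = unname(contrib) > 100 / length(contrib))
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  attr(out, "uniform") <- 100 / length(contrib)
  out
}

#' Hierarchical clustering on principal components (HCPC)
#'
#' Ward-linkage agglomeration (ward.D2) on Euclidean distances in the
#' retained-PC coordinate space, cut at `k` clusters. Labels are
#' canonicalized by decreasing cluster size (ties by first occurrence).
#'
#' @param model a [fit_pca()] model.
#' @param k number of clusters (default 3).
#' @param retain either an integer (number of leading PCs, default 7) or
#'   a fraction in (0, 1) (smallest PC count whose cumulative variance
#'   reaches it).
#' @return object of class `fibrillary_clusters`: list with `labels`,
#'   `tree` (hclust), `k`, `n_pcs`, `cumulative_variance`,
#'   `inertia_gain` (elbow report), `model`.
#' @export
hcpc <- function(model, k = 3, retain = 7) {
  n <- nrow(model$coords)
  if (k > n) stop("k larger than number of rows")
  if (retain < 1) {
    n_pcs <- which(cumsum(model$var_fraction) >= retain)[1]
  } else n_pcs <- as.integer(retain)
  n_pcs <- min(n_pcs, ncol(model$coords))
  Y <- model$coords[, seq_len(n_pcs), drop = FALSE]
  tree <- stats::hclust(stats::dist(Y), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  ord <- order(-as.numeric(sizes), as.numeric(names(sizes)))
  relabel <- integer(k); relabel[as.integer(names(sizes))[ord]] <- seq_len(k)
  labels <- relabel[raw]
  heights <- rev(tree$height)
  gain <- if (length(heights) > 1) -diff(heights[seq_len(min(10, length(heights)))])
    else numeric(0)
  structure(list(labels = labels, tree = tree, k = k, n_pcs = n_pcs,
                 cumulative_variance = sum(model$var_fraction[seq_len(n_pcs)]),
                 inertia_gain = gain, model = model),
            class = "fibrillary_clusters")
}

#' @export
print.fibrillary_clusters <- function(x, ...) {
  cat("<fibrillary_clusters> k =", x$k, "on", x$n_pcs, "PCs (",
      round(100 * x$cumulative_variance, 1), "% variance )\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Characterize clusters metric by metric
#'
#' Per metric: one-way ANOVA across cluster labels — eta squared
#' (between-SS / total-SS, the squared correlation ratio) and the F-test
#' p-value — plus, per cluster, the standardized difference between the
#' cluster mean and the overall mean (on the original metric scale) with
#' its direction. Rows sorted by eta squared, descending.
#'
#' @param metrics data.frame of metric columns (original scale).
#' @param labels integer cluster labels.
#' @return data.frame: metric, eta_sq, F, p, then per-cluster
#'   `dir_k` (+1/-1) and `smd_k` columns.
#' @export
characterize_clusters <- function(metrics, labels) {
  X <- as.data.frame(metrics)
  X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  ks <- sort(unique(labels))
  if (length(ks) < 2) {
    return(data.frame(metric = character(0), eta_sq = numeric(0),
                      F = numeric(0), p = numeric(0)))
  }
  rows <- lapply(names(X), function(m) {
    v <- X[[m]]
    ok <- is.finite(v)
    vv <- v[ok]; ll <- labels[ok]
    gm <- mean(vv)
    ssb <- sum(tapply(vv, ll, function(g) length(g) * (mean(g) - gm)^2))
    sst <- sum((vv - gm)^2)
    eta <- if (sst > 0) ssb / sst else 0
    dfb <- length(unique(ll)) - 1
    dfw <- length(vv) - length(unique(ll))
    Fv <- if (sst - ssb > 0) (ssb / dfb) / ((sst - ssb) / dfw) else Inf
    p <- if (sst > 0) stats::pf(Fv, dfb, dfw, lower.tail = FALSE) else 1
    if (sst == 0) { Fv <- 0; p <- 1 }
    out <- data.frame(metric = m, eta_sq = eta, F = Fv, p = p)
    sdv <- stats::sd(vv)
    for (k in ks) {
      d <- mean(vv[ll == k]) - gm
      out[[paste0("dir_", k)]] <- sign(d)
      out[[paste0("smd_", k)]] <- if (sdv > 0) d / sdv else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(-out$eta_sq), , drop = FALSE]
}

#' Pairwise Mann-Whitney comparison of TIL counts across clusters
#'
#' @param til_counts numeric TIL counts.
#' @param labels cluster labels.
#' @return data.frame: cluster_a, cluster_b, median_a, median_b, U, p
#'   (empty with a single cluster).
#' @export
cluster_til_comparison <- function(til_counts, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2)
    return(data.frame(cluster_a = integer(0), cluster_b = integer(0),
                      median_a = numeric(0), median_b = numeric(0),
                      U = numeric(0), p = numeric(0)))
  rows <- list()
  for (i in seq_along(ks)[-length(ks)]) for (j in (i + 1):length(ks)) {
    x <- til_counts[labels == ks[i]]; y <- til_counts[labels == ks[j]]
    mw <- mann_whitney_u(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_a = ks[i], cluster_b = ks[j],
      median_a = stats::median(x), median_b = stats::median(y),
      U = mw$U, p = mw$p)
  }
  do.call(rbind, rows)
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Export an hclust tree as Newick text
#' @param tree an `hclust` object.
#' @param labels leaf labels (default tree$labels or row indices).
#' @return single Newick string.
#' @export
hclust_to_newick <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(tree$merge) + 1))
  rec <- function(i, parent_h) {
    if (i < 0) return(paste0(labels[-i], ":", format(parent_h, digits = 6)))
    kids <- tree$merge[i, ]
    h <- tree$height[i]
    paste0("(", rec(kids[1], h), ",", rec(kids[2], h), "):",
           format(max(parent_h - h, 0), digits = 6))
  }
  n <- nrow(tree$merge)
  paste0("(", rec(tree$merge[n, 1], tree$height[n]), ",",
         rec(tree$merge[n, 2], tree$height[n]), ");")
}
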