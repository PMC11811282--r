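# Analysis stack: transfer entropy from network-level latents to region
# dynamics, silhouette-based cluster assessment, k-NN cluster assignment,
# and hierarchical clustering of transfer-entropy fingerprints.

discretize_quantile <- function(x, Q) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = Q + 1),
                        names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

te_plugin <- function(xs, ys) {
  # TE(X -> Y) with history 1: I(Y_{t+1}; X_t | Y_t), plug-in estimate
  n <- length(xs) - 1L
  y1 <- ys[-1]; y0 <- ys[-length(ys)]; x0 <- xs[-length(xs)]
  joint <- table(y1, y0, x0) / n
  p_y0x0 <- table(y0, x0) / n
  p_y1y0 <- table(y1, y0) / n
  p_y0 <- table(y0) / n
  te <- 0
  dm <- dimnames(joint)
  for (i in seq_along(dm$y1)) for (j in seq_along(dm$y0))
    for (k in seq_along(dm$x0)) {
      p <- joint[i, j, k]
      if (p == 0) next
      num <- p / p_y0x0[dm$y0[j], dm$x0[k]]
      den <- p_y1y0[dm$y1[i], dm$y0[j]] / p_y0[dm$y0[j]]
      te <- te + p * log2(num / den)
    }
  te
}

#' Transfer entropy between two time series
#'
#' Discrete plug-in estimator: both series are discretized into Q
#' quantile bins, transfer entropy with history length 1 is computed as
#' the conditional mutual information I(Y_t+1; X_t | Y_t), and estimator
#' bias is removed by subtracting the mean TE over source-permuted
#' surrogates.
#'
#' @param source,target equal-length numeric series (X and Y).
#' @param Q number of quantile bins.
#' @param n_perm permutation surrogates for bias correction (0 disables).
#' @param history embedding length; only 1 is supported by this estimator.
#' @param seed RNG seed for the surrogates.
#' @return bias-corrected TE in bits (can be slightly negative for
#'   independent series; raw and null mean are attached as attributes).
#' @export
transfer_entropy <- function(source, target, Q = 4, n_perm = 100,
                             history = 1, seed = 1L) {
  if (length(source) != length(target)) stop("series lengths differ")
  if (history != 1) stop("only history = 1 is implemented")
  if (length(source) < 10 * Q) stop("series too short for the embedding")
  xs <- discretize_quantile(source, Q)
  ys <- discretize_quantile(target, Q)
  te <- te_plugin(xs, ys)
  null_mean <- 0
  if (n_perm > 0) {
    set.seed(seed)
    null_vals <- vapply(seq_len(n_perm), function(i)
      te_plugin(sample(xs), ys), numeric(1))
    null_mean <- mean(null_vals)
  }
  structure(te - null_mean, raw = te, null_mean = null_mean)
}

#' Transfer-entropy table from network latents to region dynamics
#'
#' For each trace (one per training fold) and each condition, computes
#' TE from every network-level latent unit's posterior-mean series to
#' every region's mean deterministic output series. Rows are
#' (fold x unit) sources, columns are (region x condition) targets; the
#' z-scored variant uses a single global scale.
#'
#' @param traces nested list: \code{traces[[fold]][[condition]]} holds
#'   \code{z2_mu} (units x time) and \code{d1_region} (regions x time,
#'   per-region mean of deterministic outputs).
#' @param region_names region labels for the columns.
#' @param Q,n_perm estimator parameters.
#' @param seed RNG seed.
#' @return list with \code{matrix}, \code{zscore} and label metadata,
#'   class \code{te_table}.
#' @export
te_matrix <- function(traces, region_names = NULL, Q = 4, n_perm = 50,
                      seed = 1L) {
  folds <- names(traces)
  if (is.null(folds)) folds <- paste0("Fold", seq_along(traces))
  conds <- names(traces[[1]])
  n_units <- nrow(traces[[1]][[1]]$z2_mu)
  n_reg <- nrow(traces[[1]][[1]]$d1_region)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n_reg))
  rows <- as.vector(t(outer(folds, paste0("#", seq_len(n_units)),
                            paste, sep = " ")))
  cols <- as.vector(t(outer(region_names, conds, paste, sep = " ")))
  M <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (f in seq_along(folds)) for (cn in seq_along(conds)) {
    tr <- traces[[f]][[conds[cn]]]
    if (is.null(tr)) stop("missing trace for ", folds[f], "/", conds[cn])
    for (u in seq_len(n_units)) for (r in seq_len(n_reg)) {
      M[(f - 1) * n_units + u, (r - 1) * length(conds) + cn] <-
        transfer_entropy(tr$z2_mu[u, ], tr$d1_region[r, ], Q = Q,
                         n_perm = n_perm, seed = seed + 97 * u + r)
    }
  }
  Z <- (M - mean(M)) / sd(M)
  structure(list(matrix = M, zscore = Z, folds = folds, conds = conds,
                 region_names = region_names),
            class = "te_table")
}

#' Silhouette widths of a labeled point set
#'
#' Per point: a(i) is the mean distance to the other members of its own
#' cluster, b(i) the smallest mean distance to any other cluster, and
#' s(i) = (b - a) / max(a, b). Euclidean distance. Points in singleton
#' clusters get s(i) = 0 (cohesion undefined).
#'
#' @param points n x d numeric matrix (or vector).
#' @param labels cluster labels, length n; at least 2 distinct clusters.
#' @return list with per-point \code{s}, \code{mean}, and the inputs.
#' @export
silhouette_width <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for a single cluster")
  n <- nrow(points)
  D <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) < 2) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(lb)
      mean(D[i, labels == lb]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(s = s, mean = mean(s), labels = labels)
}

#' Test whether the mean silhouette width exceeds zero
#'
#' One-sample t-test of the per-point silhouette widths against zero
#' (reporting helper for cluster-emergence claims).
#'
#' @param points,labels as in \code{silhouette_width}.
#' @export
silhouette_test <- function(points, labels) {
  sw <- silhouette_width(points, labels)
  ht <- t.test(sw$s, alternative = "greater", mu = 0)
  list(mean = sw$mean, statistic = unname(ht$statistic),
       p_value = ht$p.value)
}

#' Assign a point to the candidate cluster with the larger silhouette
#'
#' Computes s(i) under each hypothetical membership of the query point
#' and returns the label maximizing it; exact ties go to the first label
#' in canonical sorted order.
#'
#' @param point query vector.
#' @param points,labels reference point set (two or more clusters).
#' @export
assign_by_silhouette <- function(point, points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  cand <- sort(unique(labels))
  if (any(table(labels) == 0) || length(cand) < 2)
    stop("need at least two nonempty candidate clusters")
  sc <- vapply(cand, function(lb) {
    aug <- rbind(points, point)
    silhouette_width(aug, c(labels, lb))$s[nrow(aug)]
  }, numeric(1))
  cand[which.max(sc)]  # which.max takes the first maximum: canonical tie-break
}

#' k-NN cluster assignment with LOOCV-selected k
#'
#' Selects k (odd values by default) by leave-one-out cross-validated
#' accuracy on the reference set, then classifies the query points by
#' majority vote under Euclidean distance. Vote ties go to the first
#' label in canonical sorted order (class::knn with deterministic
#' tie-break via odd k).
#'
#' @param query m x d matrix of points to classify.
#' @param points,labels reference set.
#' @param k fixed k; NULL selects from \code{k_grid} by LOOCV.
#' @param k_grid candidate k values (odd, so binary votes cannot tie).
#' @return list with \code{labels}, chosen \code{k}, LOOCV accuracy and
#'   per-class assignment proportions.
#' @export
knn_assign <- function(query, points, labels, k = NULL,
                       k_grid = seq(1, 15, by = 2)) {
  points <- as.matrix(points)
  query <- as.matrix(query)
  labels <- as.character(labels)
  if (nrow(points) < 1) stop("empty reference set")
  k_grid <- k_grid[k_grid <= nrow(points) - 1]
  if (!length(k_grid)) k_grid <- 1
  acc <- NA_real_
  if (is.null(k)) {
    accs <- vapply(k_grid, function(kk) {
      loo <- vapply(seq_len(nrow(points)), function(i)
        knn_vote(points[i, , drop = FALSE],
                 points[-i, , drop = FALSE], labels[-i], kk),
        character(1))
      mean(loo == labels)
    }, numeric(1))
    k <- k_grid[which.max(accs)]
    acc <- max(accs)
  }
  if (k > nrow(points)) stop("fewer reference points than k")
  pred <- vapply(seq_len(nrow(query)), function(i)
    knn_vote(query[i, , drop = FALSE], points, labels, k), character(1))
  props <- table(factor(pred, levels = sort(unique(labels)))) /
    max(1L, length(pred))
  list(labels = pred, k = k, loocv_accuracy = acc, proportions = props)
}

# majority vote among the k Euclidean-nearest references; vote ties go to
# the first label in canonical sorted order
knn_vote <- function(q, points, labels, k) {
  d2 <- colSums((t(points) - as.numeric(q))^2)
  nn <- order(d2)[seq_len(k)]
  votes <- table(labels[nn])
  names(votes)[which.max(votes)]  # table() orders names canonically
}

#' Hierarchical clustering of transfer-entropy fingerprints
#'
#' Agglomerative (average-linkage) clustering of the z-scored TE rows;
#' the k-cluster cut labels rows into functional-network groups.
#'
#' @param table a \code{te_table}.
#' @param k number of row groups to cut.
#' @return list with \code{hclust}, \code{groups} (named vector) and a
#'   Newick serialization of the dendrogram.
#' @export
cluster_te_rows <- function(table, k = 3) {
  Z <- if (inherits(table, "te_table")) table$zscore else as.matrix(table)
  if (nrow(Z) < 2) stop("need at least 2 rows")
  hc <- hclust(dist(Z), method = "average")
  k <- min(k, nrow(Z))
  groups <- cutree(hc, k = k)
  newick <- dendrogram_newick(as.dendrogram(hc))
  list(hclust = hc, groups = groups, k = k, newick = newick)
}

dendrogram_newick <- function(node) {
  build <- function(nd) {
    if (is.leaf(nd)) return(attr(nd, "label"))
    paste0("(", paste(vapply(seq_along(nd), function(i) build(nd[[i]]),
                             character(1)), collapse = ","), ")")
  }
  paste0(build(node), ";")
}

#' @importFrom stats is.leaf
NULL
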