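test_that("silhouette width matches hand evaluation on two tight pairs", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labs <- c("A", "A", "B", "B")
  sw <- silhouette_width(pts, labs)
  # a(i) = 1, b(i) = mean(10, sqrt(101)) for every point
  b <- mean(c(10, sqrt(101)))
  expect_equal(sw$s, rep((b - 1) / b, 4))
  expect_gt(sw$mean, 0.89)
  expect_error(silhouette_width(pts, rep("A", 4)), "single cluster")
})

test_that("silhouette equals the brute-force oracle on random data", {
  set.seed(42)
  pts <- matrix(rnorm(50 * 2), 50, 2)
  labs <- sample(c("a", "b", "c"), 50, replace = TRUE)
  sw <- silhouette_width(pts, labs)
  expect_equal(sw$s, silhouette_brute(pts, labs), tolerance = 1e-12)
  expect_true(all(sw$s >= -1 & sw$s <= 1))
  # independent library cross-check
  cs <- cluster::silhouette(as.integer(factor(labs)), dist(pts))
  expect_equal(sort(sw$s), sort(as.numeric(cs[, "sil_width"])),
               tolerance = 1e-12)
})

test_that("random labels on symmetric data give near-zero mean silhouette", {
  set.seed(8)
  pts <- matrix(rnorm(200 * 2), 200, 2)
  m <- mean(replicate(20, {
    silhouette_width(pts, sample(c("a", "b"), 200, TRUE))$mean
  }))
  expect_lt(abs(m), 0.05)
})

test_that("silhouette-rule assignment picks the closer cluster", {
  set.seed(3)
  A <- matrix(rnorm(20, 0, 0.2), 10, 2)
  B <- matrix(rnorm(20, 5, 0.2), 10, 2)
  pts <- rbind(A, B); labs <- rep(c("A", "B"), each = 10)
  expect_equal(assign_by_silhouette(colMeans(A), pts, labs), "A")
  expect_equal(assign_by_silhouette(colMeans(B), pts, labs), "B")
  # exact midpoint between mirror-image clusters: canonical tie-break
  P <- rbind(c(-1, 0), c(-2, 0)); Q <- rbind(c(1, 0), c(2, 0))
  expect_equal(assign_by_silhouette(c(0, 0), rbind(P, Q),
                                    c("A", "A", "B", "B")), "A")
  # agreement with explicit augmented-silhouette computation
  for (i in 1:20) {
    p <- rnorm(2, 2.5, 2)
    sA <- silhouette_brute(rbind(pts, p), c(labs, "A"))[21]
    sB <- silhouette_brute(rbind(pts, p), c(labs, "B"))[21]
    want <- if (sA >= sB) "A" else "B"
    expect_equal(assign_by_silhouette(p, pts, labs), want)
  }
})

test_that("k-NN assignment selects k by LOOCV and votes deterministically", {
  set.seed(5)
  ref <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
               matrix(rnorm(100, 3, 0.1), 50, 2))
  labs <- rep(c("A", "B"), each = 50)
  res <- knn_assign(rbind(c(0, 0), c(3, 3)), ref, labs)
  expect_equal(res$labels, c("A", "B"))
  expect_gte(res$loocv_accuracy, 0.99)
  # query equal to a reference point with k = 1 returns its label
  res1 <- knn_assign(ref[7, , drop = FALSE], ref, labs, k = 1)
  expect_equal(res1$labels, "A")
  # k = 1 self-classification reproduces the reference labels
  self <- knn_assign(ref, ref, labs, k = 1)
  expect_equal(self$labels, labs)
  # cross-check against the class package on unambiguous queries
  q <- rbind(c(-0.2, 0.1), c(3.2, 2.9), c(1.0, 1.1))
  ours <- knn_assign(q, ref, labs, k = 5)$labels
  theirs <- as.character(class::knn(ref, q, labs, k = 5))
  expect_equal(ours, theirs)
  expect_error(knn_assign(q, ref[0, , drop = FALSE], character(0)),
               "empty reference")
})

test_that("transfer entropy matches exact enumeration on a noisy copy chain", {
  # Y_{t+1} = X_t flipped with probability p; X iid Bernoulli(0.5).
  # Exact TE = I(Y'; X | Y) = H(Y') - H(p) = 1 - H2(p) bits.
  p_flip <- 0.1
  H2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  te_exact <- 1 - H2(p_flip)
  set.seed(21)
  n <- 6000
  # balanced classes throughout so the quantile bins recover the binary
  # values exactly (binary medians are degenerate otherwise)
  x <- sample(rep(0:1, n / 2))
  base <- x[-n]
  flip1 <- sample(which(base == 1), round(p_flip * sum(base == 1)))
  flip0 <- sample(which(base == 0), round(p_flip * sum(base == 0)))
  ynext <- base
  ynext[c(flip1, flip0)] <- 1 - ynext[c(flip1, flip0)]
  y <- c(x[n], ynext)
  te <- transfer_entropy(x, y, Q = 2, n_perm = 50, seed = 4)
  expect_lt(abs(as.numeric(te) - te_exact), 0.05)
  # reverse direction carries no information
  te_rev <- transfer_entropy(y, x, Q = 2, n_perm = 50, seed = 4)
  expect_lt(abs(as.numeric(te_rev)), 0.02)
})

test_that("transfer entropy of independent series is near zero", {
  set.seed(11)
  x <- rnorm(3000); y <- rnorm(3000)
  te <- transfer_entropy(x, y, Q = 4, n_perm = 100, seed = 2)
  expect_lt(abs(as.numeric(te)), 0.02)
  expect_error(transfer_entropy(rnorm(10), rnorm(10)), "too short")
  expect_error(transfer_entropy(rnorm(100), rnorm(99)), "lengths differ")
})

test_that("TE table recovers planted driver structure", {
  set.seed(13)
  T <- 2500
  z <- matrix(rnorm(2 * T), 2, T)
  # unit 1 drives region 1 strongly; unit 2 drives region 2
  lag <- function(v) c(0, v[-length(v)])
  d1 <- rbind(0.9 * lag(z[1, ]) + 0.1 * rnorm(T),
              0.9 * lag(z[2, ]) + 0.1 * rnorm(T))
  tr <- list(Fold1 = list(
    awake = list(z2_mu = z, d1_region = d1),
    anesthetized = list(z2_mu = z, d1_region = d1)))
  tab <- te_matrix(tr, region_names = c("R1", "R2"), n_perm = 20, seed = 1)
  expect_equal(dim(tab$matrix), c(2, 4))
  M <- tab$matrix
  expect_gt(M[1, 1], M[1, 3])  # unit 1 -> region 1 beats unit 1 -> region 2
  expect_gt(M[2, 3], M[2, 1])
  # duplicated trace for both conditions gives identical column pairs
  expect_equal(M[, 1], M[, 2])
})

test_that("hierarchical clustering of TE rows recovers planted blocks", {
  set.seed(17)
  base <- matrix(rnorm(3 * 8), 3, 8)
  rows <- base[rep(1:3, each = 4), ] + matrix(rnorm(12 * 8, 0, 0.05), 12, 8)
  rownames(rows) <- paste0("r", 1:12)
  cl <- cluster_te_rows(rows, k = 3)
  grp <- cl$groups
  expect_equal(length(unique(grp)), 3)
  for (b in 0:2)
    expect_equal(length(unique(grp[b * 4 + 1:4])), 1)
  # permutation invariance of the groupings
  perm <- sample(12)
  cl2 <- cluster_te_rows(rows[perm, ], k = 3)
  expect_equal(unname(table(cl2$groups)), unname(table(grp)))
  # identical rows merge at height zero
  same <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 5))
  cl3 <- cluster_te_rows(same, k = 2)
  expect_equal(min(cl3$hclust$height), 0)
  expect_match(cl3$newick, ";$")
})

test_that("silhouette test reports a positive-mean cluster structure", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
               matrix(rnorm(40, 4, 0.3), 20, 2))
  labs <- rep(c("x", "y"), each = 20)
  st <- silhouette_test(pts, labs)
  expect_gt(st$mean, 0.8)
  expect_lt(st$p_value, 1e-10)
})
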