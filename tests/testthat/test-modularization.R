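brute_pattern <- function(values, perm, tol = 1e-6) {
  v <- values[, perm, drop = FALSE]
  out <- matrix(0L, nrow(values), ncol(values) - 1)
  for (i in seq_len(nrow(values))) for (m in seq_len(ncol(values) - 1)) {
    d <- v[i, m + 1] - v[i, m]
    out[i, m] <- if (d > tol) 1L else if (d < -tol) -1L else 0L
  }
  rownames(out) <- rownames(values)
  out
}

test_that("flux patterns equal the sign-of-difference oracle on random matrices", {
  set.seed(42)
  for (rep in 1:200) {
    nr <- sample(1:5, 1); nc <- sample(2:8, 1)
    values <- matrix(rnorm(nr * nc), nr)
    # inject exact ties and sub-tolerance jitter
    values[sample(length(values), max(1, length(values) %/% 4))] <- 0.5
    values <- values + matrix(sample(c(0, 1e-8), length(values), TRUE), nr)
    rownames(values) <- paste0("r", seq_len(nr))
    perm <- sample(nc)
    expect_identical(to_flux_pattern(values, perm), brute_pattern(values, perm))
  }
})

test_that("basic pattern identities hold", {
  v <- rbind(a = c(1, 3, 2), b = c(2, 2, 2))
  p <- to_flux_pattern(v)
  expect_identical(p["a", ], c(1L, -1L))
  expect_identical(p["b", ], c(0L, 0L))
  expect_true(all(p %in% c(-1L, 0L, 1L)))
  # reversing a tie-free row's order negates and reverses the pattern
  v2 <- rbind(a = c(0.3, 1.9, 0.7, 2.5))
  fwd <- to_flux_pattern(v2, 1:4)
  bwd <- to_flux_pattern(v2, 4:1)
  expect_identical(bwd, -fwd[, 3:1, drop = FALSE])
  expect_error(to_flux_pattern(v, c(1, 1, 2)), "bijection")
})

test_that("adjoined pattern width and reproducibility follow the permutation count", {
  values <- matrix(rnorm(4 * 10), 4, dimnames = list(paste0("r", 1:4), NULL))
  adj <- build_adjoined_pattern(values, n_perms = 7, seed = 3)
  expect_equal(dim(adj), c(4, 7 * 9))
  expect_identical(adj, build_adjoined_pattern(values, n_perms = 7, seed = 3))
  # explicit identity permutation reduces to a single pattern matrix
  expect_identical(build_adjoined_pattern(values, permutations = list(1:10)),
                   to_flux_pattern(values))
  # duplicate input rows give identical output rows
  dupv <- values[c(1, 1, 2), ]
  adj2 <- build_adjoined_pattern(dupv, n_perms = 3, seed = 1)
  expect_identical(adj2[1, ], adj2[2, ])
})

test_that("blockwise pattern distances equal the naive adjoined computation", {
  set.seed(9)
  values <- matrix(rnorm(6 * 12), 6, dimnames = list(paste0("r", 1:6), NULL))
  d_block <- pattern_dist(values, n_perms = 5, seed = 11)
  d_naive <- stats::dist(build_adjoined_pattern(values, n_perms = 5, seed = 11))
  expect_equal(as.vector(d_block), as.vector(d_naive), tolerance = 1e-12)
})

test_that("average-linkage heights match a brute-force implementation on small inputs", {
  brute_average_linkage_heights <- function(values) {
    # naive agglomeration: merge the closest pair of clusters, average distance
    clusters <- lapply(seq_len(nrow(values)), identity)
    d <- as.matrix(stats::dist(values))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(NA, NA); bh <- Inf
      for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
      heights <- c(heights, bh)
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    heights
  }
  set.seed(14)
  for (rep in 1:10) {
    values <- matrix(rnorm(7 * 5), 7)
    hc <- stats::hclust(stats::dist(values), method = "average")
    expect_equal(sort(hc$height), sort(brute_average_linkage_heights(values)),
                 tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone merge heights
  }
})

test_that("inconsistency coefficient matches hand computation at depth 2", {
  # 4 leaves: two tight pairs far apart -> heights h1, h2 small, H large
  values <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 0), d = c(10.2, 0))
  hc <- stats::hclust(stats::dist(values), method = "average")
  inc <- inconsistency_coefficient(hc, depth = 2)
  # leaf-leaf merges have no sub-links: coefficient 0
  expect_equal(inc[1:2], c(0, 0))
  hs <- c(hc$height[3], hc$height[1], hc$height[2])
  expect_equal(inc[3], (hc$height[3] - mean(hs)) / stats::sd(hs), tolerance = 1e-12)
})

test_that("identical rows cluster together and modules separate at cutoff 1.0", {
  pat <- rbind(m1a = rep(c(1L, -1L), 25), m1b = rep(c(1L, -1L), 25),
               m2a = rep(c(-1L, 1L), 25), m2b = rep(c(-1L, 1L), 25),
               m3a = rep(c(1L, 0L, -1L, 0L), length.out = 50),
               m3b = rep(c(1L, 0L, -1L, 0L), length.out = 50))
  cl <- hierarchical_cluster(pat, cutoff = 1.0)
  expect_equal(cl$n_clusters, 3L)
  expect_equal(unname(cl$assignment["m1a"]), unname(cl$assignment["m1b"]))
  expect_equal(unname(cl$assignment["m3a"]), unname(cl$assignment["m3b"]))
  # numbering is deterministic: ascending by smallest member row
  expect_equal(unname(cl$assignment[c("m1a", "m2a", "m3a")]), 1:3)
})

test_that("clustering is invariant to row order up to renumbering", {
  set.seed(5)
  values <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("r", 1:8), NULL))
  values[2, ] <- values[1, ] + 1e-9   # force one tight pair
  cl1 <- hierarchical_cluster(to_flux_pattern(values), cutoff = 1.0)
  ord <- sample(8)
  cl2 <- hierarchical_cluster(to_flux_pattern(values)[ord, ], cutoff = 1.0)
  a1 <- cl1$assignment[paste0("r", 1:8)]
  a2 <- cl2$assignment[paste0("r", 1:8)]
  # same partition: co-membership matrices agree
  expect_identical(outer(a1, a1, "=="), outer(a2, a2, "=="))
})

test_that("single-row input yields one singleton cluster", {
  cl <- hierarchical_cluster(matrix(1:5, 1, dimnames = list("only", NULL)))
  expect_equal(cl$n_clusters, 1L)
  expect_identical(cl$assignment, c(only = 1L))
})

test_that("duplicate reinsertion lands members in their representative's cluster", {
  pat <- rbind(r1 = c(1L, -1L, 1L), r5 = c(-1L, 1L, -1L))
  cl <- hierarchical_cluster(pat, cutoff = 1.0)
  out <- reinsert_duplicates(cl, list(r5 = c("r6", "r7")))
  expect_equal(unname(out$assignment["r6"]), unname(out$assignment[["r5"]]))
  expect_equal(unname(out$assignment["r7"]), unname(out$assignment[["r5"]]))
  expect_equal(length(out$assignment), 4L)
  expect_identical(reinsert_duplicates(cl, stats::setNames(list(), character(0)))$assignment,
                   cl$assignment)
  expect_error(reinsert_duplicates(cl, list(zz = "r9")), "not clustered")
})

test_that("module recovery on the designed fixture is exact and seed-stable", {
  for (seed in c(101, 202)) {
    run <- run_toy_pipeline(seed, n_per_condition = 60, n_perms = 10)
    expect_equal(toy_truth_ari(run), 1.0)
    expect_equal(run$clusters$n_clusters, 3L)
  }
})

test_that("partitions agree across pattern-permutation seeds", {
  run <- run_toy_pipeline(77, n_per_condition = 60, n_perms = 10)
  d2 <- pattern_dist(run$core$reduced$values, 10, 999)
  cl2 <- hierarchical_cluster(d2, labels = rownames(run$core$reduced$values))
  a1 <- run$clusters$assignment[names(cl2$assignment)]
  expect_identical(outer(a1, a1, "=="),
                   outer(cl2$assignment, cl2$assignment, "=="))
})
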