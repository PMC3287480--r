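test_that("equal-frequency discretization splits quartiles and co-bins ties", {
  d <- discretize_equal_frequency(1:8, 4)
  expect_identical(d$bins, rep(1:4, each = 2L))
  expect_equal(d$counts, rep(2L, 4))
  # order independence
  x <- c(5, 1, 7, 3, 8, 2, 6, 4)
  expect_identical(discretize_equal_frequency(x, 4)$bins[order(x)],
                   rep(1:4, each = 2L))
  expect_warning(d2 <- discretize_equal_frequency(rep(3.3, 10), 4), "distinct")
  expect_identical(d2$bins, rep(1L, 10))
  # knockout-style mass at zero: zeros share one bin, positives split
  v <- c(rep(0, 1000), stats::runif(1000, 1, 2))
  d3 <- discretize_equal_frequency(v, 4)
  expect_equal(length(unique(d3$bins[v == 0])), 1L)
  expect_gte(d3$n_bins, 3L)
  expect_true(all(diff(d3$bins[order(v)]) >= 0))   # monotone in value
  # counts differ by at most 1 when all values are distinct
  for (n in c(7, 12, 41)) {
    dd <- discretize_equal_frequency(stats::runif(n), 4)
    expect_lte(diff(range(dd$counts)), 1L)
  }
})

test_that("mutual information matches direct tabulation and identity bounds", {
  # identity channel over 4 equal-frequency bins: exactly 2 bits
  b <- rep(1:4, each = 500)
  expect_equal(empirical_mi(b, b), 2)
  # independent uniform bins: analytic 0; empirical small at n = 2000
  set.seed(8)
  x <- sample.int(4, 2000, TRUE); y <- sample.int(4, 2000, TRUE)
  expect_lt(empirical_mi(x, y), 0.01)
  # hand-computed 2x2 joint table [[30,10],[10,50]]
  x2 <- rep(c(1, 1, 2, 2), c(30, 10, 10, 50))
  y2 <- rep(c(1, 2, 1, 2), c(30, 10, 10, 50))
  jt <- matrix(c(30, 10, 10, 50), 2, byrow = TRUE) / 100
  hand <- 0
  for (i in 1:2) for (j in 1:2)
    hand <- hand + jt[i, j] * log2(jt[i, j] / (sum(jt[i, ]) * sum(jt[, j])))
  expect_equal(empirical_mi(x2, y2), hand, tolerance = 1e-12)
  # symmetry, non-negativity, entropy bound on random inputs
  ent <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
  for (s in 1:25) {
    set.seed(s)
    x <- sample.int(4, 200, TRUE)
    y <- ifelse(stats::runif(200) < 0.5, x, sample.int(4, 200, TRUE))
    expect_equal(empirical_mi(x, y), empirical_mi(y, x), tolerance = 1e-12)
    expect_gte(empirical_mi(x, y), 0)
    expect_lte(empirical_mi(x, y), min(ent(x), ent(y)) + 1e-12)
  }
})

test_that("TMI equals brute-force pairwise summation and picks the hub", {
  set.seed(12)
  for (rep in 1:30) {
    nv <- sample(2:6, 1)
    bins <- matrix(sample.int(4, nv * 100, TRUE), nv,
                   dimnames = list(paste0("v", seq_len(nv)), NULL))
    target <- sample(rownames(bins), 1)
    brute <- sum(vapply(setdiff(rownames(bins), target), function(r)
      empirical_mi(bins[target, ], bins[r, ]), numeric(1)))
    expect_equal(tmi(bins, target, rownames(bins)), brute, tolerance = 1e-12)
  }
  # singleton cluster
  bins1 <- matrix(sample.int(4, 50, TRUE), 1, dimnames = list("solo", NULL))
  expect_equal(tmi(bins1, "solo", "solo"), 0)
  expect_identical(select_representative(bins1, "solo")$representative, "solo")
  # star generator: hub drives all leaves plus noise -> hub wins
  set.seed(99)
  hub <- sample.int(4, 2000, TRUE)
  leaves <- vapply(1:4, function(i)
    ifelse(stats::runif(2000) < 0.8, hub, sample.int(4, 2000, TRUE)), numeric(2000))
  bins <- rbind(hub = hub, t(leaves))
  rownames(bins) <- c("hub", paste0("leaf", 1:4))
  expect_identical(select_representative(bins, rownames(bins))$representative, "hub")
  # exact tie between duplicated variables: lexicographically smaller id wins
  dup <- matrix(rep(sample.int(4, 60, TRUE), 2), 2, byrow = TRUE,
                dimnames = list(c("rB", "rA"), NULL))
  sel <- select_representative(dup, c("rB", "rA"))
  expect_identical(sel$representative, "rA")
  expect_true(sel$tie)
  # mutually identical variables: every TMI = 2 * (n - 1) bits
  v <- rep(1:4, each = 25)
  same <- rbind(a = v, b = v, c = v)
  expect_equal(unname(select_representative(same, c("a", "b", "c"))$tmi),
               rep(4, 3))
})

test_that("MDL score matches closed forms and is family-decomposable", {
  nodes <- c("A", "B", "C")
  empty <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  # uniform independent 4-state variables: likelihood ~ 2 bits/var/sample
  M <- 4000
  bins <- matrix(rep(rep(1:4, each = M / 4), 3), 3, byrow = TRUE,
                 dimnames = list(nodes, NULL))
  score <- mdl_score(empty, bins)
  expected <- 3 * (log2(M) / 2 * 3 + 2 * M)
  expect_equal(score, expected, tolerance = 1e-9)
  # deterministic copy A -> B beats the empty graph for M >= 8
  ab <- empty; ab["A", "B"] <- 1L
  for (M2 in c(8, 40, 200)) {
    b2 <- matrix(rep(rep(1:4, length.out = M2), 2), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), NULL))
    e2 <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    a2 <- e2; a2["A", "B"] <- 1L
    # closed forms: empty = 2 * ((log2 M)/2 * 3 + 2M); arc removes B's
    # likelihood (copy is deterministic) but pays 4x3 parameters
    s_empty <- 2 * (log2(M2) / 2 * 3 + 2 * M2)
    s_arc <- log2(M2) / 2 * 3 + 2 * M2 + log2(M2) / 2 * 12
    expect_equal(mdl_score(e2, b2), s_empty, tolerance = 1e-9)
    expect_equal(mdl_score(a2, b2), s_arc, tolerance = 1e-9)
    expect_lt(mdl_score(a2, b2), mdl_score(e2, b2))
  }
  # decomposability: total equals the sum of independently recomputed families
  set.seed(4)
  bins3 <- rand_bins(nodes, 200, seed = 4)
  dag <- empty; dag["A", "B"] <- 1L; dag["B", "C"] <- 1L; dag["A", "C"] <- 1L
  fam_sum <- sum(vapply(nodes, function(nd) {
    parents <- nodes[dag[, nd] > 0]
    r <- apply(bins3, 1, function(v) length(unique(v)))
    fmbr:::family_mdl(bins3, nd, parents, r)
  }, numeric(1)))
  expect_equal(mdl_score(dag, bins3), fam_sum, tolerance = 1e-9)
  cyc <- empty; cyc["A", "B"] <- 1L; cyc["B", "A"] <- 1L
  expect_error(mdl_score(cyc, bins3), "cyclic")
})

test_that("tabu search attains the exhaustive MDL minimum on 3-node problems", {
  nodes <- c("A", "B", "C")
  dags <- all_dags(nodes)
  expect_length(dags, 25)
  n_hit <- 0
  for (s in 1:40) {
    bins <- rand_bins(nodes, 60, seed = s)
    best <- min(vapply(dags, mdl_score, numeric(1), bins = bins))
    got <- tabu_learn(bins, restarts = 3, seed = s)$mdl
    if (abs(got - best) < 1e-9) n_hit <- n_hit + 1
  }
  expect_equal(n_hit, 40)
})

test_that("deterministic copies recover the chain skeleton; noise yields no arcs", {
  v <- rep(1:4, each = 50)
  bins <- rbind(A = v, B = v, C = v)
  bn <- tabu_learn(bins, seed = 2)
  und <- bn$adj | t(bn$adj)
  expect_equal(sum(und) / 2, 2)                  # two skeleton edges
  expect_true(all(rowSums(bn$adj + t(bn$adj)) >= 1))
  # independent variables: empty graph
  set.seed(31)
  bins2 <- matrix(sample.int(4, 3 * 2000, TRUE), 3,
                  dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(sum(tabu_learn(bins2, seed = 1)$adj), 0)
  # determinism under a fixed seed
  bins3 <- rand_bins(c("A", "B", "C"), 100, seed = 5)
  expect_identical(tabu_learn(bins3, seed = 9)$adj, tabu_learn(bins3, seed = 9)$adj)
})

test_that("a known 5-node network is recovered from ancestrally sampled data", {
  nodes <- paste0("n", 1:5)
  adj <- matrix(0L, 5, 5, dimnames = list(nodes, nodes))
  adj["n1", "n2"] <- 1L; adj["n1", "n3"] <- 1L
  adj["n2", "n4"] <- 1L; adj["n3", "n5"] <- 1L
  strong <- function() {                          # strongly peaked CPT rows
    p <- matrix(0.04, 4, 4); diag(p) <- 0.88; p
  }
  cpts <- list(
    n1 = make_cpt(matrix(rep(0.25, 4), 1)),
    n2 = make_cpt(strong(), 4, "n1"),
    n3 = make_cpt(strong(), 4, "n1"),
    n4 = make_cpt(strong(), 4, "n2"),
    n5 = make_cpt(strong(), 4, "n3"))
  data <- simulate_bn_dataset(adj, cpts, 2000, seed = 17)
  bn <- tabu_learn(data, seed = 17)
  got_skel <- (bn$adj | t(bn$adj))
  want_skel <- (adj | t(adj))
  expect_identical(got_skel, want_skel)
})

test_that("learned networks are acyclic with exactly normalized CPTs", {
  for (s in 1:5) {
    bins <- rand_bins(paste0("x", 1:4), 150, seed = 100 + s)
    bn <- tabu_learn(bins, seed = s)
    expect_true(igraph::is_dag(bn_to_igraph(bn)))
    for (cpt in bn$cpts) {
      nd <- length(dim(cpt))
      sums <- apply(cpt, seq_len(nd - 1), sum)
      expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
    }
  }
})

test_that("ancestral sampling reproduces deterministic structure and seeds", {
  nodes <- c("A", "B", "C")
  adj <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  adj["A", "B"] <- 1L; adj["B", "C"] <- 1L
  copy_cpt <- make_cpt(diag(4), 4, "A")
  copy_cpt2 <- make_cpt(diag(4), 4, "B")
  cpts <- list(A = make_cpt(matrix(rep(0.25, 4), 1)),
               B = copy_cpt, C = copy_cpt2)
  d <- simulate_bn_dataset(adj, cpts, 100, seed = 4)
  expect_identical(d["A", ], d["B", ])
  expect_identical(d["B", ], d["C", ])
  expect_identical(simulate_bn_dataset(adj, cpts, 50, seed = 8),
                   simulate_bn_dataset(adj, cpts, 50, seed = 8))
  cyc <- adj; cyc["C", "A"] <- 1L
  expect_error(simulate_bn_dataset(cyc, cpts, 10, seed = 1), "cyclic")
  # empty graph, uniform nodes: pairwise MI stays near zero at n = 2000
  e3 <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  u <- make_cpt(matrix(rep(0.25, 4), 1))
  d2 <- simulate_bn_dataset(e3, list(A = u, B = u, C = u), 2000, seed = 5)
  expect_lt(empirical_mi(d2["A", ], d2["B", ]), 0.01)
})

test_that("local networks, representatives and the global network cohere", {
  run <- run_toy_pipeline(55, n_per_condition = 60, n_perms = 10)
  flux <- run$fm$values[names(run$clusters$assignment), ]
  loc <- learn_local_bns(run$clusters, flux, seed = 1)
  expect_length(loc$representatives, run$clusters$n_clusters)
  # one representative per cluster, member of that cluster
  for (cid in names(loc$representatives)) {
    members <- names(run$clusters$assignment)[run$clusters$assignment == as.integer(cid)]
    expect_true(loc$representatives[[cid]] %in% members)
  }
  # two perfectly coupled reactions: local BN prefers the single arc
  pair_bins <- rbind(p1 = rep(1:4, each = 30), p2 = rep(1:4, each = 30))
  bn2 <- tabu_learn(pair_bins, seed = 1)
  expect_equal(sum(bn2$adj), 1)
  g <- learn_global_bn(loc$representatives, loc$bins, seed = 2)
  expect_true(igraph::is_dag(bn_to_igraph(g)))
  expect_gt(sum(g$adj), 0)
  # representative choice is seed-invariant on the fixture
  run2 <- run_toy_pipeline(56, n_per_condition = 60, n_perms = 10)
  loc2 <- learn_local_bns(run2$clusters, run2$fm$values[names(run2$clusters$assignment), ],
                          seed = 77)
  expect_identical(unname(loc$representatives), unname(loc2$representatives))
})
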