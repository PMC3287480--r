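# Discrete Bayesian networks over discretized fluxes: equal-frequency
# discretization, mutual information / total mutual information, MDL scoring
# and tabu-search structure learning.

#' Equal-frequency discretization
#'
#' Divides the empirical distribution of a continuous variable into `k`
#' intervals containing equal (or as equal as possible) numbers of points.
#' Tied values are never split across bins: every occurrence of the same
#' value gets the bin of the tie group's mid-rank. With fewer than `k`
#' distinct values, the binning collapses to the number of distinct values
#' with a warning.
#'
#' @param values numeric vector (>= k points for a full k-way split).
#' @param k number of intervals (4 by default).
#' @return list with `bins` (integer vector in `1..n_bins`), `n_bins`,
#'   `edges` (approximate interval boundaries) and `counts`.
#' @export
discretize_equal_frequency <- function(values, k = 4) {
  n <- length(values)
  if (n < 1) stop_fmb("cannot discretize an empty vector")
  u <- sort(unique(values))
  if (length(u) < k)
    warning(sprintf("only %d distinct value(s); using %d bin(s) instead of %d",
                    length(u), length(u), k), call. = FALSE)
  r <- rank(values, ties.method = "average")   # mid-rank, shared by ties
  raw_bin <- ceiling(r * k / n)
  raw_bin[raw_bin < 1] <- 1L
  # renumber to consecutive occupied bins
  occupied <- sort(unique(raw_bin))
  bins <- match(raw_bin, occupied)
  edges <- vapply(seq_len(length(occupied) - 1), function(b)
    (max(values[bins == b]) + min(values[bins == b + 1])) / 2, numeric(1))
  list(bins = as.integer(bins), n_bins = length(occupied),
       edges = edges, counts = tabulate(bins))
}

#' Discretize every row of a flux matrix jointly
#'
#' All samples (both conditions) of each reaction are discretized together
#' with one shared equal-frequency scheme, so mutual information and network
#' scores computed anywhere in the pipeline refer to the same binning.
#'
#' @param values numeric matrix, variables in rows.
#' @param k bins per variable.
#' @return integer matrix of bin indices with the same dimnames.
#' @export
discretize_matrix <- function(values, k = 4) {
  out <- t(apply(values, 1, function(v) discretize_equal_frequency(v, k)$bins))
  dimnames(out) <- dimnames(values)
  storage.mode(out) <- "integer"
  out
}

#' Empirical mutual information (bits)
#'
#' `I(x;y) = sum p(x,y) log2 p(x,y) / (p(x) p(y))` over the empirical joint
#' frequencies of two discrete vectors, with `0 log 0 = 0`.
#'
#' @param x,y equal-length discrete vectors (bin indices).
#' @return mutual information in bits (non-negative, symmetric).
#' @export
empirical_mi <- function(x, y) {
  if (length(x) != length(y)) stop_fmb("mutual information needs equal lengths")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  ind <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / ind[nz]))
}

#' Total mutual information of a reaction within its module
#'
#' Sum of the pairwise empirical mutual information between `target` and
#' every other member of the cluster; a singleton cluster gives 0.
#'
#' @param bins integer matrix of discretized fluxes (variables in rows).
#' @param target target variable (row name).
#' @param members character vector of cluster member row names (including
#'   `target`).
#' @return TMI in bits.
#' @export
tmi <- function(bins, target, members) {
  if (!target %in% members) stop_fmb("target '%s' not in cluster", target)
  others <- setdiff(members, target)
  if (!length(others)) return(0)
  sum(vapply(others, function(r) empirical_mi(bins[target, ], bins[r, ]), numeric(1)))
}

#' Select the representative reaction of a module
#'
#' The member with the highest total mutual information; exact ties are
#' broken lexicographically by reaction id and flagged.
#'
#' @inheritParams tmi
#' @return list with `representative`, `tmi` (named vector over members) and
#'   `tie` flag.
#' @export
select_representative <- function(bins, members) {
  if (!length(members)) stop_fmb("empty cluster")
  tv <- vapply(sort(members), function(t) tmi(bins, t, members), numeric(1))
  best <- names(tv)[which.max(tv)]          # first of sorted names -> lexicographic
  list(representative = best, tmi = tv, tie = sum(tv == max(tv)) > 1)
}

# ---- MDL scoring ---------------------------------------------------------

# Family contribution to the MDL score (bits): complexity
# (log2 M)/2 * q_i (r_i - 1) plus negative log-likelihood of node given its
# parents under maximum-likelihood CPT frequencies.
family_mdl <- function(bins, node, parents, r) {
  M <- ncol(bins)
  x <- bins[node, ]
  q <- if (length(parents)) prod(r[parents]) else 1
  complexity <- log2(M) / 2 * q * (r[node] - 1)
  if (length(parents)) {
    key <- do.call(paste, c(lapply(parents, function(p) bins[p, ]), sep = "\r"))
    counts <- table(key, x)
  } else {
    counts <- t(as.matrix(table(x)))
  }
  nij <- rowSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log2(counts[nz] / nij[row(counts)[nz]]))
  complexity - ll
}

# topological order of a dag adjacency (adj[i,j]=1 means i -> j); NULL if cyclic
topo_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    for (w in which(adj[v, ] > 0)) {
      indeg[w] <- indeg[w] - 1
      if (!is.na(indeg[w]) && indeg[w] == 0) { avail <- c(avail, w); indeg[w] <- NA }
    }
  }
  if (length(order) < n) NULL else order
}

#' MDL score of a network structure (bits; lower is better)
#'
#' `MDL = (log2 M)/2 * sum_i q_i (r_i - 1) + sum_i NLL(X_i | Pa_i)` where
#' `r_i` is the number of states of node i, `q_i` the number of parent
#' configurations and the negative log-likelihood uses maximum-likelihood
#' conditional frequencies. The score decomposes over families.
#'
#' @param adj square 0/1 adjacency matrix (`adj[i,j] = 1` for an arc i -> j)
#'   with dimnames matching rows of `bins`.
#' @param bins integer matrix of discretized data, variables in rows.
#' @return MDL score in bits.
#' @export
mdl_score <- function(adj, bins) {
  nodes <- rownames(bins)
  adj <- adj[nodes, nodes, drop = FALSE]
  if (is.null(topo_order(adj))) stop_fmb("graph is cyclic; MDL requires a DAG")
  r <- apply(bins, 1, function(v) length(unique(v)))
  sum(vapply(seq_along(nodes), function(i)
    family_mdl(bins, nodes[i], nodes[adj[, i] > 0], r), numeric(1)))
}

# ---- tabu structure search ----------------------------------------------

move_key <- function(type, i, j) paste(type, i, j)

# would adding arc i->j create a cycle? (path j ~> i exists)
creates_cycle <- function(adj, i, j) {
  stack <- j; seen <- logical(nrow(adj))
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == i) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] > 0))
  }
  FALSE
}

tabu_search_once <- function(bins, adj0, max_iter, tabu_len, max_parents, r) {
  nodes <- rownames(bins)
  n <- length(nodes)
  fam <- function(i, adj) family_mdl(bins, nodes[i], nodes[adj[, i] > 0], r)
  adj <- adj0
  fam_scores <- vapply(seq_len(n), fam, numeric(1), adj = adj)
  score <- sum(fam_scores)
  best_adj <- adj; best_score <- score
  tabu <- character(0)
  since_best <- 0L
  cache <- new.env(parent = emptyenv())
  fam_cached <- function(i, parents_mask) {
    key <- paste(i, paste(which(parents_mask), collapse = ","), sep = ":")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- family_mdl(bins, nodes[i], nodes[parents_mask], r)
    cache[[key]] <- val
    val
  }

  for (iter in seq_len(max_iter)) {
    best_move <- NULL; best_move_score <- Inf
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (adj[i, j] == 0) {                      # add i -> j
        if (sum(adj[, j]) >= max_parents) next
        if (creates_cycle(adj, i, j)) next
        pm <- adj[, j] > 0; pm[i] <- TRUE
        new_score <- score - fam_scores[j] + fam_cached(j, pm)
        mv <- list(type = "add", i = i, j = j, score = new_score)
      } else {                                   # delete, or reverse
        pm <- adj[, j] > 0; pm[i] <- FALSE
        del_score <- score - fam_scores[j] + fam_cached(j, pm)
        mv <- list(type = "delete", i = i, j = j, score = del_score)
        key <- move_key(mv$type, i, j)
        if (mv$score < best_move_score && (!(key %in% tabu) || mv$score < best_score)) {
          best_move <- mv; best_move_score <- mv$score
        }
        # reverse i->j to j->i
        if (sum(adj[, i]) >= max_parents) next
        adj[i, j] <- 0
        cyc <- creates_cycle(adj, j, i)
        adj[i, j] <- 1
        if (cyc) next
        pmi <- adj[, i] > 0; pmi[j] <- TRUE
        new_score <- del_score - fam_scores[i] + fam_cached(i, pmi)
        mv <- list(type = "reverse", i = i, j = j, score = new_score)
      }
      key <- move_key(mv$type, mv$i, mv$j)
      if (mv$score < best_move_score && (!(key %in% tabu) || mv$score < best_score)) {
        best_move <- mv; best_move_score <- mv$score
      }
    }
    if (is.null(best_move)) break
    # apply move, record its inverse as tabu
    i <- best_move$i; j <- best_move$j
    inverse <- switch(best_move$type,
                      add = move_key("delete", i, j),
                      delete = move_key("add", i, j),
                      reverse = move_key("reverse", j, i))
    if (best_move$type == "add") {
      adj[i, j] <- 1
      fam_scores[j] <- fam_cached(j, adj[, j] > 0)
    } else if (best_move$type == "delete") {
      adj[i, j] <- 0
      fam_scores[j] <- fam_cached(j, adj[, j] > 0)
    } else {
      adj[i, j] <- 0; adj[j, i] <- 1
      fam_scores[j] <- fam_cached(j, adj[, j] > 0)
      fam_scores[i] <- fam_cached(i, adj[, i] > 0)
    }
    score <- sum(fam_scores)
    tabu <- c(inverse, tabu)
    if (length(tabu) > tabu_len) tabu <- tabu[seq_len(tabu_len)]
    if (score < best_score - 1e-9) {
      best_score <- score; best_adj <- adj; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > max(15L, tabu_len + 5L)) break   # stalled in tabu escape
    }
  }
  list(adj = best_adj, score = best_score)
}

random_dag <- function(n, max_parents, p_arc = 0.25) {
  ord <- sample.int(n)
  adj <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (stats::runif(1) < p_arc && sum(adj[, ord[b]]) < max_parents)
      adj[ord[a], ord[b]] <- 1L
  }
  adj
}

#' Learn a Bayesian network structure by tabu search under MDL
#'
#' Greedy hill climbing over DAG space with arc addition, deletion and
#' reversal moves, rejecting cycles; a tabu list of the most recent moves'
#' inverses lets the search accept the best non-tabu neighbor even when it
#' worsens the score (escaping local minima), while the best structure ever
#' visited is retained. Restart 1 starts from the empty graph, further
#' restarts from random seeded DAGs.
#'
#' @param bins integer matrix of discretized data, variables in rows.
#' @param max_iter search iterations per restart.
#' @param tabu_len tabu-list length.
#' @param restarts number of restarts (first from the empty graph).
#' @param max_parents parent-set size cap (bounds CPT size).
#' @param seed integer seed (random restarts only; the search is otherwise
#'   deterministic).
#' @return object of class `fmb_bn`: list with `nodes`, `adj` (adjacency,
#'   `adj[i,j]=1` for arc i -> j), `mdl`, `cpts` (Laplace-smoothed
#'   conditional probability tables).
#' @export
tabu_learn <- function(bins, max_iter = 200, tabu_len = 10, restarts = 3,
                       max_parents = 4, seed = 1) {
  nodes <- rownames(bins)
  if (length(nodes) < 2) stop_fmb("need at least 2 variables to learn a network")
  n <- length(nodes)
  r <- apply(bins, 1, function(v) length(unique(v)))
  starts <- with_seed(seed, c(
    list(matrix(0L, n, n)),
    lapply(seq_len(max(0, restarts - 1)), function(i) random_dag(n, max_parents))))
  best <- NULL
  for (adj0 in starts) {
    res <- tabu_search_once(bins, adj0, max_iter, tabu_len, max_parents, r)
    if (is.null(best) || res$score < best$score - 1e-9) best <- res
  }
  adj <- best$adj
  dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, adj = adj, mdl = best$score,
                 cpts = fit_cpts(adj, bins)),
            class = "fmb_bn")
}

#' Maximum-likelihood CPTs with Laplace smoothing
#'
#' One conditional probability table per node: an array whose leading
#' dimensions run over the states of the node's parents (in node order) and
#' whose last dimension runs over the node's own states; every row sums to 1.
#'
#' @param adj DAG adjacency with dimnames.
#' @param bins discretized data.
#' @param alpha Laplace pseudo-count.
#' @return named list of arrays with a `parents` attribute each.
#' @export
fit_cpts <- function(adj, bins, alpha = 1) {
  nodes <- rownames(bins)
  r <- apply(bins, 1, function(v) max(v))
  out <- list()
  for (node in nodes) {
    parents <- nodes[adj[, node] > 0]
    dims <- c(r[parents], r[node])
    counts <- array(alpha, dim = if (length(dims) > 1) dims else c(1, dims))
    for (s in seq_len(ncol(bins))) {
      idx <- c(bins[parents, s], bins[node, s])
      if (length(parents) == 0) idx <- c(1, idx)
      counts[matrix(idx, 1)] <- counts[matrix(idx, 1)] + 1
    }
    norm <- apply(counts, seq_len(length(dim(counts)) - 1), sum)
    cpt <- sweep(counts, seq_len(length(dim(counts)) - 1), norm, "/")
    attr(cpt, "parents") <- parents
    out[[node]] <- cpt
  }
  out
}

#' @export
print.fmb_bn <- function(x, ...) {
  cat(sprintf("fmb_bn: %d nodes, %d arcs, MDL %.2f bits\n",
              length(x$nodes), sum(x$adj), x$mdl))
  invisible(x)
}

#' Learn local Bayesian networks and pick module representatives
#'
#' Discretizes the flux values of all clustered reactions once (shared
#' equal-frequency scheme), learns one local network per cluster with at
#' least two members (singletons get trivial single-node networks), computes
#' every member's total mutual information within its cluster and selects
#' the representative reaction of each module.
#'
#' @param clusters an `fmb_clusters` (after duplicate reinsertion).
#' @param values numeric flux matrix containing all clustered reactions
#'   (original flux values; pattern matrices are only for clustering).
#' @param k discretization intervals.
#' @param ... passed to [tabu_learn()].
#' @return list with `bns` (per cluster), `tmi_table` (`data.frame`),
#'   `representatives` (named by cluster id), `bins`.
#' @export
learn_local_bns <- function(clusters, values, k = 4, ...) {
  assign <- clusters$assignment
  missing <- setdiff(names(assign), rownames(values))
  if (length(missing))
    stop_fmb("flux values missing for clustered reaction(s): %s",
             paste(missing, collapse = ", "))
  bins <- suppressWarnings(discretize_matrix(values[names(assign), , drop = FALSE], k))
  cl_ids <- sort(unique(assign))
  bns <- list(); reps <- character(0); rows <- list()
  for (cid in cl_ids) {
    members <- names(assign)[assign == cid]
    sel <- select_representative(bins, members)
    reps[as.character(cid)] <- sel$representative
    rows[[as.character(cid)]] <- data.frame(
      cluster_id = cid, reaction_id = names(sel$tmi), tmi_bits = unname(sel$tmi),
      is_representative = names(sel$tmi) == sel$representative,
      stringsAsFactors = FALSE)
    bns[[as.character(cid)]] <- if (length(members) >= 2)
      tabu_learn(bins[members, , drop = FALSE], ...)
    else structure(list(nodes = members,
                        adj = matrix(0L, 1, 1, dimnames = list(members, members)),
                        mdl = mdl_score(matrix(0L, 1, 1, dimnames = list(members, members)),
                                        bins[members, , drop = FALSE]),
                        cpts = fit_cpts(matrix(0L, 1, 1, dimnames = list(members, members)),
                                        bins[members, , drop = FALSE])),
                   class = "fmb_bn")
  }
  list(bns = bns, tmi_table = do.call(rbind, rows),
       representatives = reps, bins = bins)
}

#' Learn the global Bayesian network over module representatives
#'
#' @param representatives named character vector (cluster id -> reaction id),
#'   as from [learn_local_bns()].
#' @param bins shared discretized data (from [learn_local_bns()]).
#' @param ... passed to [tabu_learn()].
#' @return an `fmb_bn` over the representative reactions.
#' @export
learn_global_bn <- function(representatives, bins, ...) {
  tabu_learn(bins[representatives, , drop = FALSE], ...)
}

#' Convert a learned network to an igraph object
#' @param bn an `fmb_bn`.
#' @return an igraph directed graph.
#' @export
bn_to_igraph <- function(bn) {
  igraph::graph_from_adjacency_matrix(bn$adj, mode = "directed")
}

#' Write a learned network as GraphML or DOT
#' @param bn an `fmb_bn`.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_bn <- function(bn, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(bn_to_igraph(bn), path, format = format)
  invisible(path)
}
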