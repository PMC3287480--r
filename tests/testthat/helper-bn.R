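# enumerate all DAG adjacency matrices over `nodes` (25 DAGs for 3 nodes)
all_dags <- function(nodes) {
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)))
  out <- list()
  for (mask in 0:(2^length(pairs) - 1)) {
    adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    bits <- bitwAnd(bitwShiftR(mask, seq_along(pairs) - 1), 1L)
    adj[pairs] <- bits
    if (any(adj & t(adj))) next                       # both directions
    ok <- tryCatch({ mdl_check_acyclic(adj); TRUE }, error = function(e) FALSE)
    if (ok) out[[length(out) + 1]] <- adj
  }
  out
}
mdl_check_acyclic <- function(adj) {
  n <- nrow(adj); visited <- rep(0L, n)
  rec <- function(v) {
    visited[v] <<- 1L
    for (w in which(adj[v, ] > 0)) {
      if (visited[w] == 1L) stop("cycle")
      if (visited[w] == 0L) rec(w)
    }
    visited[v] <<- 2L
  }
  for (v in seq_len(n)) if (visited[v] == 0L) rec(v)
  invisible(TRUE)
}

rand_bins <- function(nodes, M, k = 3, seed) {
  set.seed(seed)
  out <- matrix(sample.int(k, length(nodes) * M, replace = TRUE), length(nodes),
                dimnames = list(nodes, NULL))
  # add some dependence half the time
  if (stats::runif(1) < 0.5 && length(nodes) >= 2)
    out[2, ] <- ifelse(stats::runif(M) < 0.7, out[1, ], out[2, ])
  out
}
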